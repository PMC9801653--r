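#' Select transcriptionally active and inactive gene sets by expression
#'
#' The `n` most and `n` least expressed genes in the named sample; ties at
#' a set boundary are broken by lexicographic gene id, so the selection is
#' deterministic.
#'
#' @param expression Count matrix (genes x samples).
#' @param sample_id Column to rank by.
#' @param n Set size (default 800).
#' @return List with character vectors `active` and `inactive`.
#' @export
select_gene_sets <- function(expression, sample_id, n = 800L) {
  if (!sample_id %in% colnames(expression))
    stop(sprintf("sample %s not in expression table", sample_id))
  if (nrow(expression) < 2L * n)
    stop(sprintf("need at least %d genes to pick two disjoint sets of %d",
                 2L * n, n))
  ids <- rownames(expression)
  v <- expression[, sample_id]
  active <- ids[order(-v, ids)][seq_len(n)]
  inactive <- ids[order(v, ids)][seq_len(n)]
  list(active = active, inactive = inactive)
}

# representative TSS of a model: mean of the TSS set, rounded toward the CDS
.representative_tss <- function(m) {
  mu <- mean(m$tss$position)
  if (m$gene$strand != "-") as.integer(ceiling(mu)) else as.integer(floor(mu))
}

#' TSS-centered average signal metaprofile
#'
#' For each gene in `gene_set`, a window of `window` bp on either side of
#' the representative TSS (the mean of the gene's TSS set, rounded toward
#' the CDS) is oriented so that upstream lies on the left for both
#' strands, coverage is averaged within consecutive `bin_size`-bp bins,
#' and bins are then averaged across genes (positions outside chromosome
#' bounds are excluded from the means).  The track is expected to be
#' normalized upstream (e.g. BPM); no renormalization is applied.
#'
#' @param track A [coverage_track()] of normalized signal.
#' @param models Named list of `gene_model` objects.
#' @param gene_set Character vector of gene ids.
#' @param window Half-window in bp (default 1000).
#' @param bin_size Bin width in bp (default 10).
#' @param gene_set_name,mark_name Labels carried on the result.
#' @return Object of class `meta_profile` with `2*window/bin_size` bin
#'   values and the bin-center offsets relative to the TSS.
#' @export
metaprofile <- function(track, models, gene_set, window = 1000L,
                        bin_size = 10L, gene_set_name = "genes",
                        mark_name = track$sample_id) {
  stopifnot((2L * window) %% bin_size == 0L)
  nb <- (2L * window) %/% bin_size
  acc <- matrix(NA_real_, nrow = 0L, ncol = nb)
  used <- 0L
  for (gid in gene_set) {
    m <- models[[gid]]
    if (is.null(m)) {
      warning(sprintf("gene %s has no model; skipped", gid))
      next
    }
    chrom <- m$gene$chrom
    r <- track$values[[chrom]]
    if (is.null(r)) stop(sprintf("chromosome %s absent from signal track", chrom))
    len <- length(r)
    tss <- .representative_tss(m)
    plus <- m$gene$strand != "-"
    vals <- rep(NA_real_, nb)
    for (i in seq_len(nb)) {
      off0 <- -window + (i - 1L) * bin_size
      if (plus) {
        s <- tss + off0; e <- s + bin_size - 1L
      } else {
        e <- tss - off0; s <- e - bin_size + 1L
      }
      cs <- max(1L, s); ce <- min(len, e)
      if (cs > ce) next
      vals[i] <- mean(as.numeric(S4Vectors::window(r, cs, ce)))
    }
    acc <- rbind(acc, vals)
    used <- used + 1L
  }
  values <- if (nrow(acc)) colMeans(acc, na.rm = TRUE) else rep(NA_real_, nb)
  structure(list(mark_name = mark_name, gene_set_name = gene_set_name,
                 window = window, bin_size = bin_size,
                 offsets = -window + (seq_len(nb) - 0.5) * bin_size,
                 values = values, n_genes = used),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("<meta_profile> %s over %s (%d genes), +/-%d bp, bin %d bp, %d bins\n",
              x$mark_name, x$gene_set_name, x$n_genes, x$window, x$bin_size,
              length(x$values)))
  cat(sprintf("  max %.3f at %+d bp; mean %.3f\n", max(x$values),
              as.integer(x$offsets[which.max(x$values)]), mean(x$values)))
  invisible(x)
}

#' @export
plot.meta_profile <- function(x, ...) {
  graphics::plot(x$offsets, x$values, type = "l",
                 xlab = "distance from TSS (bp)",
                 ylab = "mean normalized signal",
                 main = sprintf("%s, %s (n=%d)", x$mark_name, x$gene_set_name,
                                x$n_genes), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
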