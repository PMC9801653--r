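#' Default SCV threshold ladder
#'
#' A discrete, roughly logarithmic scale of average-coverage thresholds
#' spanning 10 to 20,000 reads.  Only the range is fixed by the method; the
#' intermediate steps are a configurable choice.
#'
#' @return Strictly increasing numeric vector.
#' @export
default_scv_ladder <- function() {
  c(10, 20, 50, 100, 200, 500, 1000, 2000, 5000, 10000, 20000)
}

.check_ladder <- function(ladder) {
  if (length(ladder) == 0L) stop("threshold ladder must be non-empty")
  if (any(ladder < 1)) stop("ladder thresholds must be >= 1")
  if (is.unsorted(ladder, strictly = TRUE)) stop("ladder must be strictly increasing")
  as.numeric(ladder)
}

#' Assign transcript predictions to annotated genes
#'
#' A prediction is assigned to gene G iff its genomic span fully contains
#' G's CDS span, it intersects no other gene's CDS, and its strand is
#' compatible (equal, or unstranded `"."`).  Predictions intersecting zero
#' or two or more CDS, or failing containment or strand compatibility, go
#' to the unassigned pool (downstream nTAR/NAT candidates).
#'
#' @param preds A [prediction_table()].
#' @param genes Named list of [gene_record()].
#' @return List with `assigned` (named list gene_id -> prediction_table) and
#'   `unassigned` (prediction_table).
#' @export
assign_predictions <- function(preds, genes) {
  if (nrow(preds) == 0L || length(genes) == 0L)
    return(list(assigned = setNames(list(), character(0)), unassigned = preds))
  gdf <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    strand = vapply(genes, `[[`, "", "strand"),
    cds_start = vapply(genes, `[[`, 1L, "cds_start"),
    cds_end = vapply(genes, `[[`, 1L, "cds_end"),
    stringsAsFactors = FALSE)
  pgr <- GenomicRanges::GRanges(preds$chrom, IRanges::IRanges(preds$start, preds$end))
  ggr <- GenomicRanges::GRanges(gdf$chrom, IRanges::IRanges(gdf$cds_start, gdf$cds_end))
  ov <- GenomicRanges::findOverlaps(pgr, ggr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  n_hits <- tabulate(qh, nbins = nrow(preds))
  target <- rep(NA_integer_, nrow(preds))
  single <- which(n_hits == 1L)
  target[qh[qh %in% single]] <- sh[qh %in% single]
  ok <- !is.na(target)
  if (any(ok)) {
    i <- which(ok)
    g <- target[i]
    contains <- preds$start[i] <= gdf$cds_start[g] & preds$end[i] >= gdf$cds_end[g]
    strand_ok <- .strand_compatible(preds$strand[i], gdf$strand[g])
    ok[i] <- contains & strand_ok
  }
  assigned_gene <- ifelse(ok, gdf$gene_id[target], NA_character_)
  assigned <- list()
  for (g in unique(assigned_gene[!is.na(assigned_gene)])) {
    assigned[[g]] <- preds[which(assigned_gene == g), , drop = FALSE]
  }
  list(assigned = assigned,
       unassigned = preds[is.na(assigned_gene), , drop = FALSE])
}

#' SCV selection: retain predictions above the most restrictive threshold
#'
#' Let `t*` be the largest ladder threshold cleared (inclusively) by at
#' least one prediction's average coverage; all predictions with
#' `avg_coverage >= t*` are selected.  If no prediction reaches the
#' smallest threshold the selection is empty and the gene gets no model.
#'
#' @param preds_for_gene [prediction_table()] of predictions assigned to
#'   one gene.
#' @param ladder Strictly increasing threshold ladder (see
#'   [default_scv_ladder()]).
#' @return The selected subset, with attribute `"threshold"` set to `t*`
#'   (or `NA` when empty).
#' @export
scv_select <- function(preds_for_gene, ladder = default_scv_ladder()) {
  ladder <- .check_ladder(ladder)
  covs <- preds_for_gene$avg_coverage
  reached <- ladder[vapply(ladder, function(t) any(covs >= t), TRUE)]
  if (length(reached) == 0L) {
    out <- preds_for_gene[0L, , drop = FALSE]
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  tstar <- max(reached)
  out <- preds_for_gene[covs >= tstar, , drop = FALSE]
  attr(out, "threshold") <- tstar
  out
}

# cluster sorted positions whose successive gaps are <= merge_bp;
# representative = position of the maximum-coverage supporter in the cluster
.cluster_positions <- function(pos, cov, merge_bp) {
  o <- order(pos)
  pos <- pos[o]; cov <- cov[o]; idx <- o
  cl <- cumsum(c(1L, as.integer(diff(pos) > merge_bp)))
  lapply(split(seq_along(pos), cl), function(k)
    list(rep = pos[k][which.max(cov[k])], members = idx[k]))
}

#' Build a per-gene model from the selected predictions
#'
#' On the + strand the TSS is the transcript start and the TES the
#' transcript end (reversed on -).  The 5'UTR is `[TSS, cds_start-1]`
#' (+ strand) or `[cds_end+1, TSS]` (-), the 3'UTR symmetric.  Distinct
#' TSS/TES coordinates are collected with the (sample, dataset) provenance
#' supporting each, the longest UTRs recorded, and a multiplicity class
#' assigned: `single`, `multi_TSS_only`, `multi_TES_only` or `multi_both`.
#'
#' @param gene A [gene_record()].
#' @param selected Non-empty [prediction_table()] of SCV-selected
#'   transcripts, each spanning the CDS entirely.
#' @param merge_bp Optional clustering tolerance: TSS/TES closer than this
#'   are merged (default 0 = distinct exact coordinates).
#' @return Object of class `gene_model`.
#' @export
build_gene_model <- function(gene, selected, merge_bp = 0L) {
  stopifnot(nrow(selected) >= 1L)
  if (!all(selected$start <= gene$cds_start & selected$end >= gene$cds_end))
    stop(sprintf("internal error: selected transcript does not contain CDS of %s",
                 gene$gene_id))
  plus <- gene$strand != "-"
  tss_pos <- if (plus) selected$start else selected$end
  tes_pos <- if (plus) selected$end else selected$start
  mk_set <- function(pos) {
    cl <- .cluster_positions(pos, selected$avg_coverage, merge_bp)
    df <- data.frame(position = vapply(cl, `[[`, 1, "rep"))
    df$support <- lapply(cl, function(c)
      data.frame(sample_id = selected$sample_id[c$members],
                 dataset_id = selected$dataset_id[c$members],
                 stringsAsFactors = FALSE))
    df <- df[order(df$position), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  tss <- mk_set(tss_pos)
  tes <- mk_set(tes_pos)
  utr5 <- if (plus) {
    cbind(start = selected$start, end = rep(gene$cds_start - 1L, nrow(selected)))
  } else {
    cbind(start = rep(gene$cds_end + 1L, nrow(selected)), end = selected$end)
  }
  utr3 <- if (plus) {
    cbind(start = rep(gene$cds_end + 1L, nrow(selected)), end = selected$end)
  } else {
    cbind(start = selected$start, end = rep(gene$cds_start - 1L, nrow(selected)))
  }
  width0 <- function(m) pmax(0L, m[, "end"] - m[, "start"] + 1L)
  pick_longest <- function(m) {
    w <- width0(m)
    if (all(w == 0L)) NULL else m[which.max(w), ]
  }
  n_tss <- nrow(tss); n_tes <- nrow(tes)
  mclass <- if (n_tss == 1L && n_tes == 1L) "single"
            else if (n_tss > 1L && n_tes == 1L) "multi_TSS_only"
            else if (n_tss == 1L && n_tes > 1L) "multi_TES_only"
            else "multi_both"
  structure(
    list(gene_id = gene$gene_id, gene = gene, selected = selected,
         tss = tss, tes = tes,
         utr5 = utr5, utr3 = utr3,
         longest_utr5 = pick_longest(utr5), longest_utr3 = pick_longest(utr3),
         multiplicity_class = mclass,
         datasets = sort(unique(selected$dataset_id)),
         threshold = attr(selected, "threshold") %||% NA_real_),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s): %d transcript(s), %d TSS, %d TES, class %s\n",
              x$gene_id, x$gene$strand, nrow(x$selected), nrow(x$tss),
              nrow(x$tes), x$multiplicity_class))
  invisible(x)
}

#' Run SCV end to end: assign, select, build models
#'
#' @param genes Named list of [gene_record()].
#' @param preds A [prediction_table()] pooling all samples.
#' @param ladder Threshold ladder.
#' @param merge_bp TSS/TES merge tolerance (default 0).
#' @return List with `models` (named list of [build_gene_model()] outputs,
#'   only genes with a non-empty selection), `unassigned`
#'   (prediction_table) and `no_model` (gene ids whose predictions never
#'   reached the smallest threshold).
#' @export
scv_annotate <- function(genes, preds, ladder = default_scv_ladder(),
                         merge_bp = 0L) {
  ladder <- .check_ladder(ladder)
  asg <- assign_predictions(preds, genes)
  models <- list(); no_model <- character(0)
  for (g in names(asg$assigned)) {
    sel <- scv_select(asg$assigned[[g]], ladder)
    if (nrow(sel) == 0L) { no_model <- c(no_model, g); next }
    models[[g]] <- build_gene_model(genes[[g]], sel, merge_bp = merge_bp)
  }
  list(models = models, unassigned = asg$unassigned, no_model = no_model)
}

#' Summarize a set of gene models
#'
#' Reports, separately for single-transcript and multi-transcript genes,
#' the median/mean/max 5' and 3' UTR sizes (multi-gene statistics pool all
#' UTRs of all transcripts); for multi-boundary genes the per-gene distance
#' between the most distant TSS and most distant TES; counts per
#' multiplicity class; and per-dataset contribution sets.
#'
#' @param models Named list of `gene_model` objects.
#' @return Object of class `scv_summary`.
#' @export
summarize_models <- function(models) {
  stat3 <- function(x) {
    if (length(x) == 0L) c(median = NA_real_, mean = NA_real_, max = NA_real_)
    else c(median = median(x), mean = mean(x), max = max(x))
  }
  w0 <- function(m) pmax(0L, m[, "end"] - m[, "start"] + 1L)
  # "single" means one distinct transcript annotation (one TSS and one TES),
  # regardless of how many samples support it
  single <- vapply(models, function(m) m$multiplicity_class == "single", TRUE)
  utr_sizes <- function(which_models, field) {
    unlist(lapply(which_models, function(m) {
      w <- w0(unique(m[[field]]))  # distinct UTR intervals per gene
      w[w > 0L]
    }), use.names = FALSE)
  }
  dist_tbl <- function(field) {
    d <- vapply(models, function(m) {
      p <- m[[field]]$position
      if (length(p) > 1L) max(p) - min(p) else NA_real_
    }, 1)
    d[!is.na(d)]
  }
  classes <- vapply(models, `[[`, "", "multiplicity_class")
  ds_sets <- vapply(models, function(m) paste(m$datasets, collapse = "+"), "")
  tssd <- dist_tbl("tss"); tesd <- dist_tbl("tes")
  structure(list(
    n_genes = length(models),
    class_counts = table(factor(classes, levels = c(
      "single", "multi_TSS_only", "multi_TES_only", "multi_both"))),
    utr5_single = stat3(utr_sizes(models[single], "utr5")),
    utr3_single = stat3(utr_sizes(models[single], "utr3")),
    utr5_multi = stat3(utr_sizes(models[!single], "utr5")),
    utr3_multi = stat3(utr_sizes(models[!single], "utr3")),
    tss_distance = c(stat3(tssd), n = length(tssd)),
    tes_distance = c(stat3(tesd), n = length(tesd)),
    dataset_venn = table(ds_sets)
  ), class = "scv_summary")
}

#' @export
print.scv_summary <- function(x, ...) {
  cat(sprintf("SCV gene-model summary: %d genes\n", x$n_genes))
  print(x$class_counts)
  f <- function(nm, s) cat(sprintf("  %-12s median %.0f  mean %.1f  max %.0f\n",
                                   nm, s[["median"]], s[["mean"]], s[["max"]]))
  cat("UTR sizes, single-transcript genes:\n")
  f("5'UTR", x$utr5_single); f("3'UTR", x$utr3_single)
  cat("UTR sizes, multi-transcript genes (all UTRs pooled):\n")
  f("5'UTR", x$utr5_multi); f("3'UTR", x$utr3_multi)
  cat(sprintf("Most-distant TSS spacing (n=%d): mean %.1f bp; TES (n=%d): mean %.1f bp\n",
              x$tss_distance[["n"]], x$tss_distance[["mean"]],
              x$tes_distance[["n"]], x$tes_distance[["mean"]]))
  cat("Dataset contributions:\n"); print(x$dataset_venn)
  invisible(x)
}

#' Extract fixed-width promoter windows upstream of every TSS
#'
#' For each TSS of each model, the `width`-bp sequence immediately upstream
#' on the coding strand (reverse-complemented for minus-strand genes),
#' truncated at chromosome edges with a warning.
#'
#' @param models Named list of `gene_model` objects.
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @param width Window width in bp (default 200).
#' @return A [Biostrings::DNAStringSet] named `<gene_id>_TSS<position>`.
#' @export
extract_promoter_windows <- function(models, genome, width = 200L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqs <- list()
  for (m in models) {
    chrom <- m$gene$chrom
    if (!chrom %in% names(genome))
      stop(sprintf("chromosome %s missing from genome FASTA", chrom))
    len <- Biostrings::width(genome[chrom])
    for (tss in m$tss$position) {
      if (m$gene$strand != "-") {
        s <- tss - width; e <- tss - 1L
        if (s < 1L) {
          warning(sprintf("%s TSS %d: window truncated at chromosome start",
                          m$gene_id, tss))
          s <- 1L
        }
        if (e < s) next
        sq <- Biostrings::subseq(genome[[chrom]], s, e)
      } else {
        s <- tss + 1L; e <- tss + width
        if (e > len) {
          warning(sprintf("%s TSS %d: window truncated at chromosome end",
                          m$gene_id, tss))
          e <- len
        }
        if (e < s) next
        sq <- Biostrings::reverseComplement(Biostrings::subseq(genome[[chrom]], s, e))
      }
      seqs[[sprintf("%s_TSS%d", m$gene_id, tss)]] <- sq
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  out
}
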