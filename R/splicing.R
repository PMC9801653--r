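#' Count introns located inside annotated UTRs
#'
#' An intron of a selected transcript (a gap between consecutive exons) is
#' a 5'UTR intron iff it lies fully within that transcript's 5'UTR
#' interval, likewise for the 3'UTR; introns straddling a CDS boundary
#' count as CDS introns.  Distinct intron coordinates are counted once per
#' gene.
#'
#' @param models Named list of `gene_model` objects.
#' @return `data.frame` with per-gene columns `n_utr5_introns`,
#'   `n_utr3_introns` and a `both_utrs` flag.
#' @export
detect_utr_introns <- function(models) {
  rows <- lapply(models, function(m) {
    u5 <- character(0); u3 <- character(0)
    for (i in seq_len(nrow(m$selected))) {
      gaps <- intron_gaps(m$selected$exons[[i]])
      if (nrow(gaps) == 0L) next
      r5 <- m$utr5[i, ]; r3 <- m$utr3[i, ]
      for (j in seq_len(nrow(gaps))) {
        g <- gaps[j, ]
        key <- paste(g["start"], g["end"], sep = "-")
        if (r5["start"] <= r5["end"] &&
            .contains(r5["start"], r5["end"], g["start"], g["end"]))
          u5 <- c(u5, key)
        else if (r3["start"] <= r3["end"] &&
                 .contains(r3["start"], r3["end"], g["start"], g["end"]))
          u3 <- c(u3, key)
      }
    }
    data.frame(gene_id = m$gene_id,
               n_utr5_introns = length(unique(u5)),
               n_utr3_introns = length(unique(u3)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), n_utr5_introns = integer(0),
                      n_utr3_introns = integer(0))
  out$both_utrs <- out$n_utr5_introns > 0L & out$n_utr3_introns > 0L
  rownames(out) <- NULL
  out
}

.empty_events <- function() {
  data.frame(event_type = character(0), gene_id = character(0),
             chrom = character(0), strand = character(0),
             j1_start = integer(0), j1_end = integer(0),
             j2_start = integer(0), j2_end = integer(0),
             exon_start = integer(0), exon_end = integer(0),
             n_samples = integer(0), max_support = numeric(0),
             samples = character(0), stringsAsFactors = FALSE)
}

#' Classify junction-based alternative splicing events
#'
#' Junctions pass the confidence filter iff they appear in at least
#' `min_samples` distinct samples AND have support of at least `min_cov`
#' in at least one sample.  Among passing junctions of one gene (assigned
#' by containment within the model span):
#' \itemize{
#' \item two junctions sharing the acceptor-side splice site and differing
#'   at the donor side form an A5SS event (strand-aware: the donor is the
#'   5' splice site on the coding strand); sharing the donor, differing
#'   acceptor gives A3SS;
#' \item a passing junction whose span strictly contains an annotated exon
#'   of the gene, with the two flanking (inclusion) junctions of that exon
#'   also passing, gives an ES event.
#' }
#' Junctions that strictly contain an annotated exon are treated as
#' skipping junctions and excluded from A5SS/A3SS pairing, so a planted
#' exon-skipping event does not shadow as a spurious splice-site shift.
#'
#' @param junctions A [junction_table()] pooling all samples.
#' @param models Named list of `gene_model` objects.
#' @param min_samples Minimum number of independent samples (default 2).
#' @param min_cov Minimum support in at least one sample (default 5).
#' @param require_inclusion Require the flanking inclusion junctions of a
#'   skipped exon to pass the filter too (default `TRUE`).
#' @return `data.frame` of events (`event_type` in A5SS/A3SS/ES) with
#'   junction coordinates, skipped-exon span for ES, and sample support.
#' @export
classify_junction_events <- function(junctions, models, min_samples = 2L,
                                     min_cov = 5, require_inclusion = TRUE) {
  agg <- aggregate_junctions(junctions)
  agg <- agg[agg$n_samples >= min_samples & agg$max_count >= min_cov, , drop = FALSE]
  if (nrow(agg) == 0L) return(.empty_events())
  # assign junctions to gene models by containment within the model span
  spans <- data.frame(
    gene_id = vapply(models, `[[`, "", "gene_id"),
    chrom = vapply(models, function(m) m$gene$chrom, ""),
    strand = vapply(models, function(m) m$gene$strand, ""),
    start = vapply(models, function(m) min(m$selected$start), 1L),
    end = vapply(models, function(m) max(m$selected$end), 1L),
    stringsAsFactors = FALSE)
  jgr <- GenomicRanges::GRanges(agg$chrom, IRanges::IRanges(agg$start, agg$end))
  ggr <- GenomicRanges::GRanges(spans$chrom, IRanges::IRanges(spans$start, spans$end))
  ov <- GenomicRanges::findOverlaps(jgr, ggr, type = "within", ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  strand_ok <- .strand_compatible(agg$strand[qh], spans$strand[sh])
  qh <- qh[strand_ok]; sh <- sh[strand_ok]
  nhit <- tabulate(qh, nbins = nrow(agg))
  if (any(nhit > 1L))
    warning(sprintf("%d junction(s) contained in more than one gene model; discarded",
                    sum(nhit > 1L)))
  keep <- nhit[qh] == 1L
  qh <- qh[keep]; sh <- sh[keep]
  events <- list()
  push <- function(...) events[[length(events) + 1L]] <<- data.frame(...,
    stringsAsFactors = FALSE)
  for (gi in unique(sh)) {
    m <- models[[spans$gene_id[gi]]]
    jj <- agg[qh[sh == gi], , drop = FALSE]
    plus <- m$gene$strand != "-"
    # annotated exons of selected transcripts (distinct)
    ex_all <- unique(do.call(rbind, m$selected$exons))
    contains_exon <- vapply(seq_len(nrow(jj)), function(k)
      any(jj$start[k] < ex_all[, "start"] & jj$end[k] > ex_all[, "end"]), TRUE)
    # --- A5SS / A3SS among non-skipping junctions
    pj <- jj[!contains_exon, , drop = FALSE]
    if (nrow(pj) > 1L) {
      pair_events <- function(shared, differing, type_plus, type_minus) {
        for (v in unique(pj[[shared]])) {
          grp <- pj[pj[[shared]] == v, , drop = FALSE]
          if (nrow(grp) < 2L) next
          cmb <- utils::combn(nrow(grp), 2L)
          for (c2 in seq_len(ncol(cmb))) {
            a <- grp[cmb[1L, c2], ]; b <- grp[cmb[2L, c2], ]
            if (a[[differing]] == b[[differing]]) next
            samp <- sort(unique(c(strsplit(a$samples, ",")[[1L]],
                                  strsplit(b$samples, ",")[[1L]])))
            if (b$start < a$start || (b$start == a$start && b$end < a$end)) {
              tmp <- a; a <- b; b <- tmp  # canonical order for dedup
            }
            push(event_type = if (plus) type_plus else type_minus,
                 gene_id = m$gene_id, chrom = m$gene$chrom,
                 strand = m$gene$strand,
                 j1_start = a$start, j1_end = a$end,
                 j2_start = b$start, j2_end = b$end,
                 exon_start = NA_integer_, exon_end = NA_integer_,
                 n_samples = length(samp), max_support = max(a$max_count, b$max_count),
                 samples = paste(samp, collapse = ","))
          }
        }
      }
      # junctions sharing the end coordinate differ on the start (left) side:
      # left side is the donor on +, the acceptor on -
      pair_events("end", "start", "A5SS", "A3SS")
      pair_events("start", "end", "A3SS", "A5SS")
    }
    # --- ES: skipping junction containing an annotated exon
    skip <- jj[contains_exon, , drop = FALSE]
    for (k in seq_len(nrow(skip))) {
      inside <- which(skip$start[k] < ex_all[, "start"] &
                      skip$end[k] > ex_all[, "end"])
      for (e in inside) {
        if (require_inclusion) {
          left_ok <- any(jj$end == ex_all[e, "start"] - 1L)
          right_ok <- any(jj$start == ex_all[e, "end"] + 1L)
          if (!(left_ok && right_ok)) next
        }
        push(event_type = "ES", gene_id = m$gene_id, chrom = m$gene$chrom,
             strand = m$gene$strand,
             j1_start = skip$start[k], j1_end = skip$end[k],
             j2_start = NA_integer_, j2_end = NA_integer_,
             exon_start = ex_all[e, "start"], exon_end = ex_all[e, "end"],
             n_samples = as.integer(skip$n_samples[k]),
             max_support = skip$max_count[k], samples = skip$samples[k])
      }
    }
  }
  if (length(events) == 0L) return(.empty_events())
  out <- do.call(rbind, events)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Intron-retention thresholds
#'
#' The four-gate IR rule: mean per-bin coverage above `t1`, per-bin
#' coverage SD below `t2`, CDS expression above `t3`, and
#' intron-coverage-to-CDS-expression ratio above `t4` (all strict).
#'
#' @param t1,t2,t3,t4 Gate values (defaults 30, 20, 200, 0.1).
#' @param bin_size Intron bin width in bp (default 8).
#' @return List of class `ir_thresholds`.
#' @export
ir_thresholds <- function(t1 = 30, t2 = 20, t3 = 200, t4 = 0.1, bin_size = 8L) {
  stopifnot(t1 > 0, t2 > 0, t3 > 0, t4 > 0, bin_size >= 1L)
  structure(list(t1 = t1, t2 = t2, t3 = t3, t4 = t4,
                 bin_size = as.integer(bin_size)),
            class = "ir_thresholds")
}

#' Call intron retention from binned intron coverage
#'
#' Per (intron, sample): the intron is segmented into consecutive
#' `bin_size`-bp bins (final partial bin included by default); with M the
#' mean per-bin coverage, S the population SD of per-bin coverages and E
#' the CDS read count, the intron is called retained iff `M > t1`,
#' `S < t2`, `E > t3` and `M / Enorm > t4`, all strict.  `Enorm` is the
#' CDS expression normalization: with `ratio_mode = "scaled"` (default)
#' `Enorm = E * read_length / CDS_length` (mean per-base CDS coverage,
#' making the ratio length-invariant); `"raw-count"` uses the raw count E
#' as the denominator.
#'
#' @param genes Named list of [gene_record()] (introns taken from the
#'   annotation).
#' @param coverage Named list `sample_id -> coverage_track`.
#' @param counts Count matrix (genes x samples) of CDS read counts.
#' @param thr An [ir_thresholds()] object.
#' @param ratio_mode `"scaled"` or `"raw-count"` (see above).
#' @param read_length Read length used by the scaled mode (default 100).
#' @param include_partial Include the final partial bin (default `TRUE`).
#' @return Long `data.frame`, one row per (gene, intron, sample), with the
#'   four metrics and a logical `retained`.
#' @export
call_intron_retention <- function(genes, coverage, counts,
                                  thr = ir_thresholds(),
                                  ratio_mode = c("scaled", "raw-count"),
                                  read_length = 100, include_partial = TRUE) {
  ratio_mode <- match.arg(ratio_mode)
  rows <- list()
  for (g in genes) {
    if (nrow(g$introns) == 0L) next
    cds_len <- sum(pmin(g$exons[, "end"], g$cds_end) -
                   pmax(g$exons[, "start"], g$cds_start) + 1L)
    for (s in names(coverage)) {
      E <- if (g$gene_id %in% rownames(counts) && s %in% colnames(counts))
        counts[g$gene_id, s] else 0
      enorm <- if (ratio_mode == "scaled") E * read_length / cds_len else E
      for (j in seq_len(nrow(g$introns))) {
        b <- bin_means(coverage[[s]], g$chrom, g$introns[j, "start"],
                       g$introns[j, "end"], thr$bin_size,
                       include_partial = include_partial)
        M <- mean(b); S <- pop_sd(b)
        ratio <- if (enorm > 0) M / enorm else Inf
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g$gene_id, intron_index = j,
          chrom = g$chrom, start = g$introns[j, "start"],
          end = g$introns[j, "end"], strand = g$strand,
          sample_id = s, mean_bin_cov = M, sd_bin_cov = S,
          cds_count = E, ratio = ratio,
          retained = M > thr$t1 & S < thr$t2 & E > thr$t3 & ratio > thr$t4,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), intron_index = integer(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), sample_id = character(0),
                      mean_bin_cov = numeric(0), sd_bin_cov = numeric(0),
                      cds_count = numeric(0), ratio = numeric(0),
                      retained = logical(0))
  rownames(out) <- NULL
  out
}

#' Collapse per-sample IR calls to one event per retained intron
#'
#' @param ir_calls Output of [call_intron_retention()].
#' @return `data.frame` with one row per intron retained in at least one
#'   sample (`event_type = "IR"`, retained sample set, sample count).
#' @export
ir_events <- function(ir_calls) {
  r <- ir_calls[ir_calls$retained, , drop = FALSE]
  if (nrow(r) == 0L)
    return(data.frame(event_type = character(0), gene_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      n_samples = integer(0), samples = character(0),
                      stringsAsFactors = FALSE))
  key <- paste(r$gene_id, r$intron_index)
  out <- do.call(rbind, lapply(split(seq_len(nrow(r)), key), function(idx) {
    x <- r[idx, , drop = FALSE]
    data.frame(event_type = "IR", gene_id = x$gene_id[1L], chrom = x$chrom[1L],
               strand = x$strand[1L], start = x$start[1L], end = x$end[1L],
               n_samples = length(unique(x$sample_id)),
               samples = paste(sort(unique(x$sample_id)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene_id, out$start), , drop = FALSE]
}

#' Per-type and combination counts of alternative splicing events
#'
#' A gene is counted once per event type; combination counts (upset-style)
#' record the exact set of types seen per gene.
#'
#' @param events `data.frame` with columns `event_type` and `gene_id`
#'   (junction events and [ir_events()] rows can be row-bound after
#'   aligning columns, or passed concatenated via `rbind_events()`).
#' @return List of class `ase_summary`: `genes_per_type`, `n_genes_any`,
#'   `combinations` table.
#' @export
summarize_ase <- function(events) {
  types <- c("A5SS", "A3SS", "ES", "IR")
  if (nrow(events) == 0L) {
    return(structure(list(
      genes_per_type = setNames(rep(0L, length(types)), types),
      n_genes_any = 0L, combinations = table(character(0))),
      class = "ase_summary"))
  }
  per_gene <- lapply(split(events$event_type, events$gene_id),
                     function(x) sort(unique(x)))
  genes_per_type <- vapply(types, function(t)
    sum(vapply(per_gene, function(s) t %in% s, TRUE)), 1L)
  combos <- table(vapply(per_gene, paste, "", collapse = "+"))
  structure(list(genes_per_type = genes_per_type,
                 n_genes_any = length(per_gene),
                 combinations = combos),
            class = "ase_summary")
}

#' Row-bind junction events and IR events into one event table
#' @param junction_events Output of [classify_junction_events()].
#' @param ir_ev Output of [ir_events()].
#' @return `data.frame` with at least `event_type` and `gene_id`.
#' @export
rbind_events <- function(junction_events, ir_ev) {
  a <- junction_events[, c("event_type", "gene_id"), drop = FALSE]
  b <- ir_ev[, c("event_type", "gene_id"), drop = FALSE]
  rbind(a, b)
}

#' @export
print.ase_summary <- function(x, ...) {
  cat(sprintf("ASE summary: %d genes with >= 1 event\n", x$n_genes_any))
  print(x$genes_per_type)
  cat("Type combinations:\n"); print(x$combinations)
  invisible(x)
}
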