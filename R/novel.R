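#' Detect novel transcriptionally active regions (nTARs)
#'
#' Unassigned predictions with average coverage of at least `min_cov`
#' (inclusive) are partitioned by overlap with the supplied annotation:
#' `overlap_class = "none"` (no intersection with any annotated feature;
#' these are the nTARs proper, ready for [merge_nested()]) or
#' `"partial_gene"` (intersects an annotated feature without having been
#' assignable to a gene).
#'
#' @param unassigned A [prediction_table()] (the unassigned pool from
#'   [assign_predictions()]).
#' @param features `data.frame` of annotated features with columns
#'   `chrom`, `start`, `end` (any feature type present in the annotation:
#'   CDS, UTRs, pseudogenes, repeats, rRNA ...).  Use
#'   [gene_features()] to derive it from gene records.
#' @param min_cov Inclusive coverage floor (default 10).
#' @return `data.frame` of candidate novel transcripts with columns
#'   `ntar_id`, `chrom`, `strand`, `start`, `end`, `avg_coverage`,
#'   `overlap_class`, `source_samples`.
#' @export
detect_ntars <- function(unassigned, features, min_cov = 10) {
  keep <- unassigned$avg_coverage >= min_cov
  p <- unassigned[keep, , drop = FALSE]
  if (nrow(p) == 0L)
    return(data.frame(ntar_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), avg_coverage = numeric(0),
                      overlap_class = character(0), source_samples = character(0),
                      stringsAsFactors = FALSE))
  pgr <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start, p$end))
  fgr <- GenomicRanges::GRanges(features$chrom,
                                IRanges::IRanges(features$start, features$end))
  hits <- GenomicRanges::countOverlaps(pgr, fgr, ignore.strand = TRUE)
  data.frame(ntar_id = sprintf("nTAR%05d", seq_len(nrow(p))),
             chrom = p$chrom, strand = p$strand,
             start = p$start, end = p$end,
             avg_coverage = p$avg_coverage,
             overlap_class = ifelse(hits == 0L, "none", "partial_gene"),
             source_samples = p$sample_id,
             stringsAsFactors = FALSE)
}

#' Annotated feature intervals from gene records
#'
#' @param genes Named list of [gene_record()].
#' @param what `"cds"` (CDS spans) or `"span"` (full exon spans).
#' @return `data.frame` with `chrom`, `start`, `end`, `strand`, `gene_id`.
#' @export
gene_features <- function(genes, what = c("cds", "span")) {
  what <- match.arg(what)
  data.frame(
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, function(g)
      if (what == "cds") g$cds_start else min(g$exons[, "start"]), 1L),
    end = vapply(genes, function(g)
      if (what == "cds") g$cds_end else max(g$exons[, "end"]), 1L),
    strand = vapply(genes, `[[`, "", "strand"),
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Merge nested and overlapping nTAR intervals
#'
#' Overlapping intervals on the same chromosome (and strand, for stranded
#' records; unstranded `"."` records are merged per chromosome ignoring
#' strand) collapse to one interval whose coverage is the maximum and
#' whose source-sample set is the union of its members.  Idempotent;
#' output intervals are pairwise non-overlapping.
#'
#' @param ntars Output of [detect_ntars()] (typically the
#'   `overlap_class == "none"` rows).
#' @param respect_strand Merge per strand (default `TRUE`; records with
#'   strand `"."` always merge per chromosome only).
#' @return Merged `data.frame` in the same shape, plus `n_members`.
#' @export
merge_nested <- function(ntars, respect_strand = TRUE) {
  if (nrow(ntars) == 0L) { ntars$n_members <- integer(0); return(ntars) }
  grp_strand <- if (respect_strand) ifelse(ntars$strand == ".", ".", ntars$strand)
                else "."
  key <- paste(ntars$chrom, grp_strand)
  out <- list()
  for (k in unique(key)) {
    x <- ntars[key == k, , drop = FALSE]
    ir <- IRanges::IRanges(x$start, x$end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(ov)
    for (g in seq_along(red)) {
      mem <- which(grp == g)
      out[[length(out) + 1L]] <- data.frame(
        chrom = x$chrom[1L],
        strand = if (length(unique(x$strand[mem])) == 1L) x$strand[mem][1L] else ".",
        start = IRanges::start(red)[g], end = IRanges::end(red)[g],
        avg_coverage = max(x$avg_coverage[mem]),
        overlap_class = x$overlap_class[mem][1L],
        source_samples = paste(sort(unique(unlist(
          strsplit(x$source_samples[mem], ",")))), collapse = ","),
        n_members = length(mem),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$ntar_id <- sprintf("nTAR%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("ntar_id", "chrom", "strand", "start", "end", "avg_coverage",
          "overlap_class", "source_samples", "n_members")]
}

#' Flag spliced nTARs by contained junctions
#'
#' `spliced = TRUE` iff at least one junction lies fully within the nTAR
#' interval (strand-compatible when both are stranded).
#'
#' @param ntars nTAR `data.frame` (merged or not).
#' @param junctions A [junction_table()].
#' @return `ntars` with a logical `spliced` column.
#' @export
flag_spliced <- function(ntars, junctions) {
  if (nrow(ntars) == 0L) { ntars$spliced <- logical(0); return(ntars) }
  spliced <- vapply(seq_len(nrow(ntars)), function(i) {
    j <- junctions[junctions$chrom == ntars$chrom[i] &
                   junctions$start >= ntars$start[i] &
                   junctions$end <= ntars$end[i], , drop = FALSE]
    if (nrow(j) == 0L) return(FALSE)
    any(j$strand == "." | ntars$strand[i] == "." | j$strand == ntars$strand[i])
  }, TRUE)
  ntars$spliced <- spliced
  ntars
}

#' Detect noncoding antisense transcripts (NATs)
#'
#' A stranded prediction is a NAT iff its span intersects (entirely or
#' partially) exactly one annotated CDS and its strand is the opposite of
#' that gene's strand.  Unstranded predictions are rejected: antisense
#' calling requires a strand-specific library.
#'
#' @param stranded_preds A [prediction_table()] from stranded samples.
#' @param genes Named list of [gene_record()].
#' @param min_cov Coverage floor (default 10); set to 0 to disable.
#' @return `data.frame` of NATs with `linked_gene` and provenance.
#' @export
detect_nats <- function(stranded_preds, genes, min_cov = 10) {
  if (any(stranded_preds$strand == "."))
    stop("NAT detection requires stranded predictions; found strand '.' ",
         "(supply transcripts from a strand-specific library)")
  p <- stranded_preds[stranded_preds$avg_coverage >= min_cov, , drop = FALSE]
  empty <- data.frame(nat_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0), end = integer(0),
                      avg_coverage = numeric(0), linked_gene = character(0),
                      gene_strand = character(0), source_samples = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(p) == 0L) return(empty)
  feats <- gene_features(genes, "cds")
  pgr <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start, p$end))
  fgr <- GenomicRanges::GRanges(feats$chrom, IRanges::IRanges(feats$start, feats$end))
  ov <- GenomicRanges::findOverlaps(pgr, fgr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  nhit <- tabulate(qh, nbins = nrow(p))
  rows <- list()
  for (i in which(nhit == 1L)) {
    g <- sh[qh == i]
    if (feats$strand[g] %in% c("+", "-") &&
        p$strand[i] == .opposite_strand(feats$strand[g])) {
      rows[[length(rows) + 1L]] <- data.frame(
        nat_id = NA_character_, chrom = p$chrom[i], strand = p$strand[i],
        start = p$start[i], end = p$end[i], avg_coverage = p$avg_coverage[i],
        linked_gene = feats$gene_id[g], gene_strand = feats$strand[g],
        source_samples = p$sample_id[i], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$nat_id <- sprintf("NAT%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Length-distribution summary of novel transcripts
#'
#' @param ntars nTAR `data.frame` (a `spliced` column is used when present).
#' @param short_bp Threshold for the "short" fraction (default 500).
#' @param breaks Histogram bin width in bp (default 250).
#' @return List of class `ntar_size_report`: n, mean/median length,
#'   fraction below `short_bp`, spliced fraction and per-flag stats, and a
#'   histogram table.
#' @export
size_report <- function(ntars, short_bp = 500, breaks = 250) {
  len <- if (nrow(ntars)) ntars$end - ntars$start + 1L else integer(0)
  spliced <- if ("spliced" %in% names(ntars)) ntars$spliced else rep(NA, nrow(ntars))
  hist_tbl <- if (length(len)) {
    bins <- floor((len - 1) / breaks) * breaks
    as.data.frame(table(bin_start = bins + 1), stringsAsFactors = FALSE)
  } else data.frame(bin_start = character(0), Freq = integer(0))
  bylen <- function(sel) {
    x <- len[sel]
    if (!length(x)) c(n = 0, mean = NA_real_, median = NA_real_)
    else c(n = length(x), mean = mean(x), median = median(x))
  }
  structure(list(
    n = length(len),
    mean_length = if (length(len)) mean(len) else NA_real_,
    median_length = if (length(len)) median(len) else NA_real_,
    fraction_short = if (length(len)) mean(len < short_bp) else NA_real_,
    short_bp = short_bp,
    spliced_fraction = if (length(len) && !all(is.na(spliced)))
      mean(spliced, na.rm = TRUE) else NA_real_,
    spliced_stats = bylen(!is.na(spliced) & spliced),
    unspliced_stats = bylen(!is.na(spliced) & !spliced),
    histogram = hist_tbl
  ), class = "ntar_size_report")
}

#' @export
print.ntar_size_report <- function(x, ...) {
  cat(sprintf("nTAR size report: n=%d, mean %.0f bp, median %.0f bp, %.1f%% < %d bp",
              x$n, x$mean_length, x$median_length, 100 * x$fraction_short,
              x$short_bp))
  if (!is.na(x$spliced_fraction))
    cat(sprintf(", spliced fraction %.2f", x$spliced_fraction))
  cat("\n")
  invisible(x)
}
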