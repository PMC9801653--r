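#' Build a transcript-prediction table
#'
#' One row per assembled transcript from one sample.  `exons` is a list
#' column of 2-column (start, end) matrices; `start`/`end` are forced to the
#' first/last exon boundary.
#'
#' @param transcript_id,chrom,strand,sample_id,dataset_id Character vectors.
#' @param avg_coverage Numeric vector, mean reads per base over the transcript.
#' @param exons List of exon matrices (one per transcript).
#' @return A `data.frame` with class `prediction_table`.
#' @export
prediction_table <- function(transcript_id, chrom, strand, avg_coverage,
                             exons, sample_id, dataset_id) {
  exons <- lapply(exons, function(e) exon_matrix(e[, 1L], e[, 2L]))
  if (any(vapply(exons, nrow, 1L) == 0L))
    stop("transcript without exons")
  if (any(avg_coverage < 0)) stop("avg_coverage must be >= 0")
  df <- data.frame(transcript_id = as.character(transcript_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = vapply(exons, function(e) min(e[, "start"]), 1L),
                   end = vapply(exons, function(e) max(e[, "end"]), 1L),
                   avg_coverage = as.numeric(avg_coverage),
                   sample_id = as.character(sample_id),
                   dataset_id = as.character(dataset_id),
                   stringsAsFactors = FALSE)
  df$exons <- exons
  class(df) <- c("prediction_table", "data.frame")
  df
}

empty_prediction_table <- function() {
  prediction_table(character(0), character(0), character(0), numeric(0),
                   list(), character(0), character(0))
}

#' Read per-sample transcript predictions from an assembler GTF
#'
#' Consumes the GTF dialect written by reference-guided assemblers
#' (StringTie-style): `transcript` features carrying a numeric per-transcript
#' coverage attribute, plus `exon` features sharing the `transcript_id`.
#'
#' @param path GTF file.
#' @param sample_id,dataset_id Provenance labels attached to every transcript.
#' @param coverage_attr Name of the coverage attribute (default `"cov"`).
#' @param coverage_track Optional [coverage_track()] used to compute the mean
#'   per-base coverage over the exon chain when the attribute is absent.
#' @return A [prediction_table()].  An empty file yields an empty table; no
#'   coverage filtering is applied here.
#' @export
read_predictions <- function(path, sample_id, dataset_id,
                             coverage_attr = "cov", coverage_track = NULL) {
  if (file.size(path) %in% c(0L, NA)) return(empty_prediction_table())
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) .stop_io(path, paste("GTF parse error:",
                                                          conditionMessage(e))))
  if (length(gr) == 0L) return(empty_prediction_table())
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  tid <- as.character(mc$transcript_id)
  is_ex <- type == "exon"
  is_tx <- type == "transcript"
  tx_ids <- unique(tid[is_tx | is_ex])
  tx_ids <- tx_ids[!is.na(tx_ids)]
  cov_by_tx <- setNames(rep(NA_real_, length(tx_ids)), tx_ids)
  if (coverage_attr %in% names(mc)) {
    cv <- suppressWarnings(as.numeric(as.character(mc[[coverage_attr]])))
    got <- is_tx & !is.na(cv)
    cov_by_tx[tid[got]] <- cv[got]
  }
  strand_chr <- as.character(GenomicRanges::strand(gr))
  strand_chr[strand_chr == "*"] <- "."
  exl <- list(); chroms <- character(0); strands <- character(0)
  for (i in seq_along(tx_ids)) {
    t <- tx_ids[i]
    sel <- which(is_ex & tid == t)
    if (length(sel) == 0L) {
      sel_tx <- which(is_tx & tid == t)  # single-exon transcript w/o exon rows
      if (length(sel_tx) == 0L)
        .stop_io(path, sprintf("transcript %s has no exons", t))
      sel <- sel_tx
    }
    exl[[i]] <- cbind(GenomicRanges::start(gr)[sel], GenomicRanges::end(gr)[sel])
    chroms[i] <- as.character(GenomicRanges::seqnames(gr))[sel[1L]]
    strands[i] <- strand_chr[sel[1L]]
  }
  missing_cov <- is.na(cov_by_tx)
  if (any(missing_cov)) {
    if (is.null(coverage_track))
      .stop_io(path, sprintf(
        "transcript %s lacks a '%s' coverage attribute and no coverage track was supplied",
        tx_ids[which(missing_cov)[1L]], coverage_attr))
    for (i in which(missing_cov)) {
      e <- exl[[i]]
      vals <- unlist(lapply(seq_len(nrow(e)), function(k)
        track_values(coverage_track, chroms[i], e[k, 1L], e[k, 2L])))
      cov_by_tx[i] <- mean(vals)
    }
  }
  prediction_table(tx_ids, chroms, strands, unname(cov_by_tx), exl,
                   sample_id, dataset_id)
}

#' Write a prediction table as a StringTie-style GTF
#'
#' @param preds A [prediction_table()] (one sample per file by convention).
#' @param path Output GTF path.
#' @param coverage_attr Attribute name for the per-transcript coverage.
#' @export
write_predictions <- function(preds, path, coverage_attr = "cov") {
  con <- file(path, "w")
  on.exit(close(con))
  fmt_attr <- function(tid, cov = NULL) {
    a <- sprintf('gene_id "%s"; transcript_id "%s";', tid, tid)
    if (!is.null(cov)) a <- sprintf('%s %s "%s";', a, coverage_attr, format(cov, scientific = FALSE))
    a
  }
  for (i in seq_len(nrow(preds))) {
    e <- preds$exons[[i]]
    lines <- c(
      paste(preds$chrom[i], "scvannotate", "transcript", preds$start[i], preds$end[i],
            "1000", preds$strand[i], ".",
            fmt_attr(preds$transcript_id[i], preds$avg_coverage[i]), sep = "\t"),
      paste(preds$chrom[i], "scvannotate", "exon", e[, "start"], e[, "end"],
            "1000", preds$strand[i], ".",
            fmt_attr(preds$transcript_id[i]), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}
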