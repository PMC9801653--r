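#' Construct a per-base coverage track
#'
#' Coverage is held as one run-length encoded vector per chromosome
#' (1-based indexing: element i is the coverage of base i).
#'
#' @param values Named list mapping chromosome to a numeric vector or
#'   [S4Vectors::Rle] of per-base coverage (all values >= 0).
#' @param sample_id Sample label.
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(values, sample_id) {
  if (is.null(names(values)) || any(names(values) == ""))
    stop("coverage values must be a named list (chromosome -> vector)")
  values <- lapply(values, function(v) {
    r <- if (is(v, "Rle")) v else S4Vectors::Rle(as.numeric(v))
    rv <- S4Vectors::runValue(r)
    if (any(rv < 0 & rv > -1e-6)) {  # epsilon dust from weighted-coverage sums
      rv[rv < 0 & rv > -1e-6] <- 0
      S4Vectors::runValue(r) <- rv
    }
    if (any(S4Vectors::runValue(r) < 0))
      stop(sprintf("coverage values must be >= 0 (min %g)",
                   min(S4Vectors::runValue(r))))
    r
  })
  structure(list(values = values, sample_id = as.character(sample_id)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> sample %s, %d chromosome(s): %s\n",
              x$sample_id, length(x$values),
              paste(sprintf("%s(%d bp)", names(x$values),
                            vapply(x$values, length, 1L)), collapse = ", ")))
  invisible(x)
}

# per-base values over [start, end] (clamped to chromosome bounds)
track_values <- function(track, chrom, start, end) {
  r <- track$values[[chrom]]
  if (is.null(r)) stop(sprintf("chromosome %s absent from coverage track", chrom))
  start <- max(1L, start); end <- min(length(r), end)
  if (start > end) return(numeric(0))
  as.numeric(S4Vectors::window(r, start, end))
}

#' Per-bin mean coverage over an interval
#'
#' Segments `[start, end]` into consecutive `bin_size`-bp bins (the final
#' partial bin is included by default) and returns the mean per-base
#' coverage of each bin.
#'
#' @param track A [coverage_track()].
#' @param chrom,start,end Interval (1-based inclusive).
#' @param bin_size Bin width in bp.
#' @param include_partial Keep the final partial bin (default `TRUE`).
#' @return Numeric vector of per-bin means.
#' @export
bin_means <- function(track, chrom, start, end, bin_size, include_partial = TRUE) {
  r <- track$values[[chrom]]
  if (is.null(r)) stop(sprintf("chromosome %s absent from coverage track", chrom))
  starts <- seq.int(start, end, by = bin_size)
  ends <- pmin(starts + bin_size - 1L, end)
  if (!include_partial && length(starts) > 1L) {
    full <- (ends - starts + 1L) == bin_size
    if (!full[length(full)]) { starts <- starts[-length(starts)]; ends <- ends[-length(ends)] }
  }
  v <- IRanges::Views(r, IRanges::IRanges(starts, ends))
  as.numeric(IRanges::viewMeans(v))
}

#' Read a bedGraph coverage file into a coverage track
#'
#' @param path bedGraph file (0-based half-open intervals on disk).
#' @param sample_id Sample label.
#' @param seqlengths Optional named integer vector of chromosome lengths;
#'   defaults to the right-most covered base per chromosome.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, sample_id, seqlengths = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) .stop_io(path, paste("bedGraph parse error:",
                                                          conditionMessage(e))))
  if (!is.null(seqlengths)) {
    gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                 GenomicRanges::ranges(gr),
                                 score = S4Vectors::mcols(gr)$score,
                                 seqlengths = seqlengths)
    cov <- GenomicRanges::coverage(gr, weight = "score")
  } else {
    cov <- GenomicRanges::coverage(gr, weight = "score")
  }
  coverage_track(as.list(cov), sample_id)
}

#' Write a coverage track as bedGraph
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  rl <- methods::as(track$values, "SimpleRleList")
  gr <- methods::as(rl, "GRanges")
  gr <- gr[S4Vectors::mcols(gr)$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a feature-by-sample count table from TSV
#'
#' First column = feature id, remaining columns = per-sample non-negative
#' integer read counts.
#'
#' @param path TSV file with header.
#' @return Numeric matrix, feature ids as rownames.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "numeric"
  if (any(m < 0)) .stop_io(path, "negative read count")
  m
}

#' Write a count matrix as TSV
#' @param counts Matrix with feature rownames.
#' @param path Output path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
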