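#' Build a junction table
#'
#' Long form: one row per (junction, sample).  `start`/`end` are the first
#' and last intronic base of the junction, 1-based inclusive.
#'
#' @param chrom,strand,sample_id Character vectors.
#' @param start,end Integer vectors, `start <= end`.
#' @param count Non-negative read support per sample.
#' @return `data.frame` with class `junction_table`.
#' @export
junction_table <- function(chrom, start, end, strand, count, sample_id) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("junction start (donor-side) must be < end")
  if (any(count < 0)) stop("junction support must be >= 0")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   strand = as.character(strand), count = as.numeric(count),
                   sample_id = as.character(sample_id), stringsAsFactors = FALSE)
  class(df) <- c("junction_table", "data.frame")
  df
}

#' Read an exon-exon junction file (BED6 or BED12)
#'
#' BED6: the interval is the intron itself (0-based half-open on disk,
#' converted to 1-based inclusive in memory); `score` is the read support.
#' BED12 (TopHat `junctions.bed` dialect): the two blocks are the flanking
#' exon anchors and the intron is derived from the gap between them.
#'
#' @param path BED file.
#' @param sample_id Sample label attached to every junction.
#' @return A [junction_table()].
#' @export
read_junctions <- function(path, sample_id) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) .stop_io(path, paste("BED parse error:",
                                                          conditionMessage(e))))
  if (length(gr) == 0L)
    return(junction_table(character(0), integer(0), integer(0),
                          character(0), numeric(0), character(0)))
  mc <- S4Vectors::mcols(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  score <- if ("score" %in% names(mc)) as.numeric(mc$score) else rep(0, length(gr))
  if ("blocks" %in% names(mc) && !is.null(mc$blocks) &&
      all(lengths(mc$blocks) >= 2L)) {
    b <- mc$blocks
    s <- GenomicRanges::start(gr)
    istart <- s + vapply(as.list(b), function(x) IRanges::end(x)[1L], 1L)
    iend <- s + vapply(as.list(b), function(x) IRanges::start(x)[2L], 1L) - 2L
  } else {
    istart <- GenomicRanges::start(gr)
    iend <- GenomicRanges::end(gr)
  }
  junction_table(as.character(GenomicRanges::seqnames(gr)), istart, iend,
                 strand, score, sample_id)
}

#' Write a junction table as BED6 (intron intervals, 0-based half-open)
#'
#' @param junctions A [junction_table()].
#' @param path Output BED path.
#' @export
write_junctions <- function(junctions, path) {
  gr <- GenomicRanges::GRanges(
    junctions$chrom, IRanges::IRanges(junctions$start, junctions$end),
    strand = ifelse(junctions$strand == ".", "*", junctions$strand))
  S4Vectors::mcols(gr)$name <- sprintf("JUNC%05d", seq_along(gr))
  S4Vectors::mcols(gr)$score <- junctions$count
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

# Aggregate a long junction table to one row per distinct junction with
# sample multiplicity and maximum per-sample support.
aggregate_junctions <- function(junctions) {
  if (nrow(junctions) == 0L)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), n_samples = integer(0),
                      max_count = numeric(0), samples = character(0),
                      stringsAsFactors = FALSE))
  key <- paste(junctions$chrom, junctions$start, junctions$end,
               junctions$strand, sep = "\r")
  sp <- split(seq_len(nrow(junctions)), key)
  out <- lapply(sp, function(idx) {
    j <- junctions[idx, , drop = FALSE]
    data.frame(chrom = j$chrom[1L], start = j$start[1L], end = j$end[1L],
               strand = j$strand[1L],
               n_samples = length(unique(j$sample_id)),
               max_count = max(j$count),
               samples = paste(sort(unique(j$sample_id)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}
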