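#' @importFrom methods as is
#' @importFrom stats rexp rnorm rpois runif median setNames
#' @importFrom utils head read.delim write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# interval [a1,a2] fully contains [b1,b2]; all coordinates 1-based inclusive
.contains <- function(a1, a2, b1, b2) a1 <= b1 & a2 >= b2

# [a1,a2] and [b1,b2] intersect
.intersects <- function(a1, a2, b1, b2) a1 <= b2 & a2 >= b1

# population standard deviation (divide by n)
pop_sd <- function(x) {
  if (length(x) <= 1L) return(0)
  sqrt(mean((x - mean(x))^2))
}

# strand compatibility: "." matches anything
.strand_compatible <- function(pred_strand, gene_strand) {
  pred_strand == "." | pred_strand == gene_strand
}

.opposite_strand <- function(s) {
  out <- s
  out[s == "+"] <- "-"
  out[s == "-"] <- "+"
  out
}

# exon matrix helper: 2-column integer matrix with columns start, end
exon_matrix <- function(starts, ends = NULL) {
  if (is.null(ends)) {
    m <- matrix(as.integer(starts), ncol = 2L, byrow = TRUE)
  } else {
    m <- cbind(as.integer(starts), as.integer(ends))
  }
  colnames(m) <- c("start", "end")
  if (nrow(m) > 0L) {
    m <- m[order(m[, "start"]), , drop = FALSE]
    if (any(m[, "end"] < m[, "start"]))
      stop("exon end before exon start")
    if (nrow(m) > 1L && any(m[-1L, "start"] <= m[-nrow(m), "end"]))
      stop("exons overlap or touch")
  }
  m
}

# gaps between consecutive exons, 1-based inclusive
intron_gaps <- function(exons) {
  n <- nrow(exons)
  if (n < 2L) {
    m <- matrix(integer(0), ncol = 2L)
  } else {
    m <- cbind(exons[-n, "end"] + 1L, exons[-1L, "start"] - 1L)
  }
  colnames(m) <- c("start", "end")
  m
}

.stop_io <- function(path, msg) {
  stop(sprintf("%s [file: %s]", msg, path), call. = FALSE)
}
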