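#' Construct a gene record
#'
#' A gene record anchors every downstream step: it carries the CDS span,
#' the exon chain and the derived introns of one annotated gene.  All
#' coordinates are 1-based inclusive.
#'
#' @param gene_id Gene identifier (unique within an annotation).
#' @param chrom Chromosome name.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @param cds_start,cds_end CDS span, 1-based inclusive, `cds_start <= cds_end`.
#' @param exons Two-column matrix (start, end) of exon intervals, or a
#'   `data.frame` with `start`/`end` columns.  Must be non-overlapping.
#' @return An object of class `gene_record` with derived `introns`.
#' @export
gene_record <- function(gene_id, chrom, strand, cds_start, cds_end, exons) {
  stopifnot(length(gene_id) == 1L, length(chrom) == 1L)
  if (!strand %in% c("+", "-", "."))
    stop("strand must be one of '+', '-', '.'")
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_start > cds_end)
    stop(sprintf("gene %s: cds_start > cds_end", gene_id))
  if (is.data.frame(exons)) exons <- cbind(start = exons$start, end = exons$end)
  exons <- exon_matrix(exons[, 1L], exons[, 2L])
  if (nrow(exons) == 0L)
    stop(sprintf("gene %s has zero exons", gene_id))
  introns <- intron_gaps(exons)
  structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = strand, cds_start = cds_start, cds_end = cds_end,
         exons = exons, introns = introns),
    class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s %s:%d-%d(%s), %d exon(s), %d intron(s)\n",
              x$gene_id, x$chrom, x$cds_start, x$cds_end, x$strand,
              nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

# Resolve a gene id for each feature of an imported GFF/GTF GRanges:
# prefer a gene_id attribute, else walk Parent links up to a gene feature.
.resolve_gene_ids <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  n <- length(gr)
  gid <- rep(NA_character_, n)
  if ("gene_id" %in% names(mc)) gid <- as.character(mc$gene_id)
  need <- is.na(gid)
  if (any(need) && all(c("ID", "Parent") %in% names(mc))) {
    ids <- as.character(mc$ID)
    parent <- vapply(as.list(mc$Parent), function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
    type <- as.character(mc$type)
    id2type <- setNames(type, ids)
    id2parent <- setNames(parent, ids)
    resolve <- function(node) {
      seen <- character(0)
      while (!is.na(node) && !node %in% seen) {
        if (!is.na(id2type[node]) && id2type[node] == "gene") return(node)
        seen <- c(seen, node)
        nxt <- id2parent[node]
        if (is.na(nxt)) return(node)  # top-most ancestor stands in for the gene
        node <- nxt
      }
      node
    }
    anchor <- ifelse(is.na(parent), ids, parent)
    gid[need] <- vapply(anchor[need], resolve, character(1))
  }
  gid
}

#' Read a reference annotation (GFF3 or GTF) into gene records
#'
#' CDS features define the CDS span; exon features (when present) define the
#' exon chain, otherwise the CDS features do.  Gene identifiers are taken
#' from a `gene_id` attribute when present, or resolved through `Parent`
#' links.  Input coordinates (1-based inclusive) are preserved.
#'
#' @param path GFF3 or GTF file.
#' @return Named list of [gene_record()] objects.
#' @export
read_annotation <- function(path) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) .stop_io(path, paste("annotation parse error:",
                                                          conditionMessage(e))))
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  gid <- .resolve_gene_ids(gr)
  keep <- type %in% c("exon", "CDS")
  if (!any(keep)) .stop_io(path, "annotation contains no exon or CDS features")
  df <- data.frame(gene_id = gid[keep],
                   chrom = as.character(GenomicRanges::seqnames(gr))[keep],
                   strand = as.character(GenomicRanges::strand(gr))[keep],
                   start = GenomicRanges::start(gr)[keep],
                   end = GenomicRanges::end(gr)[keep],
                   type = type[keep], stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  if (anyNA(df$gene_id))
    .stop_io(path, "exon/CDS feature without resolvable gene identifier")
  genes <- list()
  for (g in unique(df$gene_id)) {
    sub <- df[df$gene_id == g, , drop = FALSE]
    if (length(unique(sub$chrom)) > 1L)
      .stop_io(path, sprintf("gene %s appears on multiple chromosomes", g))
    ex <- sub[sub$type == "exon", , drop = FALSE]
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) ex <- cds
    if (nrow(ex) == 0L)
      .stop_io(path, sprintf("gene %s has zero exons", g))
    if (nrow(cds) == 0L) cds <- ex
    ex <- unique(ex[, c("start", "end")])
    genes[[g]] <- gene_record(
      gene_id = g, chrom = sub$chrom[1L], strand = sub$strand[1L],
      cds_start = min(cds$start), cds_end = max(cds$end),
      exons = as.matrix(ex))
  }
  genes
}

#' Write gene records as GFF3
#'
#' Emits one `gene` feature plus `exon` and `CDS` subfeatures per gene,
#' `gene_id` carried as an attribute.  Round-trips through
#' [read_annotation()].
#'
#' @param genes Named list of [gene_record()] objects.
#' @param path Output GFF3 path.
#' @export
write_annotation <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    ex <- g$exons
    span_start <- min(ex[, "start"]); span_end <- max(ex[, "end"])
    data.frame(
      chrom = g$chrom,
      start = unname(c(span_start, ex[, "start"], pmax(ex[, "start"], g$cds_start))),
      end = unname(c(span_end, ex[, "end"], pmin(ex[, "end"], g$cds_end))),
      type = c("gene", rep("exon", nrow(ex)), rep("CDS", nrow(ex))),
      strand = g$strand, gene_id = g$gene_id, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  # CDS pieces falling outside the CDS span collapse to invalid rows; drop them
  df <- df[df$start <= df$end, , drop = FALSE]
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = ifelse(df$strand == ".", "*", df$strand))
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$source <- "scvannotate"
  S4Vectors::mcols(gr)$ID <- ifelse(df$type == "gene", df$gene_id, NA_character_)
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$phase <- ifelse(df$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
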