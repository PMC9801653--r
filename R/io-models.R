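#' Write gene models as GFF3
#'
#' Emits, per model, one `gene` feature and one `mRNA` feature per distinct
#' (TSS, TES) boundary pair among the selected transcripts, each with
#' `exon`, `five_prime_UTR`, `CDS` and `three_prime_UTR` subfeatures.
#' Provenance is carried in aligned comma-separated attributes
#' (`transcript_ids`, `samples`, `datasets`, `coverages`); transcripts
#' sharing a boundary pair are collapsed into one mRNA (they share an exon
#' chain in this pipeline's outputs).  Round-trips through
#' [read_gene_models()].
#'
#' @param models Named list of `gene_model` objects.
#' @param path Output GFF3 path.
#' @export
write_gene_models <- function(models, path) {
  rows <- list()
  add <- function(chrom, start, end, strand, type, attrs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, strand = strand,
      type = type, attrs = attrs, stringsAsFactors = FALSE)
  }
  for (m in models) {
    g <- m$gene
    span <- range(c(m$selected$start, m$selected$end, g$cds_start, g$cds_end))
    add(g$chrom, span[1L], span[2L], g$strand, "gene",
        sprintf("ID=%s;multiplicity_class=%s;scv_threshold=%s", m$gene_id,
                m$multiplicity_class,
                format(m$threshold, scientific = FALSE, trim = TRUE)))
    key <- paste(m$selected$start, m$selected$end, sep = ":")
    k <- 0L
    for (pair in unique(key)) {
      k <- k + 1L
      idx <- which(key == pair)
      rep_i <- idx[which.max(m$selected$avg_coverage[idx])]
      mid <- sprintf("%s.m%d", m$gene_id, k)
      tx_start <- m$selected$start[rep_i]; tx_end <- m$selected$end[rep_i]
      add(g$chrom, tx_start, tx_end, g$strand, "mRNA", sprintf(
        "ID=%s;Parent=%s;transcript_ids=%s;samples=%s;datasets=%s;coverages=%s",
        mid, m$gene_id,
        paste(m$selected$transcript_id[idx], collapse = ","),
        paste(m$selected$sample_id[idx], collapse = ","),
        paste(m$selected$dataset_id[idx], collapse = ","),
        paste(format(m$selected$avg_coverage[idx], scientific = FALSE, trim = TRUE),
              collapse = ",")))
      ex <- m$selected$exons[[rep_i]]
      for (j in seq_len(nrow(ex)))
        add(g$chrom, ex[j, "start"], ex[j, "end"], g$strand, "exon",
            sprintf("ID=%s.exon%d;Parent=%s", mid, j, mid))
      plus <- g$strand != "-"
      u5 <- if (plus) c(tx_start, g$cds_start - 1L) else c(g$cds_end + 1L, tx_end)
      u3 <- if (plus) c(g$cds_end + 1L, tx_end) else c(tx_start, g$cds_start - 1L)
      if (u5[1L] <= u5[2L])
        add(g$chrom, u5[1L], u5[2L], g$strand, "five_prime_UTR",
            sprintf("ID=%s.utr5;Parent=%s", mid, mid))
      add(g$chrom, g$cds_start, g$cds_end, g$strand, "CDS",
          sprintf("ID=%s.cds;Parent=%s", mid, mid))
      if (u3[1L] <= u3[2L])
        add(g$chrom, u3[1L], u3[2L], g$strand, "three_prime_UTR",
            sprintf("ID=%s.utr3;Parent=%s", mid, mid))
    }
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(paste(df$chrom, "scvannotate", df$type, df$start, df$end, ".",
                   df$strand, ".", df$attrs, sep = "\t"), con)
  invisible(path)
}

#' Read gene models back from GFF3
#'
#' Reconstructs the `gene_model` set written by [write_gene_models()]:
#' each mRNA expands to one selected transcript per provenance entry, and
#' models are rebuilt with [build_gene_model()] so derived fields (UTRs,
#' TSS/TES sets, multiplicity class) are recomputed from the primitives.
#'
#' @param path GFF3 file produced by [write_gene_models()].
#' @param merge_bp TSS/TES merge tolerance used when rebuilding (default 0).
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(path, merge_bp = 0L) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) .stop_io(path, paste("GFF3 parse error:",
                                                          conditionMessage(e))))
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  id <- as.character(mc$ID)
  parent <- vapply(as.list(mc$Parent), function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr)); strand[strand == "*"] <- "."
  start <- GenomicRanges::start(gr); end <- GenomicRanges::end(gr)
  models <- list()
  for (gi in which(type == "gene")) {
    gid <- id[gi]
    mrna_i <- which(type == "mRNA" & parent == gid)
    if (length(mrna_i) == 0L) next
    cds_i <- which(type == "CDS" & parent == id[mrna_i[1L]])
    gene <- NULL
    tx <- list()
    for (mi in mrna_i) {
      mid <- id[mi]
      ex_i <- which(type == "exon" & parent == mid)
      exons <- exon_matrix(start[ex_i], end[ex_i])
      cds_j <- which(type == "CDS" & parent == mid)
      if (is.null(gene))
        gene <- gene_record(gid, chrom[gi], strand[gi],
                            min(start[cds_j]), max(end[cds_j]),
                            cbind(pmax(exons[, "start"], min(start[cds_j])),
                                  pmin(exons[, "end"], max(end[cds_j]))) |>
                              (\(m) m[m[, 1L] <= m[, 2L], , drop = FALSE])())
      # rtracklayer parses comma-separated GFF3 attribute values into a
      # CharacterList; plain single values stay character
      split_attr <- function(a) {
        if (is(a, "List") || is.list(a)) as.character(unlist(a))
        else strsplit(as.character(a), ",", fixed = TRUE)[[1L]]
      }
      tids <- split_attr(mc$transcript_ids[mi])
      smp <- split_attr(mc$samples[mi])
      dst <- split_attr(mc$datasets[mi])
      cv <- as.numeric(split_attr(mc$coverages[mi]))
      for (k in seq_along(tids)) {
        tx[[length(tx) + 1L]] <- list(tid = tids[k], sample = smp[k],
                                      dataset = dst[k], cov = cv[k],
                                      exons = exons, strand = strand[mi])
      }
    }
    sel <- prediction_table(
      transcript_id = vapply(tx, `[[`, "", "tid"),
      chrom = chrom[gi],
      strand = vapply(tx, `[[`, "", "strand"),
      avg_coverage = vapply(tx, `[[`, 1, "cov"),
      exons = lapply(tx, `[[`, "exons"),
      sample_id = vapply(tx, `[[`, "", "sample"),
      dataset_id = vapply(tx, `[[`, "", "dataset"))
    attr(sel, "threshold") <- suppressWarnings(as.numeric(as.character(mc$scv_threshold[gi])))
    models[[gid]] <- build_gene_model(gene, sel, merge_bp = merge_bp)
  }
  models
}
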