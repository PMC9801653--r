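# shared fixture builders; everything is constructed in code at test time

# a + strand two-exon gene with CDS 1001-2500 (the worked example geometry)
example_gene <- function(gene_id = "gA", strand = "+") {
  gene_record(gene_id, "chr1", strand, 1001, 2500,
              cbind(c(1001, 1601), c(1500, 2500)))
}

# prediction table with a single transcript spanning [start, end] with the
# gene's internal structure
example_prediction <- function(gene, start, end, cov = 100, sample = "s1",
                               dataset = "A", tid = NULL, strand = NULL) {
  ex <- gene$exons
  ex[1L, "start"] <- start
  ex[nrow(ex), "end"] <- end
  prediction_table(tid %||% sprintf("%s_%s", gene$gene_id, sample),
                   gene$chrom, strand %||% gene$strand, cov, list(ex),
                   sample, dataset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent SCV oracle: try every ladder threshold from the most
# restrictive down, return the selection at the first non-empty one
scv_oracle <- function(covs, ladder) {
  for (t in rev(sort(ladder))) {
    sel <- which(covs >= t)
    if (length(sel)) return(list(threshold = t, selected = sort(sel)))
  }
  list(threshold = NA_real_, selected = integer(0))
}

# mirror a coordinate interval within a chromosome of length L
mirror_pos <- function(x, L) L + 1L - x

mirror_gene <- function(g, L) {
  ex <- cbind(mirror_pos(g$exons[, "end"], L), mirror_pos(g$exons[, "start"], L))
  gene_record(g$gene_id, g$chrom, .flip <- c("+" = "-", "-" = "+", "." = ".")[[g$strand]],
              mirror_pos(g$cds_end, L), mirror_pos(g$cds_start, L), ex)
}

mirror_predictions <- function(preds, L) {
  out <- preds
  flip <- c("+" = "-", "-" = "+", "." = ".")
  for (i in seq_len(nrow(out))) {
    e <- preds$exons[[i]]
    m <- cbind(start = rev(mirror_pos(e[, "end"], L)),
               end = rev(mirror_pos(e[, "start"], L)))
    rownames(m) <- NULL
    out$exons[[i]] <- m
  }
  out$start <- vapply(out$exons, function(e) min(e[, "start"]), 1L)
  out$end <- vapply(out$exons, function(e) max(e[, "end"]), 1L)
  out$strand <- unname(flip[preds$strand])
  out
}

mirror_junctions <- function(j, L) {
  flip <- c("+" = "-", "-" = "+", "." = ".")
  junction_table(j$chrom, mirror_pos(j$end, L), mirror_pos(j$start, L),
                 unname(flip[j$strand]), j$count, j$sample_id)
}

# flat coverage track over a single chromosome
flat_track <- function(len, value, sample = "s1", chrom = "chr1") {
  coverage_track(setNames(list(rep(value, len)), chrom), sample)
}

small_sim <- function(...) {
  simulate_transcriptome(sim_config(n_genes = 80, n_chroms = 2, n_ntars = 10,
                                    n_nats = 6, n_partial = 5,
                                    n_junction_negatives = 3,
                                    n_ir_negatives = 2, seed = 11, ...))
}

mk_model <- function(gene_id, strand, tss, chrom = "chr1") {
  # minimal single-transcript model with the requested TSS position
  if (strand == "+") {
    cs <- tss + 200L; ce <- cs + 400L
    g <- gene_record(gene_id, chrom, strand, cs, ce, cbind(cs, ce))
    build_gene_model(g, prediction_table("t", chrom, strand, 100,
                                         list(cbind(tss, ce + 100L)), "s", "A"))
  } else {
    ce <- tss - 200L; cs <- ce - 400L
    g <- gene_record(gene_id, chrom, strand, cs, ce, cbind(cs, ce))
    build_gene_model(g, prediction_table("t", chrom, strand, 100,
                                         list(cbind(cs - 100L, tss)), "s", "A"))
  }
}


ir_fixture <- function(intron_value, cds_count, intron_len = 80L,
                       pattern = NULL) {
  gene <- gene_record("gI", "chr1", "+", 1001, 2000 + intron_len,
                      cbind(c(1001, 1501 + intron_len), c(1500, 2000 + intron_len)))
  v <- numeric(2300 + intron_len)
  v[1001:1500] <- 100
  v[(1501 + intron_len):(2000 + intron_len)] <- 100
  iv <- if (is.null(pattern)) rep(intron_value, intron_len)
        else rep(pattern, length.out = intron_len)
  v[1501:(1500 + intron_len)] <- iv
  counts <- matrix(cds_count, 1, 1, dimnames = list("gI", "s1"))
  list(genes = list(gI = gene),
       coverage = list(s1 = coverage_track(list(chr1 = v), "s1")),
       counts = counts)
}

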