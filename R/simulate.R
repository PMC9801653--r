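#' Simulation configuration for a compact multi-chromosome genome
#'
#' Defaults emulate a gene-dense filamentous-fungus genome: ~1.5 kb coding
#' sequences spaced ~1.6 kb apart, ~1.5 short introns per gene, mean UTR
#' sizes of 275 bp (5') and 303 bp (3'), six samples in three datasets of
#' which one (B) is strand-specific.  Per-gene transcript coverages are
#' drawn within a single rung of the SCV ladder so that, in the noiseless
#' setting, the planted boundary set is exactly what SCV retains.
#'
#' @param n_chroms,n_genes Genome size (defaults 4 chromosomes, 2000 genes).
#' @param cds_length_mean,intergenic_mean,introns_per_gene_mean,intron_length_mean
#'   Structural means in bp (defaults 1483, 1581, 1.49, 80).
#' @param utr5_mean,utr3_mean Mean planted UTR sizes (defaults 275, 303).
#' @param samples `data.frame` with `sample_id`, `dataset_id`, `stranded`.
#' @param p_alt_tss,p_alt_tes Per-gene probability of planting an
#'   alternative TSS/TES, each specific to one sample (defaults 0.25).
#' @param p_a5ss,p_a3ss,p_es,p_ir Per-eligible-gene planting rates for the
#'   four event types (defaults 0.05, 0.08, 0.03, 0.05).
#' @param n_ntars,n_nats Numbers of planted intergenic transcripts and
#'   antisense transcripts (defaults 60, 40).
#' @param n_partial,n_junction_negatives,n_ir_negatives Negative-control
#'   counts (partially-overlapping transcripts; one-criterion junction
#'   violations per kind; one-criterion IR violations per kind).
#' @param jitter_sd Boundary jitter SD in bp (default 0 = noiseless).
#' @param read_length Read length used for count/coverage conversions.
#' @param ladder SCV coverage ladder (see [default_scv_ladder()]).
#' @param with_coverage Build per-sample coverage tracks (default `TRUE`).
#' @param seed RNG seed; fixes the full output bit-for-bit.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 4L, n_genes = 2000L,
                       cds_length_mean = 1483, intergenic_mean = 1581,
                       introns_per_gene_mean = 1.49, intron_length_mean = 80,
                       utr5_mean = 275, utr3_mean = 303,
                       samples = data.frame(
                         sample_id = c("A1", "A2", "B1", "B2", "C1", "C2"),
                         dataset_id = c("A", "A", "B", "B", "C", "C"),
                         stranded = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
                         stringsAsFactors = FALSE),
                       p_alt_tss = 0.25, p_alt_tes = 0.25,
                       p_a5ss = 0.05, p_a3ss = 0.08, p_es = 0.03, p_ir = 0.05,
                       n_ntars = 60L, n_nats = 40L,
                       n_partial = 10L, n_junction_negatives = 5L,
                       n_ir_negatives = 2L,
                       jitter_sd = 0, read_length = 100,
                       ladder = default_scv_ladder(),
                       with_coverage = TRUE, seed = 1L) {
  cfg <- mget(names(formals()))
  if (any(c(p_alt_tss, p_alt_tes, p_a5ss, p_a3ss, p_es, p_ir) < 0 |
          c(p_alt_tss, p_alt_tes, p_a5ss, p_a3ss, p_es, p_ir) > 1))
    stop("planting rates must be in [0, 1]")
  if (any(c(cds_length_mean, intergenic_mean, intron_length_mean,
            utr5_mean, utr3_mean) <= 0)) stop("structural means must be positive")
  if (n_genes < n_chroms) stop("fewer genes than chromosomes")
  if (nrow(samples) < 2L) stop("need at least two samples")
  structure(cfg, class = "sim_config")
}

# sample n elements from x without the length-1 integer pitfall
.sample_safe <- function(x, n) {
  n <- min(n, length(x))
  x[sample.int(length(x), n)]
}

# split coding length into k exons, each >= min_exon
.split_exons <- function(coding_len, k, min_exon = 60L) {
  while (k > 1L && coding_len < k * min_exon) k <- k - 1L
  base <- coding_len %/% k
  lens <- rep(base, k)
  lens[1L] <- lens[1L] + coding_len - sum(lens)
  lens
}

#' Generate a synthetic genome, multi-sample predictions and ground truth
#'
#' Lays out genes with exponential-like intergenic spacing, emits per-sample
#' transcript predictions (each gene in 2+ samples, alternative boundaries
#' only in their designated sample), exon-exon junctions satisfying or --
#' for negative controls -- violating exactly one confidence criterion,
#' flat intron-coverage signals for planted retained introns, intergenic
#' transcripts (some overlapping, some spliced), antisense transcripts on
#' stranded samples, and a gene-by-sample count table.  Deterministic under
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory: writes `annotation.gff3`, per-sample
#'   `predictions_<s>.gtf` / `junctions_<s>.bed` / `coverage_<s>.bedGraph`,
#'   `counts.tsv` and `truth.json`.
#' @return List of class `sim_data`: `genes`, `predictions`, `junctions`,
#'   `coverage` (named list of [coverage_track()] or `NULL`), `counts`,
#'   `chrom_lengths`, `truth`, `config`.
#' @export
simulate_transcriptome <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  smp <- cfg$samples
  n_s <- nrow(smp)
  unstranded_samples <- smp$sample_id[!smp$stranded]
  stranded_samples <- smp$sample_id[smp$stranded]
  ladder <- .check_ladder(cfg$ladder)
  rung_hi <- c(ladder[-1L], 2 * ladder[length(ladder)])

  per_chrom <- diff(round(seq(0L, cfg$n_genes, length.out = cfg$n_chroms + 1L)))
  G <- list(); gi <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    chrom <- sprintf("chr%d", ci)
    cursor <- 0L
    prev <- NULL
    for (k in seq_len(per_chrom[ci])) {
      gi <- gi + 1L
      gap <- 300L + as.integer(round(rexp(1L, 1 / (cfg$intergenic_mean - 300))))
      coding <- max(300L, as.integer(round(rnorm(1L, cfg$cds_length_mean,
                                                 cfg$cds_length_mean * 0.25))))
      n_int <- rpois(1L, cfg$introns_per_gene_mean)
      int_lens <- if (n_int > 0L)
        pmax(40L, as.integer(round(rnorm(n_int, cfg$intron_length_mean, 15))))
      else integer(0)
      ex_lens <- .split_exons(coding, n_int + 1L)
      n_int <- length(ex_lens) - 1L
      int_lens <- int_lens[seq_len(n_int)]
      strand <- sample(c("+", "-"), 1L)
      cds_start <- cursor + gap
      pos <- cds_start
      ex <- matrix(0L, nrow = n_int + 1L, ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
      for (e in seq_len(n_int + 1L)) {
        ex[e, ] <- c(pos, pos + ex_lens[e] - 1L)
        pos <- ex[e, 2L] + 1L
        if (e <= n_int) pos <- pos + int_lens[e]
      }
      cds_end <- ex[n_int + 1L, 2L]
      cursor <- cds_end
      # desired flank extensions (left/right in genomic orientation)
      want_l <- if (strand == "+") cfg$utr5_mean else cfg$utr3_mean
      want_r <- if (strand == "+") cfg$utr3_mean else cfg$utr5_mean
      ext_l <- max(30L, as.integer(round(rnorm(1L, want_l, want_l * 0.3))))
      ext_r <- max(30L, as.integer(round(rnorm(1L, want_r, want_r * 0.3))))
      # clamp this gene's left extension and the previous gene's right
      # extension into the shared gap
      avail <- gap - 10L
      r_prev <- if (is.null(prev)) 0L else G[[prev]]$ext_r
      if (r_prev + ext_l > avail) {
        r_new <- max(10L, as.integer(floor(avail * r_prev / (r_prev + ext_l))))
        ext_l <- max(10L, avail - r_new)
        if (!is.null(prev)) G[[prev]]$ext_r <- r_new
      }
      if (is.null(prev)) ext_l <- min(ext_l, gap - 10L)
      G[[gi]] <- list(gene_id = sprintf("g%04d", gi), chrom = chrom,
                      strand = strand, cds_start = cds_start, cds_end = cds_end,
                      exons = ex, introns = intron_gaps(ex),
                      coding_len = coding, ext_l = ext_l, ext_r = ext_r)
      prev <- gi
    }
  }
  n_g <- length(G)

  # UTR sizes from flank extensions by strand; alternative boundaries
  for (i in seq_len(n_g)) {
    g <- G[[i]]
    g$utr5 <- if (g$strand == "+") g$ext_l else g$ext_r
    g$utr3 <- if (g$strand == "+") g$ext_r else g$ext_l
    g$alt_utr5 <- NA_integer_; g$alt_utr3 <- NA_integer_
    if (runif(1L) < cfg$p_alt_tss && g$utr5 >= 40L) {
      d <- max(15L, min(g$utr5 - 15L, as.integer(round(rnorm(1L, 156, 40)))))
      g$alt_utr5 <- g$utr5 - d
    }
    if (runif(1L) < cfg$p_alt_tes && g$utr3 >= 40L) {
      d <- max(15L, min(g$utr3 - 15L, as.integer(round(rnorm(1L, 114, 35)))))
      g$alt_utr3 <- g$utr3 - d
    }
    n_emit <- sample(2:n_s, 1L)
    g$emit <- sample(smp$sample_id, n_emit)
    g$alt_tss_sample <- if (!is.na(g$alt_utr5)) sample(g$emit, 1L) else NA_character_
    g$alt_tes_sample <- if (!is.na(g$alt_utr3)) {
      pool <- setdiff(g$emit, g$alt_tss_sample)
      if (length(pool)) sample(pool, 1L) else sample(g$emit, 1L)
    } else NA_character_
    G[[i]] <- g
  }

  # designate event genes (disjoint pools)
  n_introns_of <- vapply(G, function(g) nrow(g$introns), 1L)
  pool <- sample(seq_len(n_g))
  take <- function(n, min_introns = 1L) {
    ok <- pool[n_introns_of[pool] >= min_introns]
    got <- head(ok, n)
    pool <<- setdiff(pool, got)
    got
  }
  eligible1 <- sum(n_introns_of >= 1L)
  des <- list(
    a5ss = take(round(cfg$p_a5ss * eligible1)),
    a3ss = take(round(cfg$p_a3ss * eligible1)),
    es = take(round(cfg$p_es * eligible1), min_introns = 2L),
    ir = take(round(cfg$p_ir * eligible1)),
    jn_single = take(cfg$n_junction_negatives),
    jn_lowcov = take(cfg$n_junction_negatives),
    ir_t1 = take(cfg$n_ir_negatives), ir_t2 = take(cfg$n_ir_negatives),
    ir_t3 = take(cfg$n_ir_negatives), ir_t4 = take(cfg$n_ir_negatives))

  rung <- sample(seq_along(ladder), n_g, replace = TRUE)

  # per-(gene, sample) prediction coverage within the gene's rung
  cov_gs <- matrix(NA_real_, n_g, n_s, dimnames = list(NULL, smp$sample_id))
  for (i in seq_len(n_g)) {
    lo <- ladder[rung[i]]; hi <- lo + 0.9 * (rung_hi[rung[i]] - lo)
    cov_gs[i, G[[i]]$emit] <- round(runif(length(G[[i]]$emit), lo, hi), 1)
  }

  # counts (CDS read counts), with the T3-violation override applied below
  counts <- matrix(0, n_g, n_s,
                   dimnames = list(vapply(G, `[[`, "", "gene_id"), smp$sample_id))
  for (i in seq_len(n_g)) {
    counts[i, ] <- rpois(n_s, 2)
    e <- G[[i]]$emit
    counts[i, e] <- round(cov_gs[i, e] * G[[i]]$coding_len / cfg$read_length)
  }

  # ---- predictions -------------------------------------------------------
  pr <- list()
  truth_tss <- list(); truth_tes <- list()
  for (i in seq_len(n_g)) {
    g <- G[[i]]
    plus <- g$strand == "+"
    base_tss <- if (plus) g$cds_start - g$utr5 else g$cds_end + g$utr5
    base_tes <- if (plus) g$cds_end + g$utr3 else g$cds_start - g$utr3
    tss_set <- base_tss; tes_set <- base_tes
    for (s in g$emit) {
      u5 <- if (!is.na(g$alt_tss_sample) && s == g$alt_tss_sample) g$alt_utr5 else g$utr5
      u3 <- if (!is.na(g$alt_tes_sample) && s == g$alt_tes_sample) g$alt_utr3 else g$utr3
      if (cfg$jitter_sd > 0) {
        u5 <- min(g$ext_l + g$ext_r, max(5L, u5 + as.integer(round(rnorm(1L, 0, cfg$jitter_sd)))))
        u3 <- min(g$ext_l + g$ext_r, max(5L, u3 + as.integer(round(rnorm(1L, 0, cfg$jitter_sd)))))
        u5 <- min(u5, if (plus) g$ext_l else g$ext_r)
        u3 <- min(u3, if (plus) g$ext_r else g$ext_l)
      }
      left <- if (plus) g$cds_start - u5 else g$cds_start - u3
      right <- if (plus) g$cds_end + u3 else g$cds_end + u5
      ex <- g$exons
      ex[1L, "start"] <- left
      ex[nrow(ex), "end"] <- right
      pr[[length(pr) + 1L]] <- list(
        tid = sprintf("%s_%s", g$gene_id, s), chrom = g$chrom,
        strand = if (smp$stranded[match(s, smp$sample_id)]) g$strand else ".",
        cov = cov_gs[i, s], exons = ex, sample = s,
        dataset = smp$dataset_id[match(s, smp$sample_id)])
      if (cfg$jitter_sd == 0) {
        tss_set <- union(tss_set, if (plus) left else right)
        tes_set <- union(tes_set, if (plus) right else left)
      }
    }
    truth_tss[[i]] <- data.frame(gene_id = g$gene_id, position = sort(tss_set))
    truth_tes[[i]] <- data.frame(gene_id = g$gene_id, position = sort(tes_set))
  }

  # ---- junctions ---------------------------------------------------------
  jn <- list()
  addj <- function(chrom, start, end, strand, count, sample)
    jn[[length(jn) + 1L]] <<- data.frame(chrom = chrom, start = start, end = end,
                                         strand = strand, count = count,
                                         sample_id = sample,
                                         stringsAsFactors = FALSE)
  for (i in seq_len(n_g)) {
    g <- G[[i]]
    if (nrow(g$introns) == 0L) next
    for (s in g$emit)
      for (j in seq_len(nrow(g$introns)))
        addj(g$chrom, unname(g$introns[j, "start"]), unname(g$introns[j, "end"]),
             g$strand, max(6, round(cov_gs[i, s] / 50)), s)
  }
  ev <- list()
  addev <- function(...) ev[[length(ev) + 1L]] <<- data.frame(...,
    stringsAsFactors = FALSE)
  plant_alt <- function(i, type) {
    g <- G[[i]]
    j <- g$introns[1L, ]
    plus <- g$strand == "+"
    donor_side <- (type == "A5SS") == plus  # TRUE -> shift the start coordinate
    alt <- if (donor_side) c(j["start"] + 9L, j["end"]) else c(j["start"], j["end"] - 9L)
    ss <- .sample_safe(g$emit, 2L)
    addj(g$chrom, alt[1L], alt[2L], g$strand, 7, ss[1L])
    addj(g$chrom, alt[1L], alt[2L], g$strand, 5, ss[2L])
    addev(event_type = type, gene_id = g$gene_id, chrom = g$chrom,
          j1_start = unname(min(j["start"], alt[1L])),
          j1_end = unname(min(j["end"], alt[2L])),
          j2_start = unname(max(j["start"], alt[1L])),
          j2_end = unname(max(j["end"], alt[2L])),
          exon_start = NA_integer_, exon_end = NA_integer_,
          samples = paste(sort(ss), collapse = ","))
  }
  for (i in des$a5ss) plant_alt(i, "A5SS")
  for (i in des$a3ss) plant_alt(i, "A3SS")
  for (i in des$es) {
    g <- G[[i]]
    skip <- unname(c(g$introns[1L, "start"], g$introns[2L, "end"]))
    ss <- .sample_safe(g$emit, 2L)
    addj(g$chrom, skip[1L], skip[2L], g$strand, 7, ss[1L])
    addj(g$chrom, skip[1L], skip[2L], g$strand, 5, ss[2L])
    addev(event_type = "ES", gene_id = g$gene_id, chrom = g$chrom,
          j1_start = unname(skip[1L]), j1_end = unname(skip[2L]),
          j2_start = NA_integer_, j2_end = NA_integer_,
          exon_start = unname(g$exons[2L, "start"]),
          exon_end = unname(g$exons[2L, "end"]),
          samples = paste(sort(ss), collapse = ","))
  }
  jneg <- list()
  for (i in des$jn_single) {
    g <- G[[i]]
    if (nrow(g$introns) == 0L) next
    alt <- unname(c(g$introns[1L, "start"] + 15L, g$introns[1L, "end"]))
    s <- .sample_safe(g$emit, 1L)
    addj(g$chrom, alt[1L], alt[2L], g$strand, 50, s)
    jneg[[length(jneg) + 1L]] <- data.frame(
      kind = "single_sample", gene_id = g$gene_id, chrom = g$chrom,
      start = alt[1L], end = alt[2L], stringsAsFactors = FALSE)
  }
  for (i in des$jn_lowcov) {
    g <- G[[i]]
    if (nrow(g$introns) == 0L) next
    alt <- unname(c(g$introns[1L, "start"] + 15L, g$introns[1L, "end"]))
    ss <- .sample_safe(g$emit, 2L)
    addj(g$chrom, alt[1L], alt[2L], g$strand, 4, ss[1L])
    addj(g$chrom, alt[1L], alt[2L], g$strand, 3, ss[2L])
    jneg[[length(jneg) + 1L]] <- data.frame(
      kind = "low_coverage", gene_id = g$gene_id, chrom = g$chrom,
      start = alt[1L], end = alt[2L], stringsAsFactors = FALSE)
  }

  # ---- intron retention plants ------------------------------------------
  ir_truth <- list(); ir_neg <- list()
  ir_sig <- list()  # coverage overrides: chrom,start,end,value,sample
  addsig <- function(chrom, start, end, value, sample)
    ir_sig[[length(ir_sig) + 1L]] <<- data.frame(chrom = chrom, start = start,
                                                 end = end, value = value,
                                                 sample_id = sample,
                                                 stringsAsFactors = FALSE)
  for (i in des$ir) {
    g <- G[[i]]
    ss <- .sample_safe(g$emit, 2L)
    for (s in ss) {
      counts[i, s] <- max(counts[i, s], 500)
      enorm <- counts[i, s] * cfg$read_length / g$coding_len
      v <- max(35, ceiling(0.15 * enorm))
      addsig(g$chrom, unname(g$introns[1L, "start"]), unname(g$introns[1L, "end"]), v, s)
    }
    ir_truth[[length(ir_truth) + 1L]] <- data.frame(
      gene_id = g$gene_id, intron_index = 1L, chrom = g$chrom,
      start = unname(g$introns[1L, "start"]), end = unname(g$introns[1L, "end"]),
      samples = paste(sort(ss), collapse = ","), stringsAsFactors = FALSE)
  }
  addneg <- function(kind, g, s) ir_neg[[length(ir_neg) + 1L]] <<- data.frame(
    kind = kind, gene_id = g$gene_id, intron_index = 1L, sample_id = s,
    stringsAsFactors = FALSE)
  for (i in des$ir_t1) {  # mean exactly at T1 -> rejected (strict gate)
    g <- G[[i]]; s <- .sample_safe(g$emit, 1L)
    counts[i, s] <- 500  # E passes T3; scaled Enorm < 300 keeps the ratio above T4
    addsig(g$chrom, unname(g$introns[1L, "start"]), unname(g$introns[1L, "end"]), 30, s)
    addneg("t1_exact", g, s)
  }
  for (i in des$ir_t2) {  # alternating bins: SD >= T2
    g <- G[[i]]; s <- .sample_safe(g$emit, 1L)
    counts[i, s] <- 500
    is0 <- unname(g$introns[1L, "start"]); ie0 <- unname(g$introns[1L, "end"])
    p <- is0
    val <- 80
    while (p <= ie0) {
      addsig(g$chrom, p, min(p + 7L, ie0), val, s)
      val <- if (val == 80) 0 else 80
      p <- p + 8L
    }
    addneg("t2_sd", g, s)
  }
  for (i in des$ir_t3) {  # CDS count forced below T3
    g <- G[[i]]; s <- .sample_safe(g$emit, 1L)
    addsig(g$chrom, unname(g$introns[1L, "start"]), unname(g$introns[1L, "end"]), 40, s)
    counts[i, s] <- 150
    addneg("t3_count", g, s)
  }
  for (i in des$ir_t4) {  # high CDS expression: scaled ratio below T4
    g <- G[[i]]; s <- .sample_safe(g$emit, 1L)
    counts[i, s] <- 4L * g$coding_len  # scaled Enorm = 400 >> 10 * 31
    addsig(g$chrom, unname(g$introns[1L, "start"]), unname(g$introns[1L, "end"]), 31, s)
    addneg("t4_ratio", g, s)
  }

  # ---- free intergenic gaps for nTAR placement --------------------------
  blocked <- lapply(split(seq_len(n_g), vapply(G, `[[`, "", "chrom")), function(idx) {
    data.frame(start = vapply(idx, function(i)
                 G[[i]]$cds_start - G[[i]]$ext_l - 5L, 1L),
               end = vapply(idx, function(i)
                 G[[i]]$cds_end + G[[i]]$ext_r + 5L, 1L))
  })
  chrom_lengths <- vapply(blocked, function(b) max(b$end) + 1500L, 1L)
  free <- list()
  for (chrom in names(blocked)) {
    b <- blocked[[chrom]][order(blocked[[chrom]]$start), ]
    gs <- c(1L, b$end + 1L)
    ge <- c(b$start - 1L, chrom_lengths[[chrom]])
    ok <- ge - gs + 1L >= 240L
    if (any(ok))
      free[[length(free) + 1L]] <- data.frame(chrom = chrom, start = gs[ok],
                                              end = ge[ok],
                                              stringsAsFactors = FALSE)
  }
  free <- do.call(rbind, free)
  if (is.null(free) || nrow(free) < cfg$n_ntars)
    stop("genome too small: not enough intergenic room for the requested nTARs")
  pick <- sample(seq_len(nrow(free)), cfg$n_ntars)
  ntar_truth <- list()
  for (k in seq_along(pick)) {
    fg <- free[pick[k], ]
    gapw <- fg$end - fg$start + 1L
    L <- min(gapw - 20L, max(150L, as.integer(round(rnorm(1L, 800, 500)))))
    s0 <- fg$start + 10L; e0 <- s0 + L - 1L
    cov <- round(exp(runif(1L, log(10), log(300))), 1)
    smp_n <- sample(unstranded_samples, 1L)
    paired <- k %% 3L == 0L
    if (paired) {
      cut1 <- s0 + as.integer(floor(0.6 * L)); cut2 <- s0 + as.integer(floor(0.4 * L))
      pr[[length(pr) + 1L]] <- list(tid = sprintf("ntar%03d_a", k), chrom = fg$chrom,
                                    strand = ".", cov = cov,
                                    exons = exon_matrix(s0, cut1),
                                    sample = smp_n,
                                    dataset = smp$dataset_id[match(smp_n, smp$sample_id)])
      smp_n2 <- sample(unstranded_samples, 1L)
      pr[[length(pr) + 1L]] <- list(tid = sprintf("ntar%03d_b", k), chrom = fg$chrom,
                                    strand = ".", cov = max(10, round(cov * 0.8, 1)),
                                    exons = exon_matrix(cut2, e0),
                                    sample = smp_n2,
                                    dataset = smp$dataset_id[match(smp_n2, smp$sample_id)])
    } else {
      pr[[length(pr) + 1L]] <- list(tid = sprintf("ntar%03d", k), chrom = fg$chrom,
                                    strand = ".", cov = cov,
                                    exons = exon_matrix(s0, e0),
                                    sample = smp_n,
                                    dataset = smp$dataset_id[match(smp_n, smp$sample_id)])
    }
    spliced <- k %% 2L == 0L && L >= 160L
    if (spliced)
      addj(fg$chrom, s0 + 40L, s0 + 99L, ".", 3, sample(smp$sample_id, 1L))
    ntar_truth[[k]] <- data.frame(chrom = fg$chrom, start = s0, end = e0,
                                  spliced = spliced, paired = paired,
                                  stringsAsFactors = FALSE)
  }

  # ---- partially-overlapping transcripts (never class "none") -----------
  partial_truth <- list()
  cand <- .sample_safe(setdiff(seq_len(n_g), unlist(des)), cfg$n_partial)
  for (i in cand) {
    g <- G[[i]]
    s0 <- g$cds_start + (g$cds_end - g$cds_start) %/% 2L
    e0 <- g$cds_end + min(150L, g$ext_r)
    smp_n <- sample(unstranded_samples, 1L)
    pr[[length(pr) + 1L]] <- list(tid = sprintf("part_%s", g$gene_id),
                                  chrom = g$chrom, strand = ".",
                                  cov = round(runif(1L, 12, 80), 1),
                                  exons = exon_matrix(s0, e0), sample = smp_n,
                                  dataset = smp$dataset_id[match(smp_n, smp$sample_id)])
    partial_truth[[length(partial_truth) + 1L]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, start = s0, end = e0,
      stringsAsFactors = FALSE)
  }

  # ---- NATs and NAT negative controls (stranded samples only) -----------
  nat_truth <- list(); nat_neg <- list()
  if (cfg$n_nats > 0L && length(stranded_samples) == 0L)
    stop("NAT planting requires at least one stranded sample")
  nat_genes <- .sample_safe(setdiff(seq_len(n_g), cand), cfg$n_nats)
  for (i in nat_genes) {
    g <- G[[i]]
    s0 <- g$cds_start + (g$cds_end - g$cds_start) %/% 3L
    e0 <- g$cds_end + min(150L, g$ext_r)
    smp_n <- sample(stranded_samples, 1L)
    pr[[length(pr) + 1L]] <- list(tid = sprintf("nat_%s", g$gene_id),
                                  chrom = g$chrom,
                                  strand = .opposite_strand(g$strand),
                                  cov = round(exp(runif(1L, log(10), log(500))), 1),
                                  exons = exon_matrix(s0, e0), sample = smp_n,
                                  dataset = smp$dataset_id[match(smp_n, smp$sample_id)])
    nat_truth[[length(nat_truth) + 1L]] <- data.frame(
      chrom = g$chrom, start = s0, end = e0,
      strand = .opposite_strand(g$strand), linked_gene = g$gene_id,
      sample_id = smp_n, stringsAsFactors = FALSE)
  }
  sense_genes <- .sample_safe(setdiff(seq_len(n_g), c(cand, nat_genes)), 6L)
  for (i in sense_genes) {
    g <- G[[i]]
    s0 <- g$cds_start + (g$cds_end - g$cds_start) %/% 3L
    e0 <- g$cds_end + min(120L, g$ext_r)
    smp_n <- sample(stranded_samples, 1L)
    pr[[length(pr) + 1L]] <- list(tid = sprintf("sense_%s", g$gene_id),
                                  chrom = g$chrom, strand = g$strand,
                                  cov = round(runif(1L, 15, 200), 1),
                                  exons = exon_matrix(s0, e0), sample = smp_n,
                                  dataset = smp$dataset_id[match(smp_n, smp$sample_id)])
    nat_neg[[length(nat_neg) + 1L]] <- data.frame(
      kind = "sense", tid = sprintf("sense_%s", g$gene_id),
      gene_id = g$gene_id, stringsAsFactors = FALSE)
  }
  chrom_of <- vapply(G, `[[`, "", "chrom")
  used <- c(cand, nat_genes, sense_genes)
  adj <- which(chrom_of[-n_g] == chrom_of[-1L])
  adj <- adj[!(adj %in% used) & !((adj + 1L) %in% used)]
  spanner_first <- .sample_safe(adj, 4L)
  for (i in spanner_first) {
    g1 <- G[[i]]; g2 <- G[[i + 1L]]
    s0 <- g1$cds_start + (g1$cds_end - g1$cds_start) %/% 2L
    e0 <- g2$cds_start + (g2$cds_end - g2$cds_start) %/% 2L
    smp_n <- sample(stranded_samples, 1L)
    pr[[length(pr) + 1L]] <- list(tid = sprintf("span_%s", g1$gene_id),
                                  chrom = g1$chrom,
                                  strand = .opposite_strand(g1$strand),
                                  cov = round(runif(1L, 15, 200), 1),
                                  exons = exon_matrix(s0, e0), sample = smp_n,
                                  dataset = smp$dataset_id[match(smp_n, smp$sample_id)])
    nat_neg[[length(nat_neg) + 1L]] <- data.frame(
      kind = "two_gene_spanner", tid = sprintf("span_%s", g1$gene_id),
      gene_id = g1$gene_id, stringsAsFactors = FALSE)
  }

  # ---- assemble tables ---------------------------------------------------
  predictions <- prediction_table(
    transcript_id = vapply(pr, `[[`, "", "tid"),
    chrom = vapply(pr, `[[`, "", "chrom"),
    strand = vapply(pr, `[[`, "", "strand"),
    avg_coverage = vapply(pr, `[[`, 1, "cov"),
    exons = lapply(pr, `[[`, "exons"),
    sample_id = vapply(pr, `[[`, "", "sample"),
    dataset_id = vapply(pr, `[[`, "", "dataset"))
  junctions <- do.call(rbind, jn)
  class(junctions) <- c("junction_table", "data.frame")
  genes <- setNames(lapply(G, function(g)
    gene_record(g$gene_id, g$chrom, g$strand, g$cds_start, g$cds_end, g$exons)),
    vapply(G, `[[`, "", "gene_id"))

  coverage <- NULL
  if (cfg$with_coverage) {
    sig <- if (length(ir_sig)) do.call(rbind, ir_sig) else NULL
    coverage <- list()
    for (s in smp$sample_id) {
      seg <- list()
      for (i in seq_len(n_g)) {
        g <- G[[i]]
        if (!s %in% g$emit) next
        seg[[length(seg) + 1L]] <- data.frame(
          chrom = g$chrom, start = unname(g$exons[, "start"]),
          end = unname(g$exons[, "end"]),
          value = unname(cov_gs[i, s]), stringsAsFactors = FALSE)
        if (nrow(g$introns) > 0L) {
          keep <- rep(TRUE, nrow(g$introns))
          if (!is.null(sig)) {
            ov <- sig$sample_id == s & sig$chrom == g$chrom &
              sig$start >= g$introns[1L, "start"] & sig$end <= g$introns[1L, "end"]
            if (any(ov)) keep[1L] <- FALSE
          }
          if (any(keep))
            seg[[length(seg) + 1L]] <- data.frame(
              chrom = g$chrom, start = unname(g$introns[keep, "start"]),
              end = unname(g$introns[keep, "end"]), value = 1,
              stringsAsFactors = FALSE)
        }
      }
      if (!is.null(sig)) {
        ssig <- sig[sig$sample_id == s, c("chrom", "start", "end", "value")]
        if (nrow(ssig)) seg[[length(seg) + 1L]] <- ssig
      }
      segs <- do.call(rbind, seg)
      segs <- segs[segs$value != 0, , drop = FALSE]
      gr <- GenomicRanges::GRanges(segs$chrom,
                                   IRanges::IRanges(segs$start, segs$end),
                                   score = segs$value,
                                   seqlengths = chrom_lengths)
      cov <- GenomicRanges::coverage(gr, weight = "score")
      coverage[[s]] <- coverage_track(as.list(cov), s)
    }
  }

  mk_class <- function(i) {
    g <- G[[i]]
    multi_tss <- !is.na(g$alt_utr5); multi_tes <- !is.na(g$alt_utr3)
    if (multi_tss && multi_tes) "multi_both"
    else if (multi_tss) "multi_TSS_only"
    else if (multi_tes) "multi_TES_only"
    else "single"
  }
  truth <- list(
    genes = data.frame(gene_id = vapply(G, `[[`, "", "gene_id"),
                       chrom = chrom_of,
                       strand = vapply(G, `[[`, "", "strand"),
                       n_introns = n_introns_of,
                       multiplicity_class = vapply(seq_len(n_g), mk_class, ""),
                       stringsAsFactors = FALSE),
    tss = do.call(rbind, truth_tss),
    tes = do.call(rbind, truth_tes),
    events = if (length(ev)) do.call(rbind, ev) else NULL,
    junction_negatives = if (length(jneg)) do.call(rbind, jneg) else NULL,
    ir = if (length(ir_truth)) do.call(rbind, ir_truth) else NULL,
    ir_negatives = if (length(ir_neg)) do.call(rbind, ir_neg) else NULL,
    ntars = if (length(ntar_truth)) do.call(rbind, ntar_truth) else NULL,
    partials = if (length(partial_truth)) do.call(rbind, partial_truth) else NULL,
    nats = if (length(nat_truth)) do.call(rbind, nat_truth) else NULL,
    nat_negatives = if (length(nat_neg)) do.call(rbind, nat_neg) else NULL)

  out <- structure(list(genes = genes, predictions = predictions,
                        junctions = junctions, coverage = coverage,
                        counts = counts, chrom_lengths = chrom_lengths,
                        truth = truth, config = cfg),
                   class = "sim_data")
  if (!is.null(out_dir)) write_sim_data(out, out_dir)
  out
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf(paste0("<sim_data> %d genes on %d chromosome(s), %d predictions, ",
                     "%d junction rows, %s coverage, seed %d\n"),
              length(x$genes), length(x$chrom_lengths), nrow(x$predictions),
              nrow(x$junctions), if (is.null(x$coverage)) "no" else "with",
              x$config$seed))
  invisible(x)
}

#' Write a simulated dataset to disk in standard formats
#'
#' @param sim A `sim_data` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_sim_data <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(sim$genes, file.path(out_dir, "annotation.gff3"))
  for (s in unique(sim$predictions$sample_id)) {
    p <- sim$predictions[sim$predictions$sample_id == s, , drop = FALSE]
    write_predictions(p, file.path(out_dir, sprintf("predictions_%s.gtf", s)))
  }
  for (s in unique(sim$junctions$sample_id)) {
    j <- sim$junctions[sim$junctions$sample_id == s, , drop = FALSE]
    write_junctions(j, file.path(out_dir, sprintf("junctions_%s.bed", s)))
  }
  if (!is.null(sim$coverage))
    for (s in names(sim$coverage))
      write_bedgraph(sim$coverage[[s]], file.path(out_dir,
                                                  sprintf("coverage_%s.bedGraph", s)))
  write_count_table(sim$counts, file.path(out_dir, "counts.tsv"))
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
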