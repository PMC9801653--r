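# gene with a 5'UTR intron: transcript exons (726,900),(950,2803), CDS 1001-2500
utr_intron_model <- function() {
  gene <- gene_record("gU", "chr1", "+", 1001, 2500, cbind(1001, 2500))
  sel <- prediction_table("t1", "chr1", "+", 100,
                          list(cbind(c(726, 950), c(900, 2803))), "s1", "A")
  build_gene_model(gene, sel)
}

test_that("UTR introns are counted by strict containment in the UTR", {
  m <- utr_intron_model()
  res <- detect_utr_introns(list(gU = m))
  expect_equal(res$n_utr5_introns, 1L)  # intron (901,949) inside 5'UTR (726,1000)
  expect_equal(res$n_utr3_introns, 0L)

  # an intron straddling cds_start is not a UTR intron
  gene <- gene_record("gS", "chr1", "+", 1001, 2500, cbind(1001, 2500))
  sel <- prediction_table("t1", "chr1", "+", 100,
                          list(cbind(c(726, 1051), c(979, 2803))), "s1", "A")
  res2 <- detect_utr_introns(list(gS = build_gene_model(gene, sel)))
  expect_equal(res2$n_utr5_introns, 0L)
  expect_equal(res2$n_utr3_introns, 0L)

  # single-exon transcript: no introns at all
  gene3 <- example_gene()
  m3 <- build_gene_model(gene3, prediction_table(
    "t1", "chr1", "+", 100, list(cbind(726, 2803)), "s1", "A"))
  expect_equal(detect_utr_introns(list(g = m3))$n_utr5_introns, 0L)
})

# one + strand gene with intron (201,300) inside CDS 101-500
jgene_models <- function(strand = "+") {
  gene <- gene_record("gJ", "chr1", strand, 101, 500,
                      cbind(c(101, 301), c(200, 500)))
  sel <- example_prediction(gene, 51, 600)
  list(gJ = build_gene_model(gene, sel))
}

jt <- function(...) {
  rows <- list(...)
  do.call(junction_table, setNames(
    lapply(1:6, function(i) vapply(rows, `[[`, rows[[1]][[i]], i)),
    c("chrom", "start", "end", "strand", "count", "sample_id")))
}

test_that("junction confidence filter needs 2 samples and coverage 5 once", {
  models <- jgene_models()
  # base junction in two samples + alt donor in two samples
  j <- jt(list("chr1", 201L, 300L, "+", 9, "s1"),
          list("chr1", 201L, 300L, "+", 8, "s2"),
          list("chr1", 221L, 300L, "+", 7, "s1"),
          list("chr1", 221L, 300L, "+", 5, "s2"))
  ev <- classify_junction_events(j, models)
  expect_equal(ev$event_type, "A5SS")
  expect_equal(ev[, c("j1_start", "j1_end", "j2_start", "j2_end")],
               data.frame(j1_start = 201L, j1_end = 300L,
                          j2_start = 221L, j2_end = 300L))

  # one sample with high support: rejected (independent-sample rule)
  j1 <- jt(list("chr1", 201L, 300L, "+", 9, "s1"),
           list("chr1", 201L, 300L, "+", 8, "s2"),
           list("chr1", 221L, 300L, "+", 50, "s1"))
  expect_equal(nrow(classify_junction_events(j1, models)), 0L)

  # two samples but support below 5 everywhere: rejected
  j2 <- jt(list("chr1", 201L, 300L, "+", 9, "s1"),
           list("chr1", 201L, 300L, "+", 8, "s2"),
           list("chr1", 221L, 300L, "+", 4, "s1"),
           list("chr1", 221L, 300L, "+", 3, "s2"))
  expect_equal(nrow(classify_junction_events(j2, models)), 0L)
})

test_that("shared-site classification is strand-aware (A5SS vs A3SS)", {
  j <- jt(list("chr1", 201L, 300L, "+", 9, "s1"),
          list("chr1", 201L, 300L, "+", 8, "s2"),
          list("chr1", 221L, 300L, "+", 7, "s1"),
          list("chr1", 221L, 300L, "+", 5, "s2"))
  expect_equal(classify_junction_events(j, jgene_models("+"))$event_type, "A5SS")
  # same coordinates on a - strand gene: the shared 300-side is the donor
  jm <- jt(list("chr1", 201L, 300L, "-", 9, "s1"),
           list("chr1", 201L, 300L, "-", 8, "s2"),
           list("chr1", 221L, 300L, "-", 7, "s1"),
           list("chr1", 221L, 300L, "-", 5, "s2"))
  expect_equal(classify_junction_events(jm, jgene_models("-"))$event_type, "A3SS")
})

test_that("exon skipping needs a contained annotated exon and passing inclusion junctions", {
  gene <- gene_record("gE", "chr1", "+", 101, 800,
                      cbind(c(101, 301, 501), c(200, 400, 800)))
  models <- list(gE = build_gene_model(gene, example_prediction(gene, 51, 900)))
  j <- jt(list("chr1", 201L, 300L, "+", 9, "s1"),   # inclusion left
          list("chr1", 201L, 300L, "+", 9, "s2"),
          list("chr1", 401L, 500L, "+", 9, "s1"),   # inclusion right
          list("chr1", 401L, 500L, "+", 9, "s2"),
          list("chr1", 201L, 500L, "+", 7, "s1"),   # skipping junction
          list("chr1", 201L, 500L, "+", 6, "s2"))
  ev <- classify_junction_events(j, models)
  es <- ev[ev$event_type == "ES", ]
  expect_equal(nrow(es), 1L)
  expect_equal(es$exon_start, 301L)
  expect_equal(es$exon_end, 400L)
  # the skipping junction must not shadow as A5SS/A3SS
  expect_equal(nrow(ev[ev$event_type != "ES", ]), 0L)
  # without passing inclusion junctions the call is dropped by default
  jnoinc <- jt(list("chr1", 201L, 500L, "+", 7, "s1"),
               list("chr1", 201L, 500L, "+", 6, "s2"))
  expect_equal(nrow(classify_junction_events(jnoinc, models)), 0L)
  expect_equal(classify_junction_events(jnoinc, models,
                                        require_inclusion = FALSE)$event_type,
               "ES")
})

# -- intron retention ------------------------------------------------------

test_that("intron retention applies the four strict gates", {
  # flat 40x intron, CDS count 300, raw-count denominator:
  # M=40>30, S=0<20, E=300>200, ratio 0.133>0.1 -> retained
  f <- ir_fixture(40, 300)
  calls <- call_intron_retention(f$genes, f$coverage, f$counts,
                                 ratio_mode = "raw-count")
  expect_true(calls$retained)
  expect_equal(calls$mean_bin_cov, 40)
  expect_equal(calls$sd_bin_cov, 0)
  expect_equal(calls$ratio, 40 / 300)

  # CDS count 150: T3 fails, everything else passes
  f2 <- ir_fixture(40, 150)
  expect_false(call_intron_retention(f2$genes, f2$coverage, f2$counts,
                                     ratio_mode = "raw-count")$retained)

  # alternating 0/80 bins: SD = 40 >= T2 fails
  f3 <- ir_fixture(NA, 300, pattern = rep(c(0, 80), each = 8))
  calls3 <- call_intron_retention(f3$genes, f3$coverage, f3$counts,
                                  ratio_mode = "raw-count")
  expect_equal(calls3$sd_bin_cov, 40)
  expect_false(calls3$retained)
})

test_that("values exactly at a threshold are rejected and epsilon flips the call", {
  thr <- ir_thresholds()
  run1 <- function(value, count, mode = "raw-count") {
    f <- ir_fixture(value, count)
    call_intron_retention(f$genes, f$coverage, f$counts, thr,
                          ratio_mode = mode)$retained
  }
  expect_false(run1(30, 250))           # M == T1, all other gates pass
  expect_true(run1(30 + 1e-6, 250))
  expect_false(run1(40, 200))           # E == T3
  expect_true(run1(40, 201))
  expect_false(run1(20, 200.0001))      # ratio 20/200 < ... and M<30
  expect_false(run1(35, 350))           # ratio == T4 exactly
  expect_true(run1(35.1, 350))
})

test_that("an intron shorter than one bin has a defined single-bin profile", {
  gene <- gene_record("gT", "chr1", "+", 101, 406,
                      cbind(c(101, 302), c(300, 406)))  # intron 301 only
  expect_equal(nrow(gene$introns), 1L)
  v <- numeric(500); v[101:406] <- 50
  calls <- call_intron_retention(
    list(gT = gene), list(s1 = coverage_track(list(chr1 = v), "s1")),
    matrix(500, 1, 1, dimnames = list("gT", "s1")), ratio_mode = "raw-count")
  expect_equal(calls$sd_bin_cov, 0)
  expect_equal(calls$mean_bin_cov, 50)
})

test_that("the packaged control intron is retained in exactly its two samples", {
  dir <- system.file("extdata", "ir_control_synthetic", package = "scvannotate")
  genes <- read_annotation(file.path(dir, "annotation.gff3"))
  samples <- sprintf("ctrl_%d", 1:6)
  cov <- setNames(lapply(samples, function(s)
    read_bedgraph(file.path(dir, sprintf("coverage_%s.bedGraph", s)), s,
                  seqlengths = c(chr1 = 2300L))), samples)
  counts <- read_count_table(file.path(dir, "counts.tsv"))
  calls <- call_intron_retention(genes, cov, counts)
  expect_equal(sort(calls$sample_id[calls$retained]), c("ctrl_3", "ctrl_4"))
  ev <- ir_events(calls)
  expect_equal(ev$samples, "ctrl_3,ctrl_4")
})

test_that("ASE summaries count genes once per type and track combinations", {
  events <- data.frame(
    event_type = c("A3SS", "A3SS", "IR", "A5SS"),
    gene_id = c("g1", "g1", "g1", "g2"), stringsAsFactors = FALSE)
  s <- summarize_ase(events)
  expect_equal(unname(s$genes_per_type["A3SS"]), 1L)
  expect_equal(unname(s$genes_per_type["A5SS"]), 1L)
  expect_equal(s$n_genes_any, 2L)
  expect_equal(as.integer(s$combinations["A3SS+IR"]), 1L)
  empty <- summarize_ase(data.frame(event_type = character(0),
                                    gene_id = character(0)))
  expect_equal(sum(empty$genes_per_type), 0L)
  expect_equal(empty$n_genes_any, 0L)
})
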