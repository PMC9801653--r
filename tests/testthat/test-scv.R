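test_that("predictions are assigned only on full single-CDS containment", {
  gA <- gene_record("gA", "chr1", "+", 101, 500, cbind(101, 500))
  gB <- gene_record("gB", "chr1", "+", 901, 1300, cbind(901, 1300))
  genes <- list(gA = gA, gB = gB)
  preds <- rbind(
    example_prediction(gA, 50, 600, sample = "s1", tid = "full"),
    example_prediction(gA, 150, 600, sample = "s1", tid = "partial"),
    prediction_table("spanner", "chr1", "+", 40, list(cbind(50, 1400)),
                     "s1", "A"),
    prediction_table("antisense", "chr1", "-", 40, list(cbind(50, 600)),
                     "s1", "A"))
  class(preds) <- c("prediction_table", "data.frame")
  asg <- assign_predictions(preds, genes)
  expect_equal(names(asg$assigned), "gA")
  expect_equal(asg$assigned$gA$transcript_id, "full")
  # partial cover, two-CDS spanner and antisense all stay unassigned
  expect_setequal(asg$unassigned$transcript_id,
                  c("partial", "spanner", "antisense"))
  # unstranded predictions are compatible with either strand
  dot <- prediction_table("dot", "chr1", ".", 40, list(cbind(60, 620)), "s1", "A")
  expect_equal(names(assign_predictions(dot, genes)$assigned), "gA")
})

test_that("scv_select retains predictions above the most restrictive threshold", {
  mk <- function(covs) prediction_table(
    paste0("t", seq_along(covs)), "chr1", "+", covs,
    lapply(seq_along(covs), function(i) cbind(100, 600)), "s1", "A")
  ladder <- default_scv_ladder()
  sel <- scv_select(mk(c(12, 55, 1200)), ladder)
  expect_equal(attr(sel, "threshold"), 1000)
  expect_equal(sel$avg_coverage, 1200)
  sel <- scv_select(mk(c(12, 15)), ladder)
  expect_equal(attr(sel, "threshold"), 10)
  expect_equal(sel$avg_coverage, c(12, 15))
  # below the smallest rung: the gene gets no model
  sel <- scv_select(mk(c(4, 7)), ladder)
  expect_equal(nrow(sel), 0L)
  expect_true(is.na(attr(sel, "threshold")))
  # a coverage exactly at a rung passes (inclusive comparison)
  sel <- scv_select(mk(c(1000, 999)), ladder)
  expect_equal(attr(sel, "threshold"), 1000)
  expect_error(scv_select(mk(10), numeric(0)), "non-empty")
})

test_that("scv_select agrees with the exhaustive per-threshold oracle", {
  set.seed(42)
  ladder <- default_scv_ladder()
  for (rep in 1:50) {
    n <- sample(1:40, 1)
    covs <- round(exp(runif(n, log(1), log(40000))), 1)
    if (rep %% 5 == 0) covs[1] <- sample(ladder, 1)  # exact-at-rung cases
    p <- prediction_table(paste0("t", 1:n), "chr1", "+", covs,
                          lapply(1:n, function(i) cbind(1, 10)), "s", "A")
    sel <- scv_select(p, ladder)
    orc <- scv_oracle(covs, ladder)
    expect_equal(sort(match(sel$transcript_id, p$transcript_id)), orc$selected)
    expect_equal(attr(sel, "threshold"), orc$threshold)
  }
})

test_that("selection responds monotonically to adding or removing predictions", {
  set.seed(7)
  ladder <- default_scv_ladder()
  for (rep in 1:20) {
    covs <- round(exp(runif(8, log(5), log(30000))), 1)
    tstar <- scv_oracle(covs, ladder)$threshold
    # adding a prediction above the current maximum can only raise t*
    t_add <- scv_oracle(c(covs, max(covs) * 2.5), ladder)$threshold
    expect_true(is.na(tstar) || t_add >= tstar)
    # removing a prediction can only lower (or keep) t*
    t_rm <- scv_oracle(covs[-which.max(covs)], ladder)$threshold
    expect_true(is.na(t_rm) || t_rm <= tstar)
  }
})

test_that("gene models carry strand-aware UTRs, TSS/TES sets and classes", {
  gene <- example_gene()  # + strand, CDS 1001-2500
  m <- build_gene_model(gene, example_prediction(gene, 726, 2803))
  expect_equal(unname(m$longest_utr5), c(726, 1000))   # 275 bp
  expect_equal(unname(m$longest_utr3), c(2501, 2803))  # 303 bp
  expect_equal(diff(unname(m$longest_utr5)) + 1L, 275L)
  expect_equal(diff(unname(m$longest_utr3)) + 1L, 303L)
  expect_equal(m$tss$position, 726)
  expect_equal(m$tes$position, 2803)
  expect_equal(m$multiplicity_class, "single")

  sel2 <- rbind(example_prediction(gene, 726, 2803, sample = "s1"),
                example_prediction(gene, 800, 2803, sample = "s2"))
  class(sel2) <- c("prediction_table", "data.frame")
  m2 <- build_gene_model(gene, sel2)
  expect_equal(nrow(m2$tss), 2L)
  expect_equal(nrow(m2$tes), 1L)
  expect_equal(m2$multiplicity_class, "multi_TSS_only")
  expect_equal(m2$tes$support[[1]]$sample_id, c("s1", "s2"))

  gneg <- gene_record("gN", "chr1", "-", 1001, 2500, cbind(1001, 2500))
  m3 <- build_gene_model(gneg, example_prediction(gneg, 900, 2600))
  expect_equal(unname(m3$utr5[1, ]), c(2501, 2600))
  expect_equal(unname(m3$utr3[1, ]), c(900, 1000))
  expect_equal(m3$tss$position, 2600)
  expect_equal(m3$tes$position, 900)
})

test_that("UTR and CDS lengths add up to the transcript span for single-exon genes", {
  set.seed(5)
  for (i in 1:20) {
    cs <- sample(500:1000, 1); ce <- cs + sample(300:2000, 1)
    g <- gene_record("g", "chr1", sample(c("+", "-"), 1), cs, ce, cbind(cs, ce))
    u5 <- sample(10:400, 1); u3 <- sample(10:400, 1)
    start <- if (g$strand == "+") cs - u5 else cs - u3
    end <- if (g$strand == "+") ce + u3 else ce + u5
    m <- build_gene_model(g, example_prediction(g, start, end))
    w <- function(x) diff(unname(x)) + 1L
    expect_equal(w(m$longest_utr5) + (ce - cs + 1L) + w(m$longest_utr3),
                 end - start + 1L)
  }
})

test_that("TSS/TES merge tolerance collapses nearby boundaries", {
  gene <- example_gene()
  sel <- rbind(example_prediction(gene, 726, 2803, cov = 50, sample = "s1"),
               example_prediction(gene, 728, 2803, cov = 90, sample = "s2"))
  class(sel) <- c("prediction_table", "data.frame")
  expect_equal(build_gene_model(gene, sel)$multiplicity_class, "multi_TSS_only")
  m <- build_gene_model(gene, sel, merge_bp = 5L)
  expect_equal(m$multiplicity_class, "single")
  expect_equal(m$tss$position, 728)  # representative = max-coverage supporter
})

test_that("model summaries report UTR sizes, boundary distances and dataset sets", {
  gene <- example_gene()
  m1 <- build_gene_model(gene, example_prediction(gene, 823, 2803))  # 5'UTR 178
  s <- summarize_models(list(gA = m1))
  expect_equal(unname(s$utr5_single["median"]), 178)
  expect_equal(unname(s$utr5_single["mean"]), 178)
  expect_equal(unname(s$utr5_single["max"]), 178)

  # most distant TSS pair at {100, 256} on a synthetic gene: distance 156
  g2 <- gene_record("gB", "chr1", "+", 301, 700, cbind(301, 700))
  sel <- rbind(example_prediction(g2, 100, 900, sample = "s1"),
               example_prediction(g2, 256, 900, sample = "s2", dataset = "B"))
  class(sel) <- c("prediction_table", "data.frame")
  m2 <- build_gene_model(g2, sel)
  s2 <- summarize_models(list(gA = m1, gB = m2))
  expect_equal(unname(s2$tss_distance["mean"]), 156)
  expect_equal(unname(s2$tss_distance["n"]), 1)
  expect_equal(unname(s2$class_counts["multi_TSS_only"]), 1L, ignore_attr = TRUE)
  # dataset Venn: one gene supported by A only, one by A and B
  expect_equal(as.integer(s2$dataset_venn[c("A", "A+B")]), c(1L, 1L))
})

test_that("promoter windows are strand-aware and clamped at chromosome edges", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep(c("A", "C", "G", "T"), length.out = 3000), collapse = "")))
  gplus <- example_gene()
  mplus <- build_gene_model(gplus, example_prediction(gplus, 726, 2803))
  w <- extract_promoter_windows(list(gA = mplus), genome, width = 200)
  expect_equal(names(w), "gA_TSS726")
  expect_equal(as.character(w[[1]]),
               as.character(Biostrings::subseq(genome[["chr1"]], 526, 725)))

  gneg <- gene_record("gN", "chr1", "-", 1001, 2500, cbind(1001, 2500))
  mneg <- build_gene_model(gneg, example_prediction(gneg, 900, 2600))
  wn <- extract_promoter_windows(list(gN = mneg), genome, width = 200)
  expect_equal(as.character(wn[[1]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(genome[["chr1"]], 2601, 2800))))

  # TSS close to the chromosome start: truncated window plus a warning
  gsmall <- gene_record("gS", "chr1", "+", 60, 180, cbind(60, 180))
  msmall <- build_gene_model(gsmall, example_prediction(gsmall, 50, 200))
  expect_warning(ws <- extract_promoter_windows(list(gS = msmall), genome, 200),
                 "truncated")
  expect_equal(Biostrings::width(ws)[[1]], 49L)
  expect_error(extract_promoter_windows(
    list(gA = mplus), Biostrings::DNAStringSet(c(chrX = "ACGT")), 200),
    "chr1")
})
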