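two_genes <- function() {
  list(gA = gene_record("gA", "chr1", "+", 1001, 2500, cbind(1001, 2500)),
       gB = gene_record("gB", "chr1", "+", 5001, 6500, cbind(5001, 6500)))
}

upred <- function(tid, start, end, cov, strand = ".", sample = "s1") {
  prediction_table(tid, "chr1", strand, cov, list(cbind(start, end)),
                   sample, "A")
}

test_that("nTAR detection applies the inclusive coverage floor and overlap classes", {
  genes <- two_genes()
  feats <- gene_features(genes, "cds")
  preds <- rbind(upred("inter", 3000, 4000, 35),
                 upred("low", 3000, 4000, 9),
                 upred("edge", 3000, 4000, 10),
                 upred("partial", 2000, 3000, 50))
  class(preds) <- c("prediction_table", "data.frame")
  n <- detect_ntars(preds, feats)
  # cov 9 dropped; cov 10 kept (equal or higher than 10)
  expect_equal(sort(n$avg_coverage[n$overlap_class == "none"]), c(10, 35))
  expect_equal(n$avg_coverage[n$overlap_class == "partial_gene"], 50)
  # partition: every kept prediction lands in exactly one class
  expect_equal(nrow(n), 3L)
  expect_true(all(n$overlap_class %in% c("none", "partial_gene")))
})

test_that("merging collapses nested and overlapping intervals and is idempotent", {
  ntars <- data.frame(
    ntar_id = c("a", "b", "c"), chrom = "chr1", strand = ".",
    start = c(100L, 200L, 500L), end = c(500L, 400L, 700L),
    avg_coverage = c(20, 80, 15), overlap_class = "none",
    source_samples = c("s1", "s2", "s1"), stringsAsFactors = FALSE)
  m <- merge_nested(ntars)
  expect_equal(nrow(m), 1L)  # (100,500)+(200,400)+(500,700) chain-overlap
  expect_equal(m$start, 100L)
  expect_equal(m$end, 700L)
  expect_equal(m$avg_coverage, 80)
  expect_equal(m$source_samples, "s1,s2")

  disjoint <- ntars; disjoint$start <- c(100L, 601L, 901L)
  disjoint$end <- c(300L, 700L, 1000L)
  m2 <- merge_nested(disjoint)
  expect_equal(nrow(m2), 3L)
  # idempotence and pairwise non-overlap
  expect_equal(merge_nested(m2)[, c("chrom", "start", "end")],
               m2[, c("chrom", "start", "end")])
  o <- order(m2$start)
  expect_true(all(m2$start[o][-1] > m2$end[o][-nrow(m2)]))
})

test_that("spliced flags need a fully contained junction", {
  ntars <- data.frame(ntar_id = "n1", chrom = "chr1", strand = ".",
                      start = 1000L, end = 2200L, avg_coverage = 30,
                      overlap_class = "none", source_samples = "s1",
                      stringsAsFactors = FALSE)
  inside <- junction_table("chr1", 1400, 1500, ".", 3, "s1")
  expect_true(flag_spliced(ntars, inside)$spliced)
  overhang <- junction_table("chr1", 2100, 2300, ".", 3, "s1")
  expect_false(flag_spliced(ntars, overhang)$spliced)
  none <- junction_table(character(0), integer(0), integer(0),
                         character(0), numeric(0), character(0))
  expect_false(flag_spliced(ntars, none)$spliced)
})

test_that("NAT calls need opposite strand over exactly one CDS", {
  genes <- two_genes()  # both + strand
  anti <- upred("anti", 1500, 2800, 40, strand = "-")
  nats <- detect_nats(anti, genes)
  expect_equal(nrow(nats), 1L)
  expect_equal(nats$linked_gene, "gA")
  # sense transcript: never a NAT
  sense <- upred("sense", 1500, 2800, 40, strand = "+")
  expect_equal(nrow(detect_nats(sense, genes)), 0L)
  # spanning two CDS: never a NAT
  span <- upred("span", 1500, 5800, 40, strand = "-")
  expect_equal(nrow(detect_nats(span, genes)), 0L)
  # unstranded input is rejected outright
  expect_error(detect_nats(upred("dot", 1500, 2800, 40, strand = "."), genes),
               "strand")
})

test_that("size reports summarize length and spliced fractions", {
  ntars <- data.frame(ntar_id = c("a", "b"), chrom = "chr1", strand = ".",
                      start = c(1L, 1L), end = c(400L, 600L),
                      avg_coverage = 20, overlap_class = "none",
                      source_samples = "s1", spliced = c(TRUE, TRUE),
                      stringsAsFactors = FALSE)
  r <- size_report(ntars)
  expect_equal(r$fraction_short, 0.5)
  expect_equal(r$mean_length, 500)
  expect_equal(r$spliced_fraction, 1.0)
  empty <- size_report(ntars[0, ])
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean_length))
})
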