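test_that("simulation is deterministic under the seed", {
  a <- small_sim()
  b <- small_sim()
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$junctions, b$junctions)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$coverage, `[[`, "values"),
                   lapply(b$coverage, `[[`, "values"))
  c2 <- simulate_transcriptome(sim_config(n_genes = 80, n_chroms = 2,
                                          n_ntars = 10, n_nats = 6, seed = 12))
  expect_false(identical(a$predictions, c2$predictions))
})

test_that("planting rates of zero leave no multi-boundary genes in the truth", {
  sim <- simulate_transcriptome(sim_config(n_genes = 60, n_chroms = 1,
                                           p_alt_tss = 0, p_alt_tes = 0,
                                           n_ntars = 5, n_nats = 3,
                                           with_coverage = FALSE, seed = 2))
  expect_true(all(sim$truth$genes$multiplicity_class == "single"))
  expect_equal(nrow(sim$truth$tss), 60L)
})

test_that("the requested number of planted nTARs exists and avoids genes", {
  sim <- small_sim()
  expect_equal(nrow(sim$truth$ntars), 10L)
  feats <- gene_features(sim$genes, "cds")
  for (i in seq_len(nrow(sim$truth$ntars))) {
    n <- sim$truth$ntars[i, ]
    same <- feats[feats$chrom == n$chrom, ]
    expect_false(any(n$start <= same$end & n$end >= same$start))
  }
})

test_that("an infeasible nTAR request fails before writing anything", {
  expect_error(simulate_transcriptome(
    sim_config(n_genes = 10, n_chroms = 1, n_ntars = 500,
               with_coverage = FALSE, seed = 1)),
    "intergenic room")
})

test_that("simulated files re-read losslessly through the format readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_transcriptome(
    sim_config(n_genes = 30, n_chroms = 1, n_ntars = 4, n_nats = 3,
               n_partial = 2, seed = 5), out_dir = dir)
  genes2 <- read_annotation(file.path(dir, "annotation.gff3"))
  expect_setequal(names(genes2), names(sim$genes))
  for (g in names(sim$genes)) expect_equal(genes2[[g]], sim$genes[[g]])

  for (s in unique(sim$predictions$sample_id)) {
    orig <- sim$predictions[sim$predictions$sample_id == s, , drop = FALSE]
    ds <- orig$dataset_id[1]
    back <- read_predictions(file.path(dir, sprintf("predictions_%s.gtf", s)), s, ds)
    back <- back[match(orig$transcript_id, back$transcript_id), ]
    expect_equal(back$avg_coverage, orig$avg_coverage)
    expect_equal(lapply(back$exons, unname), lapply(orig$exons, unname))
    expect_equal(back$strand, orig$strand)
  }

  s1 <- unique(sim$junctions$sample_id)[1]
  orig_j <- sim$junctions[sim$junctions$sample_id == s1, , drop = FALSE]
  back_j <- read_junctions(file.path(dir, sprintf("junctions_%s.bed", s1)), s1)
  key <- function(j) sort(paste(j$chrom, j$start, j$end, j$strand, j$count))
  expect_equal(key(back_j), key(orig_j))

  cs <- names(sim$coverage)[1]
  back_c <- read_bedgraph(file.path(dir, sprintf("coverage_%s.bedGraph", cs)), cs,
                          seqlengths = sim$chrom_lengths)
  expect_equal(lapply(back_c$values, as.numeric),
               lapply(sim$coverage[[cs]]$values, as.numeric))

  expect_equal(read_count_table(file.path(dir, "counts.tsv")), sim$counts)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$genes$multiplicity_class, sim$truth$genes$multiplicity_class)
})

test_that("boundary jitter with zero tolerance cannot beat the noiseless run", {
  clean <- simulate_transcriptome(sim_config(n_genes = 60, n_chroms = 1,
                                             n_ntars = 5, n_nats = 3,
                                             with_coverage = FALSE, seed = 8))
  rep_clean <- evaluate_recovery(run_pipeline(clean), clean$truth)
  noisy <- simulate_transcriptome(sim_config(n_genes = 60, n_chroms = 1,
                                             n_ntars = 5, n_nats = 3,
                                             jitter_sd = 12,
                                             with_coverage = FALSE, seed = 8))
  rep_noisy <- evaluate_recovery(run_pipeline(noisy), noisy$truth)
  tssr <- function(r) r$metrics$recall[r$metrics$class == "TSS"]
  expect_equal(tssr(rep_clean), 1.0)
  expect_lte(tssr(rep_noisy), tssr(rep_clean))
})

test_that("the CLI wires simulate, scv and evaluate together", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "sim")
  expect_equal(run_cli(c("simulate", "--seed", "4", "--n-genes", "25",
                         "--n-chroms", "1", "--n-ntars", "3", "--n-nats", "2",
                         "--out-dir", out)), 0L)
  expect_true(file.exists(file.path(out, "annotation.gff3")))
  expect_true(file.exists(file.path(out, "simulate.manifest.json")))
  preds <- list.files(out, "^predictions_", full.names = TRUE)
  flags <- as.vector(rbind("--predictions",
                           sprintf("%s=%s", sub("predictions_(.*)\\.gtf", "\\1",
                                                basename(preds)), preds)))
  gff <- file.path(dir, "models.gff3")
  expect_equal(run_cli(c("scv", "--annotation", file.path(out, "annotation.gff3"),
                         flags, "--out-gff", gff)), 0L)
  models <- read_gene_models(gff)
  expect_gt(length(models), 0L)
  expect_equal(run_cli(c("evaluate", "--truth", file.path(out, "truth.json"),
                         "--results-dir", out)), 0L)
  # unknown subcommand and missing flags fail with a nonzero status
  expect_equal(run_cli("frobnicate"), 2L)
  expect_equal(suppressWarnings(run_cli(c("scv", "--annotation", "missing.gff3"))),
               1L)
})
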