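#' Run the full annotation pipeline on one input bundle
#'
#' Convenience orchestration over the module functions: SCV gene models,
#' junction-event classification, intron-retention calling (when coverage
#' tracks are available), and novel-transcript discovery (nTAR detection,
#' merging, splice flagging; NAT detection on the stranded subset of the
#' unassigned pool).
#'
#' @param sim A `sim_data` bundle from [simulate_transcriptome()], or any
#'   list with the same `genes`/`predictions`/`junctions`/`coverage`/
#'   `counts` components.
#' @param ladder SCV threshold ladder.
#' @param min_samples,min_cov Junction confidence filter parameters.
#' @param thr [ir_thresholds()] for intron retention.
#' @param ntar_min_cov Coverage floor for novel transcripts (default 10).
#' @param ratio_mode,read_length IR ratio normalization (see
#'   [call_intron_retention()]).
#' @return List of class `pipeline_result` with `models`, `unassigned`,
#'   `junction_events`, `ir_calls`, `ir_events`, `ntars` (merged class-none
#'   intervals with spliced flags), `ntar_candidates`, `nats`.
#' @export
run_pipeline <- function(sim, ladder = default_scv_ladder(),
                         min_samples = 2L, min_cov = 5,
                         thr = ir_thresholds(), ntar_min_cov = 10,
                         ratio_mode = "scaled", read_length = 100) {
  scv <- scv_annotate(sim$genes, sim$predictions, ladder = ladder)
  jev <- classify_junction_events(sim$junctions, scv$models,
                                  min_samples = min_samples, min_cov = min_cov)
  ir_calls <- NULL; irev <- NULL
  if (!is.null(sim$coverage)) {
    ir_calls <- call_intron_retention(sim$genes, sim$coverage, sim$counts,
                                      thr = thr, ratio_mode = ratio_mode,
                                      read_length = read_length)
    irev <- ir_events(ir_calls)
  }
  cand <- detect_ntars(scv$unassigned, gene_features(sim$genes, "cds"),
                       min_cov = ntar_min_cov)
  ntars <- merge_nested(cand[cand$overlap_class == "none", , drop = FALSE])
  ntars <- flag_spliced(ntars, sim$junctions)
  stranded <- scv$unassigned[scv$unassigned$strand %in% c("+", "-"), , drop = FALSE]
  nats <- if (nrow(stranded)) detect_nats(stranded, sim$genes,
                                          min_cov = ntar_min_cov)
          else NULL
  structure(list(models = scv$models, unassigned = scv$unassigned,
                 no_model = scv$no_model, junction_events = jev,
                 ir_calls = ir_calls, ir_events = irev,
                 ntar_candidates = cand, ntars = ntars, nats = nats),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_result> %d gene models, %d junction events, ",
                     "%d IR events, %d nTARs, %d NATs\n"),
              length(x$models), nrow(x$junction_events),
              if (is.null(x$ir_events)) 0L else nrow(x$ir_events),
              nrow(x$ntars), if (is.null(x$nats)) 0L else nrow(x$nats)))
  invisible(x)
}

.pr_row <- function(class, truth_keys, called_keys) {
  tp_r <- sum(truth_keys %in% called_keys)
  tp_p <- sum(called_keys %in% truth_keys)
  data.frame(class = class,
             n_truth = length(truth_keys), n_called = length(called_keys),
             recall = if (length(truth_keys)) tp_r / length(truth_keys) else NA_real_,
             precision = if (length(called_keys)) tp_p / length(called_keys) else NA_real_,
             stringsAsFactors = FALSE)
}

# match positions with tolerance: key = gene, value = positions
.match_positions <- function(truth_df, called_df, tolerance = 0L) {
  n_truth <- nrow(truth_df); n_called <- nrow(called_df)
  hit_t <- 0L
  for (i in seq_len(n_truth)) {
    p <- called_df$position[called_df$gene_id == truth_df$gene_id[i]]
    if (any(abs(p - truth_df$position[i]) <= tolerance)) hit_t <- hit_t + 1L
  }
  hit_c <- 0L
  for (i in seq_len(n_called)) {
    p <- truth_df$position[truth_df$gene_id == called_df$gene_id[i]]
    if (any(abs(p - called_df$position[i]) <= tolerance)) hit_c <- hit_c + 1L
  }
  c(recall = if (n_truth) hit_t / n_truth else NA_real_,
    precision = if (n_called) hit_c / n_called else NA_real_,
    n_truth = n_truth, n_called = n_called)
}

#' Compare pipeline outputs with planted ground truth
#'
#' Computes per-class precision and recall (TSS, TES, A5SS, A3SS, ES, IR,
#' nTAR, NAT; exact-coordinate matching with configurable tolerance),
#' multiplicity-class accuracy, and checks that every planted negative
#' control (one-criterion junction/IR violations, sense and two-gene
#' antisense transcripts) is absent from the calls.
#'
#' @param result A [run_pipeline()] result.
#' @param truth Ground-truth component of a `sim_data` bundle.
#' @param tolerance Coordinate tolerance in bp (default 0).
#' @return Object of class `recovery_report`: `$metrics` (per-class
#'   data.frame), `$multiplicity_accuracy`, `$negatives` (named counts of
#'   negative controls wrongly reported, all expected 0).
#' @export
evaluate_recovery <- function(result, truth, tolerance = 0L) {
  models <- result$models
  called_tss <- do.call(rbind, c(lapply(models, function(m)
    data.frame(gene_id = m$gene_id, position = m$tss$position)),
    list(data.frame(gene_id = character(0), position = integer(0)))))
  called_tes <- do.call(rbind, c(lapply(models, function(m)
    data.frame(gene_id = m$gene_id, position = m$tes$position)),
    list(data.frame(gene_id = character(0), position = integer(0)))))
  tss <- .match_positions(truth$tss, called_tss, tolerance)
  tes <- .match_positions(truth$tes, called_tes, tolerance)
  metrics <- rbind(
    data.frame(class = "TSS", n_truth = tss[["n_truth"]],
               n_called = tss[["n_called"]], recall = tss[["recall"]],
               precision = tss[["precision"]], stringsAsFactors = FALSE),
    data.frame(class = "TES", n_truth = tes[["n_truth"]],
               n_called = tes[["n_called"]], recall = tes[["recall"]],
               precision = tes[["precision"]], stringsAsFactors = FALSE))
  # multiplicity classes
  called_class <- vapply(models, `[[`, "", "multiplicity_class")
  tc <- truth$genes$multiplicity_class
  names(tc) <- truth$genes$gene_id
  ok <- vapply(names(tc), function(g)
    !is.na(called_class[g]) && called_class[g] == tc[g], TRUE)
  mult_acc <- mean(ok)
  # junction events
  jkey <- function(df) paste(df$event_type, df$gene_id, df$j1_start, df$j1_end,
                             df$j2_start, df$j2_end, df$exon_start, df$exon_end)
  tev <- truth$events
  for (ty in c("A5SS", "A3SS", "ES")) {
    tk <- if (!is.null(tev)) jkey(tev[tev$event_type == ty, , drop = FALSE])
          else character(0)
    ck <- jkey(result$junction_events[
      result$junction_events$event_type == ty, , drop = FALSE])
    metrics <- rbind(metrics, .pr_row(ty, tk, ck))
  }
  # IR: exact intron + exact retained-sample set
  irk <- function(df) paste(df$gene_id, df$start, df$end, df$samples)
  tk <- if (!is.null(truth$ir)) irk(truth$ir) else character(0)
  ck <- if (!is.null(result$ir_events)) irk(result$ir_events) else character(0)
  metrics <- rbind(metrics, .pr_row("IR", tk, ck))
  # nTARs: merged class-none intervals
  nk <- function(df) paste(df$chrom, df$start, df$end)
  tk <- if (!is.null(truth$ntars)) nk(truth$ntars) else character(0)
  metrics <- rbind(metrics, .pr_row("nTAR", tk, nk(result$ntars)))
  # NATs
  natk <- function(df) paste(df$chrom, df$start, df$end, df$linked_gene)
  tk <- if (!is.null(truth$nats)) natk(truth$nats) else character(0)
  ck <- if (!is.null(result$nats)) natk(result$nats) else character(0)
  metrics <- rbind(metrics, .pr_row("NAT", tk, ck))
  rownames(metrics) <- NULL
  # negative controls that leaked through
  neg <- c(junction = 0L, ir = 0L, nat_sense = 0L, nat_spanner = 0L,
           ntar_partial_as_none = 0L)
  if (!is.null(truth$junction_negatives)) {
    jn <- truth$junction_negatives
    je <- result$junction_events
    neg[["junction"]] <- sum(vapply(seq_len(nrow(jn)), function(i)
      any(je$gene_id == jn$gene_id[i] &
            ((!is.na(je$j1_start) & je$j1_start == jn$start[i] & je$j1_end == jn$end[i]) |
             (!is.na(je$j2_start) & je$j2_start == jn$start[i] & je$j2_end == jn$end[i]))),
      TRUE))
  }
  if (!is.null(truth$ir_negatives) && !is.null(result$ir_calls)) {
    irn <- truth$ir_negatives
    calls <- result$ir_calls
    neg[["ir"]] <- sum(vapply(seq_len(nrow(irn)), function(i)
      any(calls$gene_id == irn$gene_id[i] &
            calls$intron_index == irn$intron_index[i] &
            calls$sample_id == irn$sample_id[i] & calls$retained), TRUE))
  }
  if (!is.null(truth$nat_negatives) && !is.null(result$nats)) {
    nn <- truth$nat_negatives
    neg[["nat_sense"]] <- sum(nn$kind == "sense" &
                                nn$gene_id %in% result$nats$linked_gene)
    spn <- nn[nn$kind == "two_gene_spanner", , drop = FALSE]
    neg[["nat_spanner"]] <- sum(spn$gene_id %in% result$nats$linked_gene)
  }
  if (!is.null(truth$partials)) {
    pk <- paste(truth$partials$chrom, truth$partials$start, truth$partials$end)
    none <- result$ntar_candidates[
      result$ntar_candidates$overlap_class == "none", , drop = FALSE]
    neg[["ntar_partial_as_none"]] <- sum(pk %in% nk(none))
  }
  structure(list(metrics = metrics, multiplicity_accuracy = mult_acc,
                 negatives = neg, tolerance = tolerance),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery vs planted truth (tolerance %d bp):\n", x$tolerance))
  print(x$metrics, row.names = FALSE)
  cat(sprintf("Multiplicity-class accuracy: %.4f\n", x$multiplicity_accuracy))
  cat("Negative controls wrongly reported (expect all 0):\n")
  print(x$negatives)
  invisible(x)
}
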