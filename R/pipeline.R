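# End-to-end orchestration: AUC records -> %RA -> L/H ratios -> total marks ->
# group statistics.

#' Run the quantitative analysis on an AUC table
#'
#' The standard downstream pipeline: percent relative abundance per channel,
#' per-form L/H ratio matrix, group-mean normalization, log2 transform,
#' feature-wise group comparison, total-mark aggregation and mark-level
#' comparison, plus a mark fold-change estimate (mean tumor ratio over mean
#' normal ratio).
#'
#' @param auc_records data.frame `sample_id`, `family_id`, `form_id`,
#'   `channel`, `auc`.
#' @param metadata data.frame `sample_id`, `group`, optional `pair_id`.
#' @param marks Mark registry (default [builtin_marks()]).
#' @param group_a,group_b Compared groups, direction A vs B (defaults
#'   `"tumor"` vs `"normal"`).
#' @param paired Paired comparisons using `metadata$pair_id`?
#' @return List: `ra` (long %RA records), `form_ratios` (samples x forms L/H
#'   matrix), `form_results`, `mark_records`, `mark_ratios`, `mark_results`,
#'   `fold_change` (named per mark).
#' @export
analyze_cohort <- function(auc_records, metadata, marks = builtin_marks(),
                           group_a = "tumor", group_b = "normal",
                           paired = FALSE) {
  ra <- relative_abundance(auc_records)
  ratios <- lh_ratio(ra)
  ratios <- ratios[metadata$sample_id, , drop = FALSE]
  groups <- metadata$group
  log_ratios <- log2_transform(normalize_ratios(ratios))
  form_results <- compare_groups(log_ratios, groups, group_a, group_b,
                                 paired = paired,
                                 pair_ids = metadata$pair_id)
  mark_records <- aggregate_marks(ra, marks)
  mk <- mark_ratio_matrix(mark_records)[metadata$sample_id, , drop = FALSE]
  mark_results <- compare_groups(log2_transform(mk), groups, group_a, group_b,
                                 paired = paired,
                                 pair_ids = metadata$pair_id)
  fold_change <- vapply(colnames(mk), function(m) {
    mean(mk[groups == group_a, m], na.rm = TRUE) /
      mean(mk[groups == group_b, m], na.rm = TRUE)
  }, 0)
  list(ra = ra, form_ratios = ratios, form_results = form_results,
       mark_records = mark_records, mark_ratios = mk,
       mark_results = mark_results, fold_change = fold_change)
}

#' Quantify simulated (or real) peak tables for a set of runs
#'
#' Applies [quantify_run()] to each run in a combined peak table and stacks
#' the per-run AUC records into the input format of [analyze_cohort()].
#'
#' @param peaks data.frame `run_id`, `rt`, `mz`, `intensity`.
#' @param library Peptidoform library.
#' @param expected_rt data.frame `family_id`, `form_id`, `rt`.
#' @param config List from [quant_config()].
#' @return data.frame `sample_id`, `family_id`, `form_id`, `channel`, `auc`,
#'   `flag`.
#' @export
quantify_runs <- function(peaks, library, expected_rt,
                          config = quant_config()) {
  out <- lapply(unique(peaks$run_id), function(id) {
    res <- quantify_run(peaks[peaks$run_id == id, , drop = FALSE], library,
                        expected_rt, config)
    cbind(sample_id = id, res, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
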