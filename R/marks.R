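# Single-residue "total mark" scores: named sums of combinatorial
# peptidoforms within one peptide family.

#' Built-in total-mark definitions
#'
#' The standard single-residue aggregates: total H3K14ac (sum of H3K14ac,
#' H3K9me1/K14ac, H3K9me2/K14ac, H3K9me3/K14ac and H3K9ac/K14ac), total
#' H3K9me3 (H3K9me3 + H3K9me3/K14ac) and total H3K27me3 (H3K27me3 +
#' H3K27me3/K36me1). The registry is an ordinary named list and can be
#' extended or replaced by the user.
#'
#' @return Named list of mark definitions; each has `name`, `family_id` and
#'   `members` (peptidoform `form_id`s within that family).
#' @export
builtin_marks <- function() {
  list(
    total_H3K14ac = list(
      name = "total_H3K14ac", family_id = "9-17",
      members = c("K14ac", "K9me1K14ac", "K9me2K14ac", "K9me3K14ac",
                  "K9acK14ac")),
    total_H3K9me3 = list(
      name = "total_H3K9me3", family_id = "9-17",
      members = c("K9me3", "K9me3K14ac")),
    total_H3K27me3 = list(
      name = "total_H3K27me3", family_id = "27-40",
      members = c("K27me3", "K27me3K36me1"))
  )
}

.validate_mark <- function(mark) {
  stopifnot(is.list(mark), !is.null(mark$name), !is.null(mark$family_id))
  if (length(mark$members) == 0 || anyDuplicated(mark$members)) {
    stop("mark '", mark$name, "' must have non-empty, distinct members")
  }
  mark
}

#' Aggregate peptidoform %RA into total-mark scores
#'
#' Per sample and channel, a mark's %RA is the sum of its member peptidoforms'
#' %RA; members missing in a sample contribute 0 as long as at least one
#' member is observed (no member observed gives a missing mark). The mark L/H
#' ratio is then the ratio of the summed channel values (`"ratio_of_sums"`,
#' default, which is invariant to independent channel rescaling) or the mean
#' of per-member L/H ratios (`"mean_of_ratios"`, for sensitivity analysis).
#'
#' @param ra_records Output of [relative_abundance()].
#' @param marks List of mark definitions; defaults to [builtin_marks()].
#' @param mode Aggregation mode, see above.
#' @return data.frame `sample_id`, `mark`, `light_ra`, `heavy_ra`, `lh_ratio`,
#'   `n_missing` (member count unobserved in either channel).
#' @export
aggregate_marks <- function(ra_records, marks = builtin_marks(),
                            mode = c("ratio_of_sums", "mean_of_ratios")) {
  mode <- match.arg(mode)
  marks <- lapply(marks, .validate_mark)
  samples <- unique(ra_records$sample_id)
  out <- list()
  for (mark in marks) {
    sub <- ra_records[ra_records$family_id == mark$family_id &
                        ra_records$form_id %in% mark$members, , drop = FALSE]
    for (s in samples) {
      ss <- sub[sub$sample_id == s, , drop = FALSE]
      chan_sum <- function(channel) {
        v <- ss$rel_abundance[ss$channel == channel]
        if (all(is.na(v)) || length(v) == 0) NA_real_ else sum(v, na.rm = TRUE)
      }
      light <- chan_sum("light")
      heavy <- chan_sum("heavy")
      ratio <- if (mode == "ratio_of_sums") {
        if (is.na(light) || is.na(heavy) || heavy == 0) NA_real_
        else light / heavy
      } else {
        lv <- ss$rel_abundance[ss$channel == "light"][
          match(mark$members, ss$form_id[ss$channel == "light"])]
        hv <- ss$rel_abundance[ss$channel == "heavy"][
          match(mark$members, ss$form_id[ss$channel == "heavy"])]
        r <- lv / hv
        if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
      }
      n_missing <- sum(is.na(ss$rel_abundance)) +
        2 * length(setdiff(mark$members, unique(ss$form_id)))
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, mark = mark$name, light_ra = light, heavy_ra = heavy,
        lh_ratio = ratio, n_missing = n_missing, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Samples x marks L/H ratio matrix
#'
#' @param mark_records Output of [aggregate_marks()].
#' @return Numeric matrix of mark L/H ratios, samples in rows.
#' @export
mark_ratio_matrix <- function(mark_records) {
  samples <- unique(mark_records$sample_id)
  marks <- unique(mark_records$mark)
  m <- matrix(NA_real_, length(samples), length(marks),
              dimnames = list(samples, marks))
  m[cbind(match(mark_records$sample_id, samples),
          match(mark_records$mark, marks))] <- mark_records$lh_ratio
  m
}
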