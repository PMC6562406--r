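# Relative-abundance statistics: %RA per channel, super-SILAC light/heavy
# ratios, cross-sample normalization, log2 transform and condition-vs-condition
# ratios of ratios.

#' Percent relative abundance of peptidoforms
#'
#' For each sample x family x channel, divides the AUC of each observed form
#' by the summed AUCs of all observed forms of that family and multiplies by
#' 100. Forms missing in a sample are excluded from that sample's denominator.
#'
#' @param auc_records data.frame with columns `sample_id`, `family_id`,
#'   `form_id`, `channel`, `auc` (`NA` = not observed).
#' @return The input with an added `rel_abundance` column in percent
#'   (`NA` where the form, or the whole family, was not observed).
#' @export
relative_abundance <- function(auc_records) {
  need <- c("sample_id", "family_id", "channel", "form_id", "auc")
  stopifnot(all(need %in% names(auc_records)))
  grp <- interaction(auc_records$sample_id, auc_records$family_id,
                     auc_records$channel, drop = TRUE)
  tot <- tapply(auc_records$auc, grp, function(a) sum(a, na.rm = TRUE))
  denom <- as.numeric(tot[as.character(grp)])
  ra <- 100 * auc_records$auc / denom
  ra[!is.finite(ra)] <- NA_real_
  auc_records$rel_abundance <- ra
  auc_records
}

.feature_id <- function(family_id, form_id) paste(family_id, form_id)

#' Light/heavy ratio matrix of relative abundances
#'
#' Computes per-form L/H ratios of %RA, with the %RA of each channel computed
#' independently. Heavy forms without a light counterpart are not considered
#' for quantification (the ratio is dropped); light forms without a heavy
#' counterpart are kept as missing ratios.
#'
#' @param ra_records Output of [relative_abundance()].
#' @return Numeric matrix, samples x features (feature =
#'   `"<family_id> <form_id>"`), values L/H ratios or `NA`.
#' @export
lh_ratio <- function(ra_records) {
  feat <- .feature_id(ra_records$family_id, ra_records$form_id)
  samples <- unique(ra_records$sample_id)
  features <- unique(feat)
  get_mat <- function(channel) {
    sub <- ra_records[ra_records$channel == channel, , drop = FALSE]
    m <- matrix(NA_real_, length(samples), length(features),
                dimnames = list(samples, features))
    m[cbind(match(sub$sample_id, samples),
            match(.feature_id(sub$family_id, sub$form_id), features))] <-
      sub$rel_abundance
    m
  }
  light <- get_mat("light")
  heavy <- get_mat("heavy")
  ratio <- light / heavy
  ratio[!is.na(heavy) & heavy == 0] <- NA_real_
  ratio
}

#' Normalize a ratio matrix over the sample mean
#'
#' Each value is divided by the mean of the present (non-missing) values of
#' its column, either across all samples or within sample groups (e.g. within
#' each tumor type). Column means of present values become 1 within each
#' scope; the operation is idempotent.
#'
#' @param mat Samples x features ratio matrix.
#' @param groups Optional factor/character vector of length `nrow(mat)`; when
#'   given, normalization is carried out within each group separately.
#' @return Normalized matrix of the same shape.
#' @export
normalize_ratios <- function(mat, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", nrow(mat))
  stopifnot(length(groups) == nrow(mat))
  out <- mat
  for (g in unique(groups)) {
    rows <- which(groups == g)
    mu <- colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)
    mu[is.nan(mu)] <- NA_real_
    out[rows, ] <- sweep(mat[rows, , drop = FALSE], 2, mu, "/")
  }
  out
}

#' Elementwise log2 transform
#'
#' @param mat Matrix of positive ratios (missing values allowed).
#' @return log2-transformed matrix; missing values preserved.
#' @export
log2_transform <- function(mat) {
  bad <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive value at [", bad[1, 1], ", ", bad[1, 2],
         "]; log2 requires values > 0")
  }
  log2(mat)
}

#' Condition-vs-condition ratio of ratios
#'
#' Divides matched L/H ratios of condition A by condition B (e.g. G2-M
#' synchronized over G1-S synchronized cells), elementwise per replicate pair.
#'
#' @param mat_a,mat_b Ratio matrices with identical dimensions and dimnames
#'   (rows are matched replicate pairs).
#' @return Matrix of A/B ratios; missing wherever either side is missing.
#' @export
condition_ratio <- function(mat_a, mat_b) {
  if (!identical(dim(mat_a), dim(mat_b)) ||
      !identical(colnames(mat_a), colnames(mat_b))) {
    stop("condition matrices must have matched dimensions and columns")
  }
  mat_a / mat_b
}
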