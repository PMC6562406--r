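# Group statistics: Student's t tests with significance tiers, Ki-67
# correlation with the display rule, PCA under an explicit missing-value
# policy, correlation-distance UPGMA clustering, Benjamini-Hochberg FDR.

.tier <- function(p) {
  if (is.na(p)) NA_character_
  else if (p < 0.05) "dark"
  else if (p < 0.1) "light"
  else "none"
}

#' Two-group Student's t test with direction and display tier
#'
#' Two-sided Student's t test, pooled variance by default (Welch via
#' `var_equal = FALSE`), or a paired t test on complete pairs. Identical
#' paired vectors (all differences zero) use the convention t = 0, p = 1.
#' With insufficient data the result is flagged not computable.
#'
#' @param a,b Numeric vectors (group A and B; for `paired = TRUE` they must be
#'   matched by position and incomplete pairs are dropped).
#' @param paired Paired test?
#' @param var_equal Pooled-variance (classic Student) test? Default `TRUE`.
#' @return List: `t`, `p`, `direction` (`"increase"`/`"decrease"` of A vs B),
#'   `tier` (`"dark"` p < 0.05, `"light"` p < 0.1, `"none"`), `computable`.
#' @export
ptm_ttest <- function(a, b, paired = FALSE, var_equal = TRUE) {
  if (paired) {
    stopifnot(length(a) == length(b))
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    enough <- length(a) >= 2
  } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    enough <- length(a) >= 2 && length(b) >= 2
  }
  if (!enough) {
    return(list(t = NA_real_, p = NA_real_, direction = NA_character_,
                tier = NA_character_, computable = FALSE))
  }
  delta <- mean(a) - mean(b)
  direction <- if (delta >= 0) "increase" else "decrease"
  if (paired && all(a == b)) {
    return(list(t = 0, p = 1, direction = direction, tier = "none",
                computable = TRUE))
  }
  tt <- tryCatch(
    stats::t.test(a, b, paired = paired, var.equal = var_equal),
    error = function(e) NULL)
  if (is.null(tt)) {
    return(list(t = NA_real_, p = NA_real_, direction = direction,
                tier = NA_character_, computable = FALSE))
  }
  list(t = unname(tt$statistic), p = tt$p.value, direction = direction,
       tier = .tier(tt$p.value), computable = TRUE)
}

#' Feature-wise group comparison of a ratio matrix
#'
#' Applies [ptm_ttest()] to every column of a samples x features matrix,
#' comparing `group_a` against `group_b` samples.
#'
#' @param mat Samples x features numeric matrix.
#' @param groups Group label per row of `mat`.
#' @param group_a,group_b Labels to compare (direction is A vs B).
#' @param paired Paired test? Requires `pair_ids`.
#' @param pair_ids Pair identifier per row; paired tests match A and B samples
#'   sharing a pair id.
#' @param var_equal Pooled-variance test? Default `TRUE`.
#' @return data.frame `feature`, `mean_a`, `mean_b`, `t`, `p`, `direction`,
#'   `tier`, `computable`.
#' @export
compare_groups <- function(mat, groups, group_a, group_b, paired = FALSE,
                           pair_ids = NULL, var_equal = TRUE) {
  stopifnot(length(groups) == nrow(mat))
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (paired) {
    stopifnot(!is.null(pair_ids), length(pair_ids) == nrow(mat))
    common <- intersect(pair_ids[ia], pair_ids[ib])
    ia <- ia[match(common, pair_ids[ia])]
    ib <- ib[match(common, pair_ids[ib])]
  }
  rows <- lapply(colnames(mat), function(f) {
    res <- ptm_ttest(mat[ia, f], mat[ib, f], paired = paired,
                     var_equal = var_equal)
    data.frame(feature = f,
               mean_a = mean(mat[ia, f], na.rm = TRUE),
               mean_b = mean(mat[ib, f], na.rm = TRUE),
               t = res$t, p = res$p, direction = res$direction,
               tier = res$tier, computable = res$computable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation with the Ki-67 proliferation index
#'
#' Pairwise-complete Pearson correlation with a two-sided p value from the t
#' transform. `display` is `TRUE` when r exceeds `display_threshold` (the
#' value is literally compared, not its absolute value; set
#' `absolute = TRUE` for the |r| variant).
#'
#' @param values Feature values per sample (e.g. L/H ratios).
#' @param ki67 Ki-67 percentages per sample.
#' @param display_threshold Display rule threshold on r (default 0.4).
#' @param absolute Apply the threshold to |r|?
#' @return List `r`, `p`, `n`, `display`, `significant` (p < 0.05),
#'   `computable`.
#' @export
ki67_correlation <- function(values, ki67, display_threshold = 0.4,
                             absolute = FALSE) {
  stopifnot(length(values) == length(ki67))
  keep <- !is.na(values) & !is.na(ki67)
  x <- values[keep]; y <- ki67[keep]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), display = FALSE,
                significant = FALSE, computable = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  shown <- if (absolute) abs(r) > display_threshold else r > display_threshold
  list(r = r, p = ct$p.value, n = length(x), display = shown,
       significant = ct$p.value < 0.05, computable = TRUE)
}

#' PCA with an explicit missing-value policy
#'
#' Before the decomposition: (1) samples with more than `max_sample_missing`
#' missing values are removed; (2) features with no valid value in at least
#' one group, or with more than `max_feature_missing` missing values, are
#' removed; (3) remaining missing values are substituted with the feature's
#' average across all retained samples. Columns are centered (not scaled) and
#' decomposed with [stats::prcomp()].
#'
#' @param mat Samples x features matrix with missing values.
#' @param groups Group label per sample (the "categories" of the policy).
#' @param max_sample_missing Sample filter threshold (default 10).
#' @param max_feature_missing Feature filter threshold (default 5).
#' @return List: `scores`, `loadings`, `explained` (variance fractions),
#'   `samples`, `features` (retained identifiers).
#' @export
pca_with_policy <- function(mat, groups, max_sample_missing = 10,
                            max_feature_missing = 5) {
  stopifnot(length(groups) == nrow(mat))
  keep_s <- rowSums(is.na(mat)) <= max_sample_missing
  m <- mat[keep_s, , drop = FALSE]
  g <- groups[keep_s]
  if (nrow(m) < 2) stop("fewer than 2 samples remain after filtering")
  n_na <- colSums(is.na(m))
  none_in_group <- vapply(seq_len(ncol(m)), function(j) {
    any(vapply(unique(g), function(gr) all(is.na(m[g == gr, j])), TRUE))
  }, TRUE)
  keep_f <- !none_in_group & n_na <= max_feature_missing
  m <- m[, keep_f, drop = FALSE]
  if (ncol(m) == 0) stop("no features remain after filtering")
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j], na.rm = TRUE)
    m[is.na(m[, j]), j] <- mu
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, explained = expl,
       samples = rownames(mat)[keep_s], features = colnames(mat)[keep_f])
}

#' Hierarchical clustering with correlation distance and average linkage
#'
#' Distance is 1 - Pearson correlation (pairwise complete observations),
#' merged by UPGMA (average linkage). Items with undefined correlations
#' (constant profiles) are excluded and reported.
#'
#' @param mat Samples x features matrix.
#' @param margin Cluster `"rows"` (samples, default) or `"cols"` (features).
#' @return List: `hclust` (an [stats::hclust] object), `excluded` (dropped
#'   item names).
#' @export
hcluster_corr <- function(mat, margin = c("rows", "cols")) {
  margin <- match.arg(margin)
  x <- if (margin == "rows") t(mat) else mat
  keep <- apply(x, 2, function(v) stats::sd(v, na.rm = TRUE) > 0 &&
                  sum(!is.na(v)) >= 2)
  excluded <- colnames(x)[!keep]
  x <- x[, keep, drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 items with non-constant profiles")
  d <- stats::as.dist(1 - stats::cor(x, use = "pairwise.complete.obs"))
  if (anyNA(d)) stop("undefined pairwise correlation between retained items")
  list(hclust = stats::hclust(d, method = "average"), excluded = excluded)
}

#' Write a dendrogram in Newick format
#'
#' @param hc An [stats::hclust] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up BH adjustment with pass flags at the given FDR cutoff.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @param cutoff FDR cutoff for the pass flags (default 0.05).
#' @return data.frame `p`, `padj`, `pass`.
#' @export
bh_fdr <- function(p, cutoff = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p values must lie in [0, 1] with no missing values")
  }
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, padj = padj, pass = padj < cutoff)
}
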