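# Synthetic cohorts with known ground truth: group-level fold changes on total
# marks, a fixed heavy spike-in profile, multiplicative lognormal intensity
# noise, a Ki-67 covariate linked to a chosen mark, and simulated centroided
# MS1 peak tables for the XIC stage.

#' Default baseline %RA profiles per peptide family
#'
#' Plausible resting-tissue relative abundances for every peptidoform in the
#' default H3 library; each family sums to 100. These are the package's own
#' choice of realistic values (the assay's real inter-sample profiles are not
#' part of the package), every form is given non-zero abundance so that
#' isobaric sets are exercised.
#'
#' @return Named list (by family id) of named numeric vectors (by form id).
#' @export
default_baseline <- function() {
  list(
    "3-8" = c(unmod = 78, K4me1 = 12, K4me2 = 6, K4me3 = 2, K4ac = 2),
    "9-17" = c(unmod = 28, K14ac = 15, K9me1 = 10, K9me1K14ac = 5,
               K9me2 = 14, K9me2K14ac = 3, K9me3 = 12, K9me3K14ac = 2,
               K9ac = 9, K9acK14ac = 2),
    "18-26" = c(unmod = 50, K23ac = 20, K18ac = 14, K18acK23ac = 8,
                K18me1 = 6, K18me1K23ac = 2),
    "27-40" = c(unmod = 8, K36me1 = 5, K36me2 = 6, K36me3 = 3,
                K27me1 = 14, K27me1K36me1 = 4, K27me1K36me2 = 3,
                K27me1K36me3 = 1,
                K27me2 = 16, K27me2K36me1 = 3, K27me2K36me2 = 2,
                K27me2K36me3 = 1,
                K27me3 = 18, K27me3K36me1 = 6, K27me3K36me2 = 2,
                K27me3K36me3 = 1,
                K27ac = 4, K27acK36me1 = 1.5, K27acK36me2 = 1,
                K27acK36me3 = 0.5),
    "73-83" = c(unmod = 72, K79me1 = 14, K79me2 = 9, K79me3 = 2, K79ac = 3)
  )
}

#' Cohort simulation configuration
#'
#' @param n_per_group Named integer vector of group sizes
#'   (default `c(normal = 8, tumor = 8)`).
#' @param fold_changes Named vector of tumor-vs-normal fold changes applied to
#'   the member peptidoforms of the named total marks (family renormalized to
#'   100 afterwards). Default: total H3K14ac halved, total H3K9me3 increased
#'   1.5-fold, the direction of change seen in tissues.
#' @param baseline Baseline light-channel %RA profiles, see
#'   [default_baseline()].
#' @param heavy_profile Spike-in %RA profiles, identical for every sample
#'   (default: the baseline, emulating an equal-part heavy mixture).
#' @param marks Mark registry resolving `fold_changes` names to members.
#' @param noise_sd Lognormal AUC noise, standard deviation on the log2 scale
#'   (default 0.2).
#' @param sample_scale_sd Per-sample global loading factor, log2 sd (default
#'   0.25); cancels in %RA by construction.
#' @param auc_scale Global AUC scale (arbitrary area units, default 1e6).
#' @param missing_rate Probability that an observed form is dropped from a
#'   sample/channel (default 0).
#' @param ki67 List: `mean` (named per group, percent), `sd` (residual sd),
#'   `link_mark`, `link_r` (target Pearson r with the linked mark),
#'   `bio_sd` (per-sample biological log2 sd on the linked mark members).
#' @param paired Give matched pair ids to normal/tumor samples?
#' @return Config list for [generate_cohort()].
#' @export
cohort_config <- function(n_per_group = c(normal = 8, tumor = 8),
                          fold_changes = c(total_H3K14ac = 0.5,
                                           total_H3K9me3 = 1.5),
                          baseline = default_baseline(),
                          heavy_profile = NULL,
                          marks = builtin_marks(),
                          noise_sd = 0.2,
                          sample_scale_sd = 0.25,
                          auc_scale = 1e6,
                          missing_rate = 0,
                          ki67 = list(mean = c(normal = 15, tumor = 45),
                                      sd = 8, link_mark = "total_H3K9me3",
                                      link_r = 0.6, bio_sd = 0.3),
                          paired = TRUE) {
  stopifnot(all(n_per_group >= 1), noise_sd >= 0, sample_scale_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (any(fold_changes <= 0)) stop("fold changes must be > 0")
  for (fam in names(baseline)) {
    if (abs(sum(baseline[[fam]]) - 100) > 1e-6) {
      stop("baseline %RA of family ", fam, " must sum to 100")
    }
  }
  bad <- setdiff(names(fold_changes), names(marks))
  if (length(bad) > 0) stop("fold change on unknown mark(s): ",
                            paste(bad, collapse = ", "))
  if (is.null(heavy_profile)) heavy_profile <- baseline
  list(n_per_group = n_per_group, fold_changes = fold_changes,
       baseline = baseline, heavy_profile = heavy_profile, marks = marks,
       noise_sd = noise_sd, sample_scale_sd = sample_scale_sd,
       auc_scale = auc_scale, missing_rate = missing_rate, ki67 = ki67,
       paired = paired)
}

# Multiply the members of the given marks by their fold changes and
# renormalize each family to 100.
.apply_fold_changes <- function(baseline, fold_changes, marks) {
  prof <- baseline
  for (mk in names(fold_changes)) {
    def <- marks[[mk]]
    fam <- def$family_id
    hit <- intersect(def$members, names(prof[[fam]]))
    prof[[fam]][hit] <- prof[[fam]][hit] * fold_changes[[mk]]
  }
  lapply(prof, function(v) {
    out <- 100 * v / sum(v)
    if (any(out <= 0 | out >= 100)) {
      stop("fold change drives a %RA outside (0, 100) after renormalization")
    }
    out
  })
}

# Deterministic expected retention-time apex per family x form: families are
# placed 8 min apart, forms 0.7 min apart in library order, so isobaric
# partners are chromatographically separated.
.rt_apexes <- function(baseline) {
  fams <- names(baseline)
  out <- list()
  for (i in seq_along(fams)) {
    forms <- names(baseline[[fams[i]]])
    out[[i]] <- data.frame(family_id = fams[i], form_id = forms,
                           rt = 10 + 8 * (i - 1) + 0.7 * (seq_along(forms) - 1),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Tumor light-channel profiles are obtained by multiplying the designated
#' mark members' baseline abundance by the configured fold change and
#' renormalizing the family to 100; the heavy channel (spike-in) profile is
#' identical across samples. Observed AUCs are
#' `sample scale x true %RA x lognormal noise`. A per-sample biological
#' multiplier on the Ki-67-linked mark induces the configured correlation
#' between Ki-67 and that mark. Fully reproducible from `seed`.
#'
#' @param config List from [cohort_config()].
#' @param seed Integer RNG seed.
#' @return List: `truth` (`sample_id`, `group`, `family_id`, `form_id`,
#'   `channel`, `true_ra`, `auc`, `rt`), `metadata` (`sample_id`, `group`,
#'   `pair_id`, `ki67`, `storage`), `expected_rt`, `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  set.seed(seed)
  groups <- rep(names(config$n_per_group), config$n_per_group)
  within_idx <- unlist(lapply(config$n_per_group, seq_len))
  sample_id <- paste0(groups, "_", within_idx)
  n <- length(sample_id)
  pair_id <- if (isTRUE(config$paired)) within_idx else seq_len(n)

  profiles <- list(
    normal = config$baseline,
    tumor = .apply_fold_changes(config$baseline, config$fold_changes,
                                config$marks))
  for (g in setdiff(unique(groups), names(profiles))) {
    profiles[[g]] <- config$baseline
  }

  ki <- config$ki67
  link <- ki$link_mark
  bio_z <- if (!is.null(link) && ki$bio_sd > 0) {
    stats::rnorm(n, 0, ki$bio_sd)
  } else rep(0, n)
  beta <- if (!is.null(link) && !is.null(ki$link_r) && ki$bio_sd > 0 &&
              ki$link_r != 0) {
    (ki$link_r / sqrt(1 - ki$link_r^2)) * ki$sd / ki$bio_sd
  } else 0
  ki67 <- ki$mean[groups] + beta * bio_z + stats::rnorm(n, 0, ki$sd)
  ki67 <- pmin(pmax(ki67, 0), 100)

  link_members <- if (!is.null(link)) config$marks[[link]]$members else NULL
  link_family <- if (!is.null(link)) config$marks[[link]]$family_id else NULL

  rt <- .rt_apexes(config$baseline)
  rt_key <- stats::setNames(rt$rt, paste(rt$family_id, rt$form_id))

  scale_i <- config$auc_scale * 2^stats::rnorm(n, 0, config$sample_scale_sd)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    light <- profiles[[groups[i]]]
    if (!is.null(link)) {
      light[[link_family]][link_members] <-
        light[[link_family]][link_members] * 2^bio_z[i]
      light[[link_family]] <- 100 * light[[link_family]] /
        sum(light[[link_family]])
    }
    per_chan <- lapply(c(light = "light", heavy = "heavy"), function(ch) {
      prof <- if (ch == "light") light else config$heavy_profile
      fam <- rep(names(prof), lengths(prof))
      form <- unlist(lapply(prof, names), use.names = FALSE)
      ra <- unlist(prof, use.names = FALSE)
      auc <- scale_i[i] * (ra / 100) *
        2^stats::rnorm(length(ra), 0, config$noise_sd)
      if (config$missing_rate > 0) {
        auc[stats::runif(length(auc)) < config$missing_rate] <- NA_real_
      }
      data.frame(sample_id = sample_id[i], group = groups[i],
                 family_id = fam, form_id = form, channel = ch,
                 true_ra = ra, auc = auc,
                 rt = unname(rt_key[paste(fam, form)]),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- rbind(per_chan$light, per_chan$heavy)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  metadata <- data.frame(sample_id = sample_id, group = groups,
                         pair_id = pair_id, ki67 = ki67,
                         storage = "frozen", stringsAsFactors = FALSE)
  list(truth = truth, metadata = metadata, expected_rt = rt,
       config = config, seed = seed)
}

#' Peak-shape configuration for [simulate_peaks()]
#'
#' @param rt_sd Gaussian elution peak sd in minutes (default 0.12; with the
#'   default 0.02-min scan interval a peak carries ~35 points).
#' @param scan_interval MS1 scan spacing in minutes (default 0.02).
#' @param z_split Intensity fractions of the 2+ and 3+ precursors.
#' @param mz_jitter_ppm Uniform m/z jitter per centroid in ppm (default 0).
#' @param rt_pad Window half-width around an apex that receives points, in
#'   sds (default 5).
#' @return List of shape parameters.
#' @export
peak_shape <- function(rt_sd = 0.12, scan_interval = 0.02,
                       z_split = c("2" = 0.7, "3" = 0.3),
                       mz_jitter_ppm = 0, rt_pad = 5) {
  list(rt_sd = rt_sd, scan_interval = scan_interval, z_split = z_split,
       mz_jitter_ppm = mz_jitter_ppm, rt_pad = rt_pad)
}

#' Simulate centroided MS1 peak tables from ground truth
#'
#' Emits Gaussian elution profiles at the theoretical light/heavy m/z of the
#' 2+ and 3+ precursors, with peak areas proportional to the true AUC. Forms
#' with missing or zero AUC emit no peaks.
#'
#' @param cohort Output of [generate_cohort()].
#' @param library Peptidoform library from [build_h3_library()].
#' @param shape List from [peak_shape()].
#' @param sample_ids Samples to simulate (default: all).
#' @return data.frame `run_id`, `rt`, `mz`, `intensity` across the requested
#'   runs (`run_id` = sample id).
#' @export
simulate_peaks <- function(cohort, library, shape = peak_shape(),
                           sample_ids = NULL) {
  truth <- cohort$truth
  if (!is.null(sample_ids)) {
    truth <- truth[truth$sample_id %in% sample_ids, , drop = FALSE]
  }
  libkey <- paste(library$family_id, library$form_id)
  miss <- setdiff(unique(paste(truth$family_id, truth$form_id)), libkey)
  if (length(miss) > 0) {
    stop("library lacks m/z for: ", paste(utils::head(miss, 3), collapse = ", "))
  }
  grid0 <- seq(0, max(truth$rt) + shape$rt_pad * shape$rt_sd + 1,
               by = shape$scan_interval)
  out <- list()
  for (i in seq_len(nrow(truth))) {
    auc <- truth$auc[i]
    if (is.na(auc) || auc <= 0) next
    li <- match(paste(truth$family_id[i], truth$form_id[i]), libkey)
    apex <- truth$rt[i]
    ts <- grid0[abs(grid0 - apex) <= shape$rt_pad * shape$rt_sd]
    dens <- stats::dnorm(ts, apex, shape$rt_sd)
    for (z in names(shape$z_split)) {
      mz <- library[[paste0("mz_", truth$channel[i], "_z", z)]][li]
      if (shape$mz_jitter_ppm > 0) {
        mz <- mz * (1 + stats::runif(length(ts), -shape$mz_jitter_ppm,
                                     shape$mz_jitter_ppm) * 1e-6)
      }
      out[[length(out) + 1L]] <- data.frame(
        run_id = truth$sample_id[i], rt = ts, mz = mz,
        intensity = auc * shape$z_split[[z]] * dens,
        stringsAsFactors = FALSE)
    }
  }
  peaks <- do.call(rbind, out)
  peaks <- peaks[order(peaks$run_id, peaks$rt, peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Ground-truth AUC table of a synthetic cohort
#'
#' @param cohort Output of [generate_cohort()].
#' @return data.frame `sample_id`, `family_id`, `form_id`, `channel`, `auc`.
#' @export
truth_auc <- function(cohort) {
  cohort$truth[, c("sample_id", "family_id", "form_id", "channel", "auc")]
}
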