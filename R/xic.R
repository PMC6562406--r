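# Extracted-ion-chromatogram quantification from centroided MS1 peak lists:
# ppm-window extraction, trapezoidal AUC, valley-based resolution of co-eluting
# isobaric peptidoforms, identification-score filtering, per-run orchestration.

#' Read a simplified centroided peak table
#'
#' Plain-text stand-in for an mzML run: one row per centroid with columns
#' `run_id`, `rt` (minutes), `mz`, `intensity`. All rows sharing an `rt` value
#' belong to one MS1 scan.
#'
#' @param path TSV file path.
#' @return data.frame with the four columns above.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("run_id", "rt", "mz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("peak table missing column(s): ",
                             paste(miss, collapse = ", "))
  df
}

#' Read centroided MS1 spectra from an mzML file
#'
#' Requires the `mzR` package. Retention times are converted to minutes.
#'
#' @param path mzML file path.
#' @param run_id Run identifier to stamp on the peaks; defaults to the file
#'   name.
#' @return data.frame with columns `run_id`, `rt`, `mz`, `intensity` (MS1
#'   scans only).
#' @export
read_mzml <- function(path, run_id = basename(path)) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package")
  }
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hd <- mzR::header(ms)
  ms1 <- which(hd$msLevel == 1)
  out <- lapply(ms1, function(i) {
    pk <- mzR::peaks(ms, i)
    if (nrow(pk) == 0) return(NULL)
    data.frame(run_id = run_id, rt = hd$retentionTime[i] / 60,
               mz = pk[, 1], intensity = pk[, 2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract an ion chromatogram
#'
#' For every scan (unique `rt`) inside the retention-time window, sums the
#' intensities of all centroids within `ppm_tolerance` of the target m/z. The
#' target is rounded to four decimals before matching, mirroring the
#' four-decimal mass precision of the original extraction.
#'
#' @param peaks Peak data.frame (`rt`, `mz`, `intensity`) from one run.
#' @param target_mz Theoretical ion m/z.
#' @param ppm_tolerance Matching half-window in parts per million (default 10).
#' @param rt_window Optional `c(min, max)` in minutes; `NULL` keeps all scans.
#' @return data.frame `rt`, `intensity`, sorted by `rt`; zero rows if no scans
#'   fall in the window.
#' @export
extract_xic <- function(peaks, target_mz, ppm_tolerance = 10,
                        rt_window = NULL) {
  if (ppm_tolerance <= 0) stop("ppm_tolerance must be positive")
  target <- round(target_mz, 4)
  if (!is.null(rt_window)) {
    peaks <- peaks[peaks$rt >= rt_window[1] & peaks$rt <= rt_window[2], ,
                   drop = FALSE]
  }
  if (nrow(peaks) == 0) {
    return(data.frame(rt = numeric(0), intensity = numeric(0)))
  }
  rts <- sort(unique(peaks$rt))
  hit <- abs(peaks$mz - target) / target * 1e6 <= ppm_tolerance
  agg <- tapply(peaks$intensity[hit], factor(peaks$rt[hit], levels = rts),
                sum)
  intensity <- as.numeric(agg)
  intensity[is.na(intensity)] <- 0
  data.frame(rt = rts, intensity = intensity)
}

#' Trapezoidal area under an ion chromatogram
#'
#' @param trace data.frame `rt`, `intensity` sorted by `rt`.
#' @return Area (intensity x minutes); 0 for fewer than two points.
#' @export
integrate_auc <- function(trace) {
  if (nrow(trace) < 2) return(0)
  if (is.unsorted(trace$rt, strictly = FALSE)) {
    stop("trace retention times must be sorted")
  }
  pracma::trapz(trace$rt, trace$intensity)
}

# Indices of local maxima above a relative height threshold.
.find_apexes <- function(y, min_frac = 0.05) {
  n <- length(y)
  if (n == 0 || max(y) <= 0) return(integer(0))
  thr <- min_frac * max(y)
  idx <- which(y >= thr &
                 y >= c(-Inf, y[-n]) &
                 y > c(y[-1], -Inf))
  # collapse plateaus: neighbouring indices with equal height
  if (length(idx) > 1) idx <- idx[c(TRUE, diff(idx) > 1 | diff(y[idx]) != 0)]
  idx
}

#' Resolve co-eluting isobaric peptidoforms on a shared chromatogram
#'
#' Isobaric forms (identical theoretical m/z) produce one XIC with multiple
#' apexes. The trace is split at the intensity valleys between apexes and the
#' resulting segments are assigned to the forms in the expected elution order
#' given by `template`. When the number of detected apexes does not match the
#' number of forms the set is flagged unresolved and all areas are withheld.
#'
#' @param trace Shared XIC data.frame (`rt`, `intensity`).
#' @param template Character vector of form ids in expected elution order.
#' @return data.frame `form_id`, `auc`, `flag` (`"ok"`, `"unresolved"` or
#'   `"missing"`).
#' @export
resolve_isobaric <- function(trace, template) {
  if (length(template) == 0) stop("template must name at least one form")
  k <- length(template)
  if (k == 1) {
    return(data.frame(form_id = template, auc = integrate_auc(trace),
                      flag = "ok", stringsAsFactors = FALSE))
  }
  apex <- .find_apexes(trace$intensity)
  if (length(apex) != k) {
    return(data.frame(form_id = template, auc = NA_real_,
                      flag = "unresolved", stringsAsFactors = FALSE))
  }
  # valley = global minimum between consecutive apexes
  bounds <- c(1L, vapply(seq_len(k - 1), function(i) {
    seg <- apex[i]:apex[i + 1]
    seg[which.min(trace$intensity[seg])]
  }, 1L), nrow(trace))
  auc <- vapply(seq_len(k), function(i) {
    integrate_auc(trace[bounds[i]:bounds[i + 1], , drop = FALSE])
  }, 0)
  data.frame(form_id = template, auc = auc, flag = "ok",
             stringsAsFactors = FALSE)
}

#' Filter peptide identifications by search score and localization probability
#'
#' Identifications with a search score below `min_score` or a site
#' localization probability below `min_loc_prob` are removed; records exactly
#' at a threshold are kept.
#'
#' @param records data.frame with columns `score` and `localization_prob`.
#' @param min_score Minimum retained score (default 60).
#' @param min_loc_prob Minimum retained localization probability (default
#'   0.75).
#' @return The retained rows.
#' @export
filter_identifications <- function(records, min_score = 60,
                                   min_loc_prob = 0.75) {
  stopifnot(all(c("score", "localization_prob") %in% names(records)))
  if (any(records$localization_prob < 0 | records$localization_prob > 1)) {
    stop("localization_prob must lie in [0, 1]")
  }
  records[records$score >= min_score &
            records$localization_prob >= min_loc_prob, , drop = FALSE]
}

#' Quantification configuration
#'
#' @param ppm_tolerance XIC matching tolerance in ppm (default 10).
#' @param charges Precursor charges to extract and sum (default `c(2, 3)`).
#' @param rt_half_window Half-width in minutes of the extraction window around
#'   the expected retention time (default 2).
#' @return List used by [quantify_run()].
#' @export
quant_config <- function(ppm_tolerance = 10, charges = c(2, 3),
                         rt_half_window = 2) {
  list(ppm_tolerance = ppm_tolerance, charges = charges,
       rt_half_window = rt_half_window)
}

#' Quantify one LC-MS run against a peptidoform library
#'
#' For every peptidoform and channel, extracts XICs for the configured charges
#' inside `rt_half_window` of the expected retention time, integrates and sums
#' the areas. Peptidoforms of a family whose theoretical m/z coincide (to four
#' decimals) are treated as an isobaric set: their shared chromatogram is
#' split at valleys and assigned by expected elution order
#' ([resolve_isobaric()]).
#'
#' @param peaks Peak data.frame for one run (`rt`, `mz`, `intensity`).
#' @param library Peptidoform library from [build_h3_library()].
#' @param expected_rt data.frame `family_id`, `form_id`, `rt` giving the
#'   expected apex of each form (from identifications or the simulator).
#' @param config List from [quant_config()].
#' @return data.frame `family_id`, `form_id`, `channel`, `auc`, `flag`; AUC is
#'   `NA` for forms with no signal or unresolved isobaric sets.
#' @export
quantify_run <- function(peaks, library, expected_rt,
                         config = quant_config()) {
  key <- paste(library$family_id, library$form_id)
  ert <- stats::setNames(expected_rt$rt,
                         paste(expected_rt$family_id, expected_rt$form_id))
  if (anyNA(ert[key])) {
    stop("expected_rt missing for: ",
         paste(utils::head(key[is.na(ert[key])], 3), collapse = ", "))
  }
  out <- list()
  for (channel in c("light", "heavy")) {
    for (fam in unique(library$family_id)) {
      sub <- library[library$family_id == fam, , drop = FALSE]
      # isobaric clusters: identical mass to 4 decimals
      cl <- split(seq_len(nrow(sub)), round(sub$mass, 4))
      for (rows in cl) {
        grp <- sub[rows, , drop = FALSE]
        rt_exp <- ert[paste(grp$family_id, grp$form_id)]
        ord <- order(rt_exp)
        grp <- grp[ord, , drop = FALSE]
        rt_exp <- rt_exp[ord]
        win <- c(min(rt_exp) - config$rt_half_window,
                 max(rt_exp) + config$rt_half_window)
        auc <- rep(0, nrow(grp))
        flag <- rep("ok", nrow(grp))
        for (z in config$charges) {
          mzcol <- paste0("mz_", channel, "_z", z)
          trace <- extract_xic(peaks, grp[[mzcol]][1],
                               ppm_tolerance = config$ppm_tolerance,
                               rt_window = win)
          if (nrow(grp) == 1) {
            auc <- auc + integrate_auc(trace)
          } else {
            res <- resolve_isobaric(trace, grp$form_id)
            if (any(res$flag != "ok")) {
              flag <- res$flag
              auc <- rep(NA_real_, nrow(grp))
              break
            }
            auc <- auc + res$auc
          }
        }
        miss <- !is.na(auc) & auc <= 0
        auc[miss] <- NA_real_
        flag[miss] <- "missing"
        out[[length(out) + 1L]] <- data.frame(
          family_id = grp$family_id, form_id = grp$form_id,
          channel = channel, auc = auc, flag = flag,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
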