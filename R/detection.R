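# ROC-based detection evaluation: silence defines the false-positive
# class, speech and noise the true-positive class, and sweeps quantify
# how nuisance regression, sample rate and boxcar duration change AUC
# and the true-positive rate at 5% false positives.

#' Assemble a detection table from channel-level GLM fits
#'
#' One row per (subject, channel, condition, chromophore) with the
#' condition regressor's p value. Rows with condition `"silence"` form
#' the negative class; `"speech"` and `"noise"` rows are positives.
#'
#' @param fits named/indexed list of `fnirs_glm` objects, one per subject.
#' @param channels channel indices to include (e.g. the STG channels);
#'   default all fitted channels.
#' @param chroma chromophore tag(s) to include (default `"hbo"`).
#' @return data.frame of class `detection_table`: `subject`, `unit`,
#'   `id`, `condition`, `chroma`, `p`.
#' @export
detection_table <- function(fits, channels = NULL, chroma = "hbo") {
  out <- list()
  for (s in seq_along(fits)) {
    r <- fits[[s]]$results
    conds <- fits[[s]]$design$conditions
    sel <- r$regressor %in% conds & r$chroma %in% chroma
    if (!is.null(channels)) sel <- sel & r$channel %in% channels
    r <- r[sel, , drop = FALSE]
    if (!nrow(r)) next
    out[[s]] <- data.frame(subject = s, unit = "channel",
                           id = r$label, condition = r$regressor,
                           chroma = r$chroma, p = r$p,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  class(tab) <- c("detection_table", class(tab))
  tab
}

#' ROC curve from a detection table
#'
#' Sweeps the p-value threshold over all distinct values: a row is
#' "detected" when `p <= threshold`; FPR is the detected fraction of
#' silence rows, TPR the detected fraction of speech+noise rows. AUC by
#' the trapezoid rule (equivalent to the Mann-Whitney statistic with
#' ties counted half), and TPR at a fixed FPR by linear interpolation
#' between adjacent vertices (`interpolate = FALSE` uses the step
#' convention: the last vertex at or below the target FPR).
#'
#' @param table a [detection_table()] (or any data.frame with `condition`
#'   and `p`).
#' @param positive conditions counted as the positive class.
#' @param at_fpr FPR at which to report TPR (default 0.05).
#' @param interpolate linear interpolation at `at_fpr` (default TRUE).
#' @return list of class `roc_result`: `fpr`, `tpr` (curve vertices,
#'   including (0,0) and (1,1)), `thresholds`, `auc`, `tpr_at`,
#'   `at_fpr`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(table, positive = c("speech", "noise"),
                      at_fpr = 0.05, interpolate = TRUE) {
  lab <- table$condition %in% positive
  p <- table$p
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC needs both positive and negative rows")
  th <- sort(unique(p))
  tpr <- vapply(th, function(x) mean(p[lab] <= x), 0)
  fpr <- vapply(th, function(x) mean(p[!lab] <= x), 0)
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  if (fpr[length(fpr)] < 1 || tpr[length(tpr)] < 1) {
    fpr <- c(fpr, 1); tpr <- c(tpr, 1); th <- c(th, Inf)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, thresholds = c(-Inf, th),
                 auc = auc,
                 tpr_at = tpr_at_fpr(fpr, tpr, at_fpr, interpolate),
                 at_fpr = at_fpr, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' TPR at a fixed FPR on an ROC polyline
#'
#' @param fpr,tpr curve vertices (nondecreasing).
#' @param at target FPR.
#' @param interpolate linear interpolation (default) or step convention.
#' @return scalar TPR.
#' @export
tpr_at_fpr <- function(fpr, tpr, at = 0.05, interpolate = TRUE) {
  if (interpolate)
    stats::approx(fpr, tpr, xout = at, ties = max, rule = 2)$y
  else
    max(tpr[fpr <= at], 0)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f, TPR@%d%%FPR = %.3f (%d pos / %d neg)\n",
              x$auc, round(100 * x$at_fpr), x$tpr_at, x$n_pos, x$n_neg))
  invisible(x)
}

#' Run the canonical-GLM detection pipeline on a cohort
#'
#' For every simulated (or loaded) session: resample the raw intensity,
#' convert to optical density and hemoglobin, prune channels outside
#' 20-40 mm, build the canonical design, fit the AR-prewhitened GLM with
#' the requested short-channel nuisance, and collect channel-level
#' p values over the STG channels.
#'
#' @param cohort list of sessions, each a list with element `recording`
#'   (as from [simulate_cohort()]).
#' @param rate analysis sample rate in Hz (default 0.6).
#' @param boxcar_dur boxcar duration in s (`NULL` = stimulus duration).
#' @param nuisance a [nuisance_spec()].
#' @param rois ROIs whose channels enter the table (default the two STG).
#' @param chroma chromophore for the table (default `"hbo"`).
#' @param ar_order AR order for prewhitening (default 4).
#' @param ppf,extinctions Beer-Lambert parameters.
#' @return a [detection_table()].
#' @export
glm_detection_run <- function(cohort, rate = 0.6, boxcar_dur = NULL,
                              nuisance = nuisance_spec("none"),
                              rois = c("left_STG", "right_STG"),
                              chroma = "hbo", ar_order = 4,
                              ppf = 0.1, extinctions = NULL) {
  fits <- lapply(cohort, function(sess) {
    rec <- resample_recording(sess$recording, rate)
    rec <- to_optical_density(rec)
    rec <- beer_lambert(rec, ppf = ppf, extinctions = extinctions)
    rec <- prune_channels(rec)
    sel <- rec$rows$chroma %in% chroma       # fit only what the table uses
    rec$data <- rec$data[sel, , drop = FALSE]
    rec$rows <- rec$rows[sel, , drop = FALSE]
    design <- build_design(rec$events, rec$sfreq, ncol(rec$data),
                           basis = "canonical", boxcar_dur = boxcar_dur)
    fit_glm(rec, design, nuisance = nuisance, ar_order = ar_order,
            channels = intersect(
              unlist(rec$montage$roi_map[rois]),
              which(channel_kinds(rec$montage) == "long")))
  })
  chans <- unique(unlist(lapply(fits, function(f)
    unlist(f$montage$roi_map[rois]))))
  detection_table(fits, channels = chans, chroma = chroma)
}

#' Sweep short-channel nuisance methods
#'
#' Runs [glm_detection_run()] once per nuisance method on the same
#' cohort and returns one ROC per method.
#'
#' @param cohort list of sessions.
#' @param methods list of [nuisance_spec()]s (default: none, mean,
#'   individual, 1/2/4 PCs, all PCs).
#' @param ... passed to [glm_detection_run()].
#' @return named list of `roc_result`s (attribute `tables` holds the
#'   detection tables).
#' @export
sweep_nuisance <- function(cohort, methods = default_nuisance_methods(),
                           ...) {
  tabs <- lapply(methods, function(m)
    glm_detection_run(cohort, nuisance = m, ...))
  rocs <- lapply(tabs, roc_curve)
  attr(rocs, "tables") <- tabs
  rocs
}

#' @rdname sweep_nuisance
#' @export
default_nuisance_methods <- function() {
  list(none = nuisance_spec("none"),
       short_mean = nuisance_spec("short_mean"),
       short_individual = nuisance_spec("short_individual"),
       short_pca_1 = nuisance_spec("short_pca", 1),
       short_pca_2 = nuisance_spec("short_pca", 2),
       short_pca_4 = nuisance_spec("short_pca", 4),
       short_pca_all = nuisance_spec("short_pca_all"))
}

#' Sweep analysis sample rate
#'
#' @param cohort list of sessions.
#' @param rates sample rates in Hz.
#' @param ... passed to [glm_detection_run()].
#' @return named list of `roc_result`s.
#' @export
sweep_rate <- function(cohort, rates = c(0.6, 1, 2), ...) {
  rocs <- lapply(rates, function(r)
    roc_curve(glm_detection_run(cohort, rate = r, ...)))
  names(rocs) <- paste0(rates, "Hz")
  rocs
}

#' Sweep boxcar duration
#'
#' @param cohort list of sessions.
#' @param durations boxcar durations in s.
#' @param ... passed to [glm_detection_run()].
#' @return named list of `roc_result`s.
#' @export
sweep_boxcar <- function(cohort, durations = c(0.5, 1, 3, 5), ...) {
  rocs <- lapply(durations, function(d)
    roc_curve(glm_detection_run(cohort, boxcar_dur = d, ...)))
  names(rocs) <- paste0(durations, "s")
  rocs
}
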