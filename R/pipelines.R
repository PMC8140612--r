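# End-to-end per-subject pipelines: raw intensity in, one response
# estimate per (subject, ROI, condition, chromophore) out. These are the
# two analysis routes compared at the group level.

#' Canonical-GLM subject estimates for a cohort
#'
#' Runs the canonical-model chain on every session (resample, optical
#' density, Beer-Lambert, 20-40 mm pruning, AR-prewhitened GLM with the
#' chosen short-channel nuisance) and pools channel betas into ROI
#' estimates by inverse standard error.
#'
#' @param cohort list of sessions (each with element `recording`).
#' @param rate analysis sample rate in Hz (default 0.6).
#' @param boxcar_dur boxcar duration in s (default 3; `NULL` uses each
#'   stimulus's duration).
#' @param nuisance a [nuisance_spec()] (default all short-channel PCs).
#' @param rois ROIs to export (default the two STG).
#' @param source source tag for the output table.
#' @param ar_order,ppf,extinctions pipeline parameters.
#' @return a [subject_estimates()] table.
#' @export
glm_subject_estimates <- function(cohort, rate = 0.6, boxcar_dur = 3,
                                  nuisance = nuisance_spec("short_pca_all"),
                                  rois = c("left_STG", "right_STG"),
                                  source = "glm_corrected", ar_order = 4,
                                  ppf = 0.1, extinctions = NULL) {
  out <- list()
  for (s in seq_along(cohort)) {
    rec <- resample_recording(cohort[[s]]$recording, rate)
    rec <- to_optical_density(rec)
    rec <- beer_lambert(rec, ppf = ppf, extinctions = extinctions)
    rec <- prune_channels(rec)
    design <- build_design(rec$events, rec$sfreq, ncol(rec$data),
                           basis = "canonical", boxcar_dur = boxcar_dur)
    fit <- fit_glm(rec, design, nuisance = nuisance, ar_order = ar_order,
                   channels = intersect(
                     unlist(rec$montage$roi_map[rois]),
                     which(channel_kinds(rec$montage) == "long")))
    for (roi in rois) {
      po <- pool_roi(fit, roi)
      out[[length(out) + 1]] <- data.frame(
        subject = s, roi = roi, condition = po$regressor,
        chroma = po$chroma, estimate = po$beta, stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, out)
  subject_estimates(d$subject, d$roi, d$condition, d$chroma, d$estimate,
                    source = source)
}

#' Epoch-averaging subject estimates for a cohort
#'
#' Runs the averaging chain on every session (resample to 3 Hz, optical
#' density, optional scalp-coupling pruning, TDDR, nearest-short-channel
#' regression, Beer-Lambert, 20-40 mm pruning, anti-correlation
#' enhancement, 0.01-0.7 Hz bandpass, epoching with linear detrend,
#' 100 uM peak-to-peak rejection) and exports the mean ROI waveform
#' amplitude in the 5-7 s window.
#'
#' @param cohort list of sessions.
#' @param rate analysis sample rate in Hz (default 3).
#' @param use_sci drop channels failing the scalp-coupling index
#'   (default TRUE).
#' @param window amplitude window in s (default `c(5, 7)`).
#' @param rois ROIs to export.
#' @param source source tag for the output table.
#' @param ppf,extinctions Beer-Lambert parameters.
#' @return a [subject_estimates()] table.
#' @export
averaging_subject_estimates <- function(cohort, rate = 3, use_sci = TRUE,
                                        window = c(5, 7),
                                        rois = c("left_STG", "right_STG"),
                                        source = "averaging",
                                        ppf = 0.1, extinctions = NULL) {
  out <- list()
  for (s in seq_along(cohort)) {
    rec <- resample_recording(cohort[[s]]$recording, rate)
    rec <- to_optical_density(rec)
    sci <- if (use_sci) scalp_coupling_index(rec) else NULL
    rec <- tddr(rec)
    rec <- short_channel_regress(rec)
    rec <- beer_lambert(rec, ppf = ppf, extinctions = extinctions)
    rec <- prune_channels(rec, sci_report = sci)
    rec <- negative_correlation_enhance(rec)
    rec <- bandpass_filter(rec)
    ep <- reject_epochs(epoch_recording(rec))
    avg <- average_epochs(ep)
    for (roi in rois) {
      am <- roi_amplitude(avg, roi, window = window)
      out[[length(out) + 1]] <- data.frame(
        subject = s, roi = roi, condition = am$condition,
        chroma = am$chroma, estimate = am$value, stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, out)
  subject_estimates(d$subject, d$roi, d$condition, d$chroma, d$estimate,
                    source = source)
}
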