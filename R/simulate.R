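# Forward simulator for the passive auditory block design: known neural
# amplitudes in the STG channels, a shared systemic signal (Mayer wave,
# cardiac pulse, slow drift) coupled into every channel including the
# short channels, AR(1) sensor noise, and a physical optics stage mapping
# micromolar concentration changes to two-wavelength raw intensity.

#' Extinction coefficients for hemoglobin
#'
#' Molar extinction coefficients (1/cm per mol/l) of oxy- and
#' deoxyhemoglobin at common continuous-wave NIRS wavelengths, from the
#' standard compiled tables used across the fNIRS toolchain ecosystem.
#'
#' @param wavelengths numeric(2), wavelengths in nm. Bundled values exist
#'   for 690, 760, 830 and 850 nm.
#' @return 2x2 matrix, rows = wavelengths, columns = `hbo`, `hbr`.
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850)) {
  tab <- rbind(`690` = c(hbo = 276.0,    hbr = 2051.96),
               `760` = c(hbo = 1486.59,  hbr = 3843.71),
               `830` = c(hbo = 2321.40,  hbr = 1791.73),
               `850` = c(hbo = 2526.39,  hbr = 1798.64))
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(tab)))
    stop("no bundled extinction coefficients for wavelength(s) ",
         paste(setdiff(key, rownames(tab)), collapse = ", "),
         " nm; supply a custom matrix")
  e <- tab[key, , drop = FALSE]
  rownames(e) <- key
  e
}

#' Default neural amplitude table
#'
#' Peak concentration change (micromolar) of the noise-free response to a
#' single isolated stimulus, per condition and ROI. Defaults place
#' responses only in the two STG regions, with the speech HbO response
#' 1 uM larger than noise and no response to silence; HbR is
#' `hbr_ratio` times HbO (inverted, smaller, the conventional shape).
#'
#' @param speech_hbo,noise_hbo peak HbO amplitudes (uM).
#' @param hbr_ratio HbR/HbO amplitude ratio (default -1/3).
#' @return data.frame with columns `condition`, `roi`, `hbo`, `hbr`.
#' @export
default_amplitudes <- function(speech_hbo = 2.0, noise_hbo = 1.0,
                               hbr_ratio = -1 / 3) {
  amp <- expand.grid(condition = c("speech", "noise"),
                     roi = c("left_STG", "right_STG"),
                     stringsAsFactors = FALSE)
  amp$hbo <- ifelse(amp$condition == "speech", speech_hbo, noise_hbo)
  amp$hbr <- amp$hbo * hbr_ratio
  amp
}

#' Simulation configuration
#'
#' Bundles every parameter of the forward model. Defaults reproduce the
#' experimental design this package targets: 17 subjects, 5.2 Hz raw
#' sample rate, three conditions (speech 5.25 s, noise 5 s, silence 5 s),
#' 20 trials each in random order, inter-stimulus interval (stimulus
#' offset to next onset) uniform on 10-20 s, neural responses confined to
#' the STG channels, and systemic physiology shared between long and
#' short channels.
#'
#' @param n_subjects number of simulated participants (default 17).
#' @param sfreq raw sample rate in Hz (default 5.2).
#' @param trials_per_condition trials per condition (default 20).
#' @param isi_bounds ISI bounds in s (default `c(10, 20)`).
#' @param durations named stimulus durations in s.
#' @param amplitudes amplitude table from [default_amplitudes()].
#' @param hrf an [hrf_params()] object.
#' @param mayer_freq,mayer_amp Mayer-wave frequency (Hz) and HbO amplitude
#'   (uM); default 0.1 Hz / 1 uM.
#' @param cardiac_freq,cardiac_amp cardiac frequency (Hz) and HbO
#'   amplitude (uM); default 1.1 Hz / 0.5 uM.
#' @param drift_scale random-walk drift innovation SD (uM per sample).
#' @param sys_gain_range per-channel systemic coupling gain bounds;
#'   channels receive the shared systemic trace scaled by a uniform draw
#'   from this interval.
#' @param hbr_sys_ratio systemic HbR/HbO ratio (default 0.3; systemic
#'   fluctuations co-vary positively across chromophores).
#' @param noise_sd marginal SD of AR(1) sensor noise in uM (default 0.4).
#' @param noise_ar1 AR(1) coefficient of sensor noise (default 0.3).
#' @param ppf partial pathlength factor used by the optics (default 0.1).
#' @param extinctions extinction matrix (see [extinction_coefficients()]).
#' @param seed master seed; subject `i` uses `seed + i`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 17, sfreq = 5.2,
                       trials_per_condition = 20, isi_bounds = c(10, 20),
                       durations = c(speech = 5.25, noise = 5, silence = 5),
                       amplitudes = default_amplitudes(),
                       hrf = hrf_params(),
                       mayer_freq = 0.1, mayer_amp = 1.0,
                       cardiac_freq = 1.1, cardiac_amp = 0.5,
                       drift_scale = 0.05, sys_gain_range = c(0.5, 1.5),
                       hbr_sys_ratio = 0.3,
                       noise_sd = 0.4, noise_ar1 = 0.3,
                       ppf = 0.1, extinctions = NULL, seed = 1) {
  stopifnot(isi_bounds[1] < isi_bounds[2], sfreq > 0,
            trials_per_condition >= 0, all(durations > 0),
            all(is.finite(amplitudes$hbo)), all(is.finite(amplitudes$hbr)),
            noise_sd >= 0, abs(noise_ar1) < 1, ppf > 0)
  structure(list(
    n_subjects = n_subjects, sfreq = sfreq,
    trials_per_condition = trials_per_condition, isi_bounds = isi_bounds,
    durations = durations, amplitudes = amplitudes, hrf = hrf,
    mayer_freq = mayer_freq, mayer_amp = mayer_amp,
    cardiac_freq = cardiac_freq, cardiac_amp = cardiac_amp,
    drift_scale = drift_scale, sys_gain_range = sys_gain_range,
    hbr_sys_ratio = hbr_sys_ratio,
    noise_sd = noise_sd, noise_ar1 = noise_ar1,
    ppf = ppf, extinctions = extinctions, seed = seed),
    class = "sim_config")
}

#' Generate a randomized block-design event schedule
#'
#' Interleaves `trials_per_condition` trials of each condition in random
#' order. The interval from each stimulus offset to the next onset is
#' drawn uniformly from `isi_bounds`; the first onset uses one such draw
#' from the recording start.
#'
#' @param cfg a [sim_config()].
#' @return events data.frame (`onset`, `duration`, `condition`).
#' @export
generate_events <- function(cfg) {
  conds <- names(cfg$durations)
  n <- cfg$trials_per_condition * length(conds)
  if (n == 0) return(empty_events())
  labels <- sample(rep(conds, cfg$trials_per_condition))
  isi <- stats::runif(n, cfg$isi_bounds[1], cfg$isi_bounds[2])
  dur <- unname(cfg$durations[labels])
  onset <- numeric(n)
  onset[1] <- isi[1]
  if (n > 1)
    for (i in 2:n) onset[i] <- onset[i - 1] + dur[i - 1] + isi[i]
  data.frame(onset = onset, duration = dur, condition = labels,
             stringsAsFactors = FALSE)
}

# samples needed to cover schedule + HRF tail
session_samples <- function(cfg, schedule) {
  end_s <- if (nrow(schedule))
    max(schedule$onset + schedule$duration) + cfg$hrf$time_length + 1
  else 60
  as.integer(ceiling(end_s * cfg$sfreq))
}

#' Generate noise-free neural concentration traces
#'
#' For every channel belonging to an ROI with a configured amplitude, the
#' trace is the sum over that condition's events of a boxcar (stimulus
#' duration) convolved with the canonical HRF, scaled so that the peak of
#' an isolated event equals the configured amplitude (uM). Channels in no
#' configured ROI, and all short channels, stay at zero.
#'
#' @param cfg a [sim_config()].
#' @param schedule events data.frame from [generate_events()].
#' @param montage an `fnirs_montage`.
#' @return list of class `fnirs_ground_truth` with elements `neural`
#'   (rows = channel x {hbo, hbr}, uM), `rows`, `amplitudes`, `schedule`,
#'   `sfreq`.
#' @export
generate_neural <- function(cfg, schedule, montage) {
  if (!all(cfg$amplitudes$roi %in% names(montage$roi_map)))
    stop("amplitude table references ROI absent from montage: ",
         paste(setdiff(cfg$amplitudes$roi, names(montage$roi_map)),
               collapse = ", "))
  nch <- nrow(montage$channels)
  n <- session_samples(cfg, schedule)
  rows <- data.frame(channel = rep(seq_len(nch), each = 2),
                     chroma = rep(c("hbo", "hbr"), nch),
                     stringsAsFactors = FALSE)
  neural <- matrix(0, nrow = 2 * nch, ncol = n)

  # per condition: peak-normalized regressor summed over events
  regs <- list()
  for (cond in unique(schedule$condition)) {
    r <- single_event_response(cfg$durations[[cond]], cfg$sfreq, cfg$hrf)
    x <- numeric(n)
    for (onset in schedule$onset[schedule$condition == cond]) {
      i0 <- round(onset * cfg$sfreq) + 1
      idx <- i0:min(n, i0 + length(r) - 1)
      x[idx] <- x[idx] + r[seq_along(idx)]
    }
    regs[[cond]] <- x
  }
  for (k in seq_len(nrow(cfg$amplitudes))) {
    a <- cfg$amplitudes[k, ]
    if (is.null(regs[[a$condition]])) next
    for (ch in montage$roi_map[[a$roi]]) {
      neural[rows_idx(rows, ch, "hbo"), ] <-
        neural[rows_idx(rows, ch, "hbo"), ] + a$hbo * regs[[a$condition]]
      neural[rows_idx(rows, ch, "hbr"), ] <-
        neural[rows_idx(rows, ch, "hbr"), ] + a$hbr * regs[[a$condition]]
    }
  }
  structure(list(neural = neural, rows = rows, amplitudes = cfg$amplitudes,
                 schedule = schedule, sfreq = cfg$sfreq),
            class = "fnirs_ground_truth")
}

rows_idx <- function(rows, channel, chroma) {
  which(rows$channel == channel & rows$chroma == chroma)
}

# Forward optics: concentration rows (uM) -> optical density rows, then
# intensity I = exp(-OD) with baseline I0 = 1 (OD is invariant to I0).
forward_od <- function(conc, rows, montage, ppf, extinctions = NULL) {
  if (is.null(extinctions))
    extinctions <- extinction_coefficients(montage$wavelengths)
  d_cm <- sd_distance(montage) * 100
  nch <- nrow(montage$channels)
  od <- matrix(0, nrow = 2 * nch, ncol = ncol(conc))
  od_rows <- data.frame(
    channel = rep(seq_len(nch), each = 2),
    chroma = rep(as.character(montage$wavelengths), nch),
    stringsAsFactors = FALSE)
  for (ch in seq_len(nch)) {
    cpair <- conc[c(rows_idx(rows, ch, "hbo"), rows_idx(rows, ch, "hbr")),
                  , drop = FALSE]
    od[od_rows$channel == ch, ] <-
      (extinctions %*% cpair) * d_cm[ch] * ppf * 1e-6
  }
  list(od = od, rows = od_rows)
}

#' Generate one simulated session
#'
#' Produces a raw-intensity recording for one subject plus its ground
#' truth. Concentration traces are neural + systemic + AR(1) noise; the
#' systemic part is one shared trace (Mayer sinusoid with subject-random
#' phase, cardiac sinusoid, random-walk drift) scaled per channel by a
#' uniform gain, fully present in short channels, which carry no neural
#' signal. Concentrations map to two-wavelength optical density through
#' the extinction matrix, separation and partial pathlength factor, then
#' to intensity `I = exp(-OD)`.
#'
#' @param cfg a [sim_config()].
#' @param subject_index integer; the subject seed is `cfg$seed +
#'   subject_index`, so the full draw is reproducible per subject.
#' @param montage montage to simulate (default [build_paper_montage()]).
#' @return list with elements `recording` (`fnirs_recording`,
#'   raw intensity) and `truth` (`fnirs_ground_truth` with extra elements
#'   `systemic`, `gains`, `noise_free`).
#' @export
generate_session <- function(cfg, subject_index = 1,
                             montage = build_paper_montage()) {
  set.seed((cfg$seed + subject_index) %% .Machine$integer.max)
  schedule <- generate_events(cfg)
  truth <- generate_neural(cfg, schedule, montage)
  n <- ncol(truth$neural)
  t <- (seq_len(n) - 1) / cfg$sfreq
  nch <- nrow(montage$channels)

  systemic <- cfg$mayer_amp *
      sin(2 * pi * cfg$mayer_freq * t + stats::runif(1, 0, 2 * pi)) +
    cfg$cardiac_amp *
      sin(2 * pi * cfg$cardiac_freq * t + stats::runif(1, 0, 2 * pi)) +
    cumsum(stats::rnorm(n, sd = cfg$drift_scale))
  gains <- stats::runif(nch, cfg$sys_gain_range[1], cfg$sys_gain_range[2])

  conc <- truth$neural
  for (ch in seq_len(nch)) {
    conc[rows_idx(truth$rows, ch, "hbo"), ] <-
      conc[rows_idx(truth$rows, ch, "hbo"), ] + gains[ch] * systemic
    conc[rows_idx(truth$rows, ch, "hbr"), ] <-
      conc[rows_idx(truth$rows, ch, "hbr"), ] +
      cfg$hbr_sys_ratio * gains[ch] * systemic
  }
  noise_free <- conc
  if (cfg$noise_sd > 0) {
    innov_sd <- cfg$noise_sd * sqrt(1 - cfg$noise_ar1^2)
    for (r in seq_len(nrow(conc)))
      conc[r, ] <- conc[r, ] +
        as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd),
                                 cfg$noise_ar1, method = "recursive"))
  }
  fwd <- forward_od(conc, truth$rows, montage, cfg$ppf, cfg$extinctions)
  rec <- fnirs_recording(exp(-fwd$od), "raw_intensity", cfg$sfreq, montage,
                         events = schedule, rows = fwd$rows)
  truth$systemic <- systemic
  truth$gains <- gains
  truth$noise_free <- noise_free
  list(recording = rec, truth = truth)
}

#' Simulate a cohort of sessions
#'
#' @param cfg a [sim_config()].
#' @param subjects integer vector of subject indices (default
#'   `1:cfg$n_subjects`).
#' @inheritParams generate_session
#' @return list of `generate_session()` results, one per subject.
#' @export
simulate_cohort <- function(cfg, subjects = seq_len(cfg$n_subjects),
                            montage = build_paper_montage()) {
  lapply(subjects, function(s) generate_session(cfg, s, montage))
}

#' Inject a motion artifact into a recording (test utility)
#'
#' Adds a spike (one-sample excursion) or a step (level shift from
#' `at_sample` onward) of the given size to selected rows. Used to
#' exercise motion-correction; not part of the analysis pipelines.
#'
#' @param rec an `fnirs_recording`.
#' @param rows integer row indices to corrupt.
#' @param at_sample sample index of the artifact.
#' @param size artifact magnitude in the recording's unit.
#' @param kind `"step"` or `"spike"`.
#' @return the corrupted recording.
#' @export
inject_artifact <- function(rec, rows, at_sample, size,
                            kind = c("step", "spike")) {
  kind <- match.arg(kind)
  n <- ncol(rec$data)
  stopifnot(at_sample >= 1, at_sample <= n)
  for (r in rows) {
    if (kind == "step")
      rec$data[r, at_sample:n] <- rec$data[r, at_sample:n] + size
    else
      rec$data[r, at_sample] <- rec$data[r, at_sample] + size
  }
  rec
}
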