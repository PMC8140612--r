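# Spectral quality control: does the bandpass filter keep the expected
# stimulus-driven frequency content (~0.05 Hz for this block design)
# while removing the ~1 Hz cardiac pulse and slow drift?

#' Welch power spectral density
#'
#' Averaged periodogram over Hann-windowed, 50%-overlapping segments.
#'
#' @param x numeric vector.
#' @param sfreq sample rate in Hz.
#' @param seg_len segment length in samples (default: 8 segments or the
#'   whole signal, whichever is shorter).
#' @return data.frame: `freq` (Hz), `power`.
#' @export
welch_psd <- function(x, sfreq, seg_len = NULL) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- max(16, min(n, floor(n / 4)))
  seg_len <- min(seg_len, n)
  step <- max(1, floor(seg_len / 2))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  pw <- acc / (length(starts) * sum(w^2) * sfreq)
  nf <- floor(seg_len / 2) + 1
  data.frame(freq = (seq_len(nf) - 1) * sfreq / seg_len,
             power = pw[seq_len(nf)])
}

#' Spectrum of the expected hemodynamic response
#'
#' Power spectrum of the model regressor (event boxcars convolved with
#' the canonical HRF, all conditions pooled): the frequency content the
#' analysis filter must retain. For this block design the power
#' concentrates near 0.05 Hz, the average presentation rate.
#'
#' @param schedule events data.frame.
#' @param sfreq sample rate in Hz.
#' @param hrf an [hrf_params()].
#' @param n_samples optional signal length (default: schedule extent).
#' @return list of class `response_spectrum`: `spectrum` (data.frame),
#'   `peak_freq` (Hz).
#' @export
expected_response_spectrum <- function(schedule, sfreq,
                                       hrf = hrf_params(),
                                       n_samples = NULL) {
  schedule <- as_events(schedule)
  if (!nrow(schedule)) stop("schedule has no events")
  if (is.null(n_samples))
    n_samples <- ceiling((max(schedule$onset + schedule$duration) +
                            hrf$time_length) * sfreq)
  x <- numeric(n_samples)
  for (i in seq_len(nrow(schedule))) {
    r <- single_event_response(schedule$duration[i], sfreq, hrf)
    i0 <- round(schedule$onset[i] * sfreq) + 1
    if (i0 > n_samples) next
    idx <- i0:min(n_samples, i0 + length(r) - 1)
    x[idx] <- x[idx] + r[seq_along(idx)]
  }
  if (stats::var(x) == 0)
    return(structure(list(
      spectrum = data.frame(freq = numeric(0), power = numeric(0)),
      peak_freq = NA_real_), class = "response_spectrum"))
  ps <- welch_psd(x, sfreq)
  nz <- ps$freq > 0
  structure(list(spectrum = ps,
                 peak_freq = ps$freq[nz][which.max(ps$power[nz])]),
            class = "response_spectrum")
}

#' Analytic frequency response of FIR taps
#'
#' @param taps FIR coefficients.
#' @param freqs frequencies in Hz at which to evaluate.
#' @param sfreq sample rate in Hz.
#' @return numeric vector of magnitude responses.
#' @export
filter_frequency_response <- function(taps, freqs, sfreq) {
  vapply(freqs, function(f) {
    Mod(sum(taps * exp(-2i * pi * f / sfreq * (seq_along(taps) - 1))))
  }, 0)
}

#' Spectral quality-control report
#'
#' Combines three views: the mean raw-data spectrum across channels with
#' a 95% band, the expected-response spectrum from the event schedule,
#' and the analytic magnitude response of the analysis bandpass filter.
#' Flags are raised when the filter attenuates the expected-response
#' peak by more than 3 dB, or attenuates the cardiac peak (strongest raw
#' spectral peak in 0.7-1.45 Hz, when present) by less than 20 dB.
#'
#' @param rec a raw `fnirs_recording` (sfreq above 2 Hz for the cardiac
#'   check).
#' @param spec a [filter_spec()].
#' @param schedule events data.frame (default: the recording's events).
#' @return list of class `spectrum_report`: `raw` (freq, mean power,
#'   lower/upper band), `expected` (`response_spectrum`),
#'   `filter` (freq, magnitude), `cardiac_freq`,
#'   `response_attenuation_db`, `cardiac_attenuation_db`, `flags`.
#' @export
qc_report <- function(rec, spec = filter_spec(), schedule = rec$events) {
  psds <- apply(rec$data, 1, function(x) welch_psd(x, rec$sfreq)$power)
  freqs <- welch_psd(rec$data[1, ], rec$sfreq)$freq
  raw <- data.frame(freq = freqs,
                    power = rowMeans(psds),
                    lower = apply(psds, 1, stats::quantile, 0.025),
                    upper = apply(psds, 1, stats::quantile, 0.975))

  taps <- bandpass_taps(spec, rec$sfreq,
                        max_taps = 2 * (ncol(rec$data) - 1) - 1)
  filt <- data.frame(freq = freqs,
                     magnitude = filter_frequency_response(
                       taps, freqs, rec$sfreq))
  flags <- character(0)

  expected <- NULL
  resp_att <- NA_real_
  if (nrow(schedule)) {
    expected <- expected_response_spectrum(schedule, rec$sfreq)
    h <- filter_frequency_response(taps, expected$peak_freq, rec$sfreq)
    resp_att <- -20 * log10(max(h, 1e-12))
    if (resp_att > 3)
      flags <- c(flags, sprintf(
        "filter attenuates expected-response peak (%.3f Hz) by %.1f dB",
        expected$peak_freq, resp_att))
  }

  cardiac_freq <- NA_real_
  cardiac_att <- NA_real_
  if (rec$sfreq > 2) {
    band <- raw$freq >= 0.7 & raw$freq <= 1.45
    if (any(band)) {
      peak_power <- max(raw$power[band])
      # a cardiac peak must stand clear of the broadband floor
      if (peak_power > 5 * stats::median(raw$power[raw$freq > 0.5])) {
        cardiac_freq <- raw$freq[band][which.max(raw$power[band])]
        h <- filter_frequency_response(taps, cardiac_freq, rec$sfreq)
        cardiac_att <- -20 * log10(max(h, 1e-12))
        if (cardiac_att < 20)
          flags <- c(flags, sprintf(
            "filter only attenuates cardiac peak (%.2f Hz) by %.1f dB",
            cardiac_freq, cardiac_att))
      }
    }
  }
  structure(list(raw = raw, expected = expected, filter = filt,
                 cardiac_freq = cardiac_freq,
                 response_attenuation_db = resp_att,
                 cardiac_attenuation_db = cardiac_att, flags = flags),
            class = "spectrum_report")
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat("<spectrum_report>\n")
  if (!is.null(x$expected))
    cat(sprintf("  expected-response peak: %.3f Hz (filter loss %.2f dB)\n",
                x$expected$peak_freq, x$response_attenuation_db))
  if (is.na(x$cardiac_freq))
    cat("  no cardiac peak detected\n")
  else
    cat(sprintf("  cardiac peak: %.2f Hz (filter attenuation %.1f dB)\n",
                x$cardiac_freq, x$cardiac_attenuation_db))
  if (length(x$flags)) cat("  FLAGS:\n", paste("  -", x$flags, "\n"))
  else cat("  no flags\n")
  invisible(x)
}
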