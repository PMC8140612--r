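# Canonical double-gamma hemodynamic response function.

#' Canonical HRF parameters
#'
#' The standard double-gamma parameterization: a positive gamma density
#' peaking ~5 s after onset minus a scaled undershoot gamma. Delays and
#' dispersions are in seconds.
#'
#' @param peak_delay delay of response peak (s), default 6.
#' @param undershoot_delay delay of undershoot (s), default 16.
#' @param peak_dispersion dispersion of response (s), default 1.
#' @param undershoot_dispersion dispersion of undershoot (s), default 1.
#' @param undershoot_ratio ratio of undershoot to response, default 1/6.
#' @param time_length kernel support (s), default 32.
#' @return A list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, time_length = 32) {
  p <- list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
            peak_dispersion = peak_dispersion,
            undershoot_dispersion = undershoot_dispersion,
            undershoot_ratio = undershoot_ratio, time_length = time_length)
  if (any(unlist(p[1:4]) <= 0) || undershoot_ratio < 0 || time_length <= 0)
    stop("hrf parameters must be positive")
  structure(p, class = "hrf_params")
}

#' Sample the canonical HRF kernel
#'
#' Difference of two gamma densities (shape = delay / dispersion,
#' scale = dispersion), sampled at `sfreq` on `[0, time_length]` and
#' normalized to unit peak.
#'
#' @param params an [hrf_params()] object.
#' @param sfreq sample rate in Hz.
#' @return numeric vector, the kernel with `max(kernel) == 1`.
#' @export
canonical_hrf <- function(params = hrf_params(), sfreq) {
  stopifnot(sfreq > 0)
  t <- seq(0, params$time_length, by = 1 / sfreq)
  k <- stats::dgamma(t, shape = params$peak_delay / params$peak_dispersion,
                     scale = params$peak_dispersion) -
    params$undershoot_ratio *
      stats::dgamma(t, shape = params$undershoot_delay /
                           params$undershoot_dispersion,
                    scale = params$undershoot_dispersion)
  k / max(k)
}

# Response of one isolated event: unit boxcar of `duration` convolved with
# the canonical kernel. Returned at unit peak if `normalize`.
single_event_response <- function(duration, sfreq, params = hrf_params(),
                                  normalize = TRUE) {
  stopifnot(duration > 0)
  box <- rep(1, max(1L, round(duration * sfreq)))
  k <- canonical_hrf(params, sfreq)
  r <- conv_full(box, k)
  if (normalize) r / max(r) else r
}

# Full linear convolution (zero-padded FFT for speed on long signals).
conv_full <- function(x, y) {
  n <- length(x) + length(y) - 1L
  nfft <- stats::nextn(n, 2)
  re <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                        stats::fft(c(y, numeric(nfft - length(y)))),
                      inverse = TRUE)) / nfft
  re[seq_len(n)]
}
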