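# Shared fixtures: tiny montages with known geometry and quiet (noise-
# and systemic-free) simulation configurations. Everything is generated
# in code; no binary fixtures.

# n_long long channels (3 cm) plus n_short short channels (8 mm), laid
# out along the x axis so nearest-short assignment is unambiguous.
tiny_montage <- function(n_long = 2, n_short = 1) {
  src <- data.frame(label = paste0("S", seq_len(n_long + n_short)),
                    x = 0.1 * seq_len(n_long + n_short), y = 0, z = 0)
  det <- data.frame(label = paste0("D", seq_len(n_long + n_short)),
                    x = 0.1 * seq_len(n_long + n_short) +
                      c(rep(0.03, n_long), rep(0.008, n_short)),
                    y = 0, z = 0)
  fnirs_montage(src, det,
                data.frame(source = src$label, detector = det$label),
                roi_map = list(roi_a = seq_len(n_long)))
}

# deterministic single-row recording around a given trace
row_recording <- function(x, sfreq = 5.2, unit = "optical_density") {
  m <- tiny_montage(1, 0)
  fnirs_recording(rbind(x, x), unit, sfreq, m)
}

quiet_cfg <- function(...) {
  args <- list(mayer_amp = 0, cardiac_amp = 0, drift_scale = 0,
               noise_sd = 0)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}

# deterministic multi-tone probe with a step artifact, matching the
# frozen TDDR reference fixture
tddr_probe <- function(n = 200, sfreq = 5.2) {
  tt <- (1:n) / sfreq
  x <- 0.01 * sin(2 * pi * 0.05 * tt) +
    0.003 * sin(2 * pi * 0.33 * tt + 1) +
    0.002 * cos(2 * pi * 1.7 * tt)
  x[120:n] <- x[120:n] + 0.05
  x
}

center_rows <- function(x) x - rowMeans(x)
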