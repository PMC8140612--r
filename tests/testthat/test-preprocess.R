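test_that("optical density conversion is the log-ratio to the mean", {
  x <- c(1, 1, 1, 1)
  expect_true(all(to_optical_density(row_recording(x + 1,
    unit = "raw_intensity"))$data == 0))
  # OD difference between two samples is -log(I1/I2) regardless of the
  # mean reference, so an intensity dip of exp(-0.5) reads as +0.5 OD
  y <- c(1, exp(-0.5), 1, 1)
  od <- to_optical_density(row_recording(y, unit = "raw_intensity"))
  expect_equal(od$data[1, 2] - od$data[1, 1], 0.5, tolerance = 1e-12)
  # unit tags enforce pipeline order
  expect_error(to_optical_density(od), "raw intensity")
  bad <- row_recording(y, unit = "raw_intensity")
  bad$data[1, 1] <- 0
  expect_error(to_optical_density(bad), "nonpositive")
})

test_that("scalp-coupling index separates shared from independent cardiac", {
  set.seed(11)
  n <- 2000
  tt <- (1:n) / 5.2
  card <- sin(2 * pi * 1.1 * tt)
  m <- tiny_montage(2, 0)
  dat <- rbind(card + rnorm(n, sd = 0.2),          # good channel
               0.7 * card + rnorm(n, sd = 0.2),
               rnorm(n), rnorm(n))                 # bad channel
  rec <- fnirs_recording(dat, "optical_density", 5.2, m)
  rep_ <- scalp_coupling_index(rec)
  expect_gt(rep_$sci[1], 0.8)
  expect_lt(abs(rep_$sci[2]), 0.3)
  expect_equal(rep_$dropped, 2L)
  expect_equal(rep_$kept, 1L)

  # perfectly anti-correlated wavelengths give SCI -1
  anti <- fnirs_recording(rbind(card, -card, card, card),
                          "optical_density", 5.2, m)
  expect_equal(scalp_coupling_index(anti)$sci[1], -1, tolerance = 1e-9)

  # infeasible at low sample rate (why SCI is skipped at 1 Hz)
  lo <- fnirs_recording(dat, "optical_density", 1, m)
  expect_error(scalp_coupling_index(lo), "cardiac band")
  expect_error(scalp_coupling_index(to_optical_density(
    fnirs_recording(dat - min(dat) + 1, "raw_intensity", 5.2, m))),
    NA)
})

test_that("TDDR matches the cited reference implementation", {
  x <- tddr_probe()
  ref <- scan(test_path("tddr_reference.txt"), quiet = TRUE)
  out <- tddr(row_recording(x))
  expect_lt(max(abs(out$data[1, ] - ref)), 1e-8)
})

test_that("TDDR removes steps, keeps inlier signal, preserves the mean", {
  set.seed(3)
  n <- 2912
  tt <- (1:n) / 5.2
  clean <- 0.01 * sin(2 * pi * 0.05 * tt) + rnorm(n, sd = 0.004)
  rng <- diff(range(clean))

  # step of 10x signal sd: level shift reduced by >= 80%
  stepped <- clean
  stepped[1500:n] <- stepped[1500:n] + 10 * sd(clean)
  out <- tddr(row_recording(stepped))$data[1, ]
  shift_in <- mean(stepped[1600:2000]) - mean(stepped[1000:1400])
  shift_out <- mean(out[1600:2000]) - mean(out[1000:1400])
  expect_lt(abs(shift_out), 0.2 * abs(shift_in))
  # the mean is approximately preserved (exactly for the low band)
  expect_equal(mean(out), mean(stepped), tolerance = 1e-3)

  # all-zero input passes through untouched
  z <- tddr(row_recording(rep(0, 100)))
  expect_true(all(z$data == 0))
  expect_error(tddr(row_recording(c(0, 1))), "3 samples")
})

test_that("short-channel regression removes what the short channel sees", {
  m <- tiny_montage(1, 1)
  set.seed(4)
  s <- rnorm(500)
  # long = 2 x short exactly: fully removed (up to the mean)
  dat <- rbind(2 * s, 2 * s, s, s)
  rec <- fnirs_recording(dat, "optical_density", 5.2, m)
  out <- short_channel_regress(rec)
  expect_lt(max(abs(out$data[1, ] - mean(2 * s))), 1e-9)

  # orthogonal long is untouched
  o <- rnorm(500)
  o <- o - mean(o)
  o <- o - sum(o * (s - mean(s))) / sum((s - mean(s))^2) * (s - mean(s))
  rec2 <- fnirs_recording(rbind(o, o, s, s), "optical_density", 5.2, m)
  out2 <- short_channel_regress(rec2)
  expect_equal(out2$data[1, ], o, tolerance = 1e-9,
               ignore_attr = TRUE)

  # least-squares optimality: never increases variance
  y <- rnorm(500) + 0.5 * s
  rec3 <- fnirs_recording(rbind(y, y, s, s), "optical_density", 5.2, m)
  out3 <- short_channel_regress(rec3)
  expect_lte(var(out3$data[1, ]), var(y))

  expect_error(short_channel_regress(
    fnirs_recording(matrix(1, 2, 5), "optical_density", 5.2,
                    tiny_montage(1, 0))), "no short channels")
})

test_that("shared-systemic simulation is cleaned by short regression", {
  cfg <- sim_config(mayer_amp = 4, noise_sd = 0.2, seed = 12,
                    trials_per_condition = 5)
  sess <- generate_session(cfg, 1)
  od <- to_optical_density(sess$recording)
  corr <- short_channel_regress(od)
  stg_row <- which(od$rows$channel == od$montage$roi_map$left_STG[1])[1]
  expect_lt(var(corr$data[stg_row, ]), var(od$data[stg_row, ]))
  # corrected trace correlates better with the neural ground truth
  neural_od <- sess$truth$neural[
    sess$truth$rows$channel == od$rows$channel[stg_row] &
      sess$truth$rows$chroma == "hbo", ]
  expect_gt(abs(cor(corr$data[stg_row, ], neural_od)),
            abs(cor(od$data[stg_row, ], neural_od)))
})

test_that("Beer-Lambert inverts a hand-solved 2x2 system and is linear", {
  # E = [[1,2],[3,1]], d_cm * ppf = 1, OD = [5,5] -> conc = [1, 2]
  src <- data.frame(label = "S1", x = 0, y = 0, z = 0)
  det <- data.frame(label = "D1", x = 0.1, y = 0, z = 0)  # 10 cm
  m <- fnirs_montage(src, det,
                     data.frame(source = "S1", detector = "D1"))
  E <- matrix(c(1, 3, 2, 1), 2, 2,
              dimnames = list(c("760", "850"), c("hbo", "hbr")))
  rec <- fnirs_recording(matrix(5, 2, 4), "optical_density", 5.2, m)
  hb <- beer_lambert(rec, ppf = 0.1, extinctions = E)
  expect_equal(unname(hb$data[, 1]), c(1, 2) * 1e6, tolerance = 1e-9)
  expect_identical(hb$unit, "molar")
  expect_identical(hb$rows$chroma, c("hbo", "hbr"))

  # zero OD maps to zero concentration; linear in the input
  rec0 <- fnirs_recording(matrix(0, 2, 4), "optical_density", 5.2, m)
  expect_true(all(beer_lambert(rec0, extinctions = E)$data == 0))
  rec2 <- rec
  rec2$data <- 3 * rec2$data
  expect_equal(beer_lambert(rec2, ppf = 0.1, extinctions = E)$data,
               3 * hb$data, tolerance = 1e-12)

  Esing <- matrix(c(1, 2, 2, 4), 2, 2)
  expect_error(beer_lambert(rec, extinctions = Esing), "singular")
  expect_error(beer_lambert(hb), "optical density")
})

test_that("anti-correlation enhancement has its fixed point and contract", {
  m <- tiny_montage(1, 0)
  set.seed(5)
  a <- rnorm(300) + sin((1:300) / 10)
  # input already satisfying hbr = -hbo/beta is unchanged
  rec <- fnirs_recording(rbind(a, -a / 3), "molar", 5.2, m,
                         rows = data.frame(channel = 1,
                                           chroma = c("hbo", "hbr")))
  out <- negative_correlation_enhance(rec)
  expect_equal(out$data[1, ], a, tolerance = 1e-9, ignore_attr = TRUE)

  # any nondegenerate input becomes exactly anti-correlated
  b <- rnorm(300)
  rec2 <- fnirs_recording(rbind(a, b), "molar", 5.2, m,
                          rows = rec$rows)
  out2 <- negative_correlation_enhance(rec2)
  expect_equal(cor(out2$data[1, ], out2$data[2, ]), -1,
               tolerance = 1e-9)

  rec3 <- fnirs_recording(rbind(a, rep(0, 300)), "molar", 5.2, m,
                          rows = rec$rows)
  expect_error(negative_correlation_enhance(rec3), "sd\\(HbR\\)")
})

test_that("bandpass keeps the response band and kills drift and pulse", {
  sfreq <- 3
  tt <- seq(0, 1200, by = 1 / sfreq)
  mid <- seq(round(length(tt) * 0.3), round(length(tt) * 0.7))
  # DC is outside the passband (>= 40 dB down)
  dc <- bandpass_filter(row_recording(rep(2, length(tt)), sfreq = sfreq))
  expect_lt(max(abs(dc$data[1, mid])), 2 * 0.01)
  expect_lt(abs(mean(dc$data[1, mid])), 0.02)
  # 0.05 Hz passes within 10%
  s5 <- bandpass_filter(row_recording(sin(2 * pi * 0.05 * tt),
                                      sfreq = sfreq))
  expect_gt(max(abs(s5$data[1, mid])), 0.9)
  expect_lt(max(abs(s5$data[1, mid])), 1.1)
  # 1 Hz attenuated by >= 20 dB
  s1 <- bandpass_filter(row_recording(sin(2 * pi * 1 * tt),
                                      sfreq = sfreq))
  expect_lt(max(abs(s1$data[1, mid])), 0.1)
  # infeasible band errors
  expect_error(bandpass_taps(filter_spec(), 1), "infeasible")
})

test_that("resampling preserves slow content, duration and events", {
  cfg <- quiet_cfg(trials_per_condition = 1, seed = 2)
  sess <- generate_session(cfg, 1)
  rec <- sess$recording
  same <- resample_recording(rec, rec$sfreq)
  expect_identical(same$data, rec$data)

  tt <- seq(0, 1200, by = 1 / 5.2)
  x <- sin(2 * pi * 0.05 * tt)
  rec2 <- row_recording(x + 2, sfreq = 5.2, unit = "raw_intensity")
  r06 <- resample_recording(rec2, 0.6)
  mid <- seq(round(ncol(r06$data) * 0.3), round(ncol(r06$data) * 0.7))
  expect_equal(max(abs(r06$data[1, mid] - 2)), 1, tolerance = 0.05)
  # duration preserved within one (new) sample period
  expect_lt(abs(ncol(r06$data) / 0.6 - ncol(rec2$data) / 5.2), 1 / 0.6 + 1e-9)
  # events are in seconds and unchanged
  r3 <- resample_recording(rec, 3)
  expect_equal(r3$events, rec$events)
  expect_error(resample_recording(rec, -1), "positive")
  expect_error(resample_recording(rec, 10), "upsampling")
})

test_that("pruning drops out-of-range and poorly coupled channels only", {
  m <- build_paper_montage()
  rec <- fnirs_recording(matrix(1, 64, 10), "raw_intensity", 5.2, m)
  # all long channels in bounds: nothing dropped
  expect_equal(nrow(prune_channels(rec)$montage$channels), 32)
  # shrink the head so some channels fall under 20 mm
  m2 <- build_paper_montage(scale = 0.68)
  d2 <- sd_distance(m2)
  out2 <- prune_channels(fnirs_recording(matrix(1, 64, 10),
                                         "raw_intensity", 5.2, m2))
  kinds <- channel_kinds(m2)
  expected_keep <- sum(kinds == "short" |
                         (d2 >= 0.02 & d2 <= 0.04))
  expect_equal(nrow(out2$montage$channels), expected_keep)
  # SCI flags remove exactly the flagged long channels
  fake_sci <- structure(list(sci = rep(1, 32), threshold = 0.8,
                             kept = setdiff(1:32, c(3, 7, 9)),
                             dropped = c(3L, 7L, 9L)),
                        class = "sci_report")
  out3 <- prune_channels(rec, sci_report = fake_sci)
  expect_equal(nrow(out3$montage$channels), 29)
  # dropping everything is an error
  m3 <- build_paper_montage(scale = 0.4)
  expect_error(prune_channels(fnirs_recording(matrix(1, 64, 10),
                                              "raw_intensity", 5.2, m3)),
               "every long channel")
})

test_that("bandpass and resample commute for in-band content", {
  tt <- seq(0, 1200, by = 1 / 5.2)
  x <- sin(2 * pi * 0.05 * tt) + 0.5 * sin(2 * pi * 0.2 * tt + 1)
  rec <- row_recording(x, sfreq = 5.2)
  spec <- filter_spec(h_freq = 0.5, h_trans = 0.2)
  a <- resample_recording(bandpass_filter(rec, spec), 2)
  b <- bandpass_filter(resample_recording(rec, 2), spec)
  mid <- seq(round(ncol(a$data) * 0.3), round(ncol(a$data) * 0.7))
  expect_lt(max(abs(a$data[1, mid] - b$data[1, mid])), 0.05)
})
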