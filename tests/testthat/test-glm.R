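test_that("canonical HRF has the standard double-gamma shape", {
  k <- canonical_hrf(hrf_params(), sfreq = 10)
  t <- seq(0, 32, by = 0.1)
  # gamma density with shape 6, scale 1 has its mode at (6-1)*1 = 5 s
  expect_lt(abs(t[which.max(k)] - 5), 0.1 + 1e-9)
  expect_equal(max(k), 1)
  expect_equal(k[1], 0)                      # density zero at origin
  # no undershoot: a pure gamma density, nonnegative everywhere
  k0 <- canonical_hrf(hrf_params(undershoot_ratio = 0), sfreq = 10)
  expect_true(all(k0 >= 0))
  # with the undershoot the tail dips negative
  expect_lt(min(k), 0)
  expect_error(hrf_params(peak_delay = -1), "positive")
})

test_that("design matrices carry the advertised columns", {
  ev <- data.frame(onset = c(20, 80, 140), duration = 5,
                   condition = c("speech", "noise", "silence"))
  d <- build_design(ev, sfreq = 1, n_samples = 300)
  # T = 300 s, drift_hf = 0.01: k/(2T) <= 0.01 for k = 1..6
  expect_equal(sum(grepl("^drift_", colnames(d$X))), 6)
  expect_true("constant" %in% colnames(d$X))
  expect_setequal(d$condition_cols, c("speech", "noise", "silence"))
  expect_false(any(duplicated(colnames(d$X))))
  # drift columns are orthogonal to the constant
  drifts <- d$X[, grepl("^drift_", colnames(d$X)), drop = FALSE]
  expect_lt(max(abs(colSums(drifts))), 1e-8)

  # silence is modelled: its column is nonzero (the false-positive probe)
  sil <- data.frame(onset = c(20, 60), duration = 5,
                    condition = "silence")
  ds <- build_design(sil, 1, 150)
  expect_gt(max(abs(ds$X[, "silence"])), 0.5)

  # FIR: 14 columns per condition at 1 Hz
  df <- build_design(ev, 1, 300, basis = "fir")
  expect_equal(sum(grepl("^speech_delay", colnames(df$X))), 14)
  expect_equal(length(df$condition_cols), 42)
  expect_error(build_design(ev, 1, 300, basis = "fir", boxcar_dur = 3),
               "does not apply")
  expect_error(build_design(ev, 1, 300, boxcar_dur = -1), "positive")
  expect_error(build_design(ev[0, ], 1, 300), "at least one event")
})

test_that("canonical regressors have unit isolated-event peak", {
  ev <- data.frame(onset = 30, duration = 5, condition = "speech")
  d <- build_design(ev, sfreq = 2, n_samples = 200)
  expect_equal(max(d$X[, "speech"]), 1, tolerance = 0.01)
})

test_that("nuisance columns follow the specification", {
  cfg <- sim_config(trials_per_condition = 2, seed = 17)
  sess <- generate_session(cfg, 1)
  rec <- beer_lambert(to_optical_density(sess$recording))

  pca_all <- nuisance_columns(rec, nuisance_spec("short_pca_all"), "hbo")
  expect_equal(ncol(pca_all), 8)             # 8 short channels: rank bound
  # PCA columns are mutually orthogonal
  g <- crossprod(pca_all)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-8)

  ind <- nuisance_columns(rec, nuisance_spec("short_individual"), "hbo")
  expect_equal(ncol(ind), 8)
  mn <- nuisance_columns(rec, nuisance_spec("short_mean"), "hbo")
  expect_equal(ncol(mn), 1)
  expect_equal(mn[, 1], colMeans(t(ind)), ignore_attr = TRUE)

  expect_equal(ncol(nuisance_columns(rec, nuisance_spec("none"), "hbo")),
               0)
  expect_error(nuisance_columns(rec, nuisance_spec("short_pca", 9),
                                "hbo"), "9 PCs")

  # with one short channel, mean and individual coincide
  keep <- c(rec$montage$roi_map$left_STG, 25)
  rec1 <- subset_channels(rec, keep)
  m1 <- nuisance_columns(rec1, nuisance_spec("short_mean"), "hbo")
  i1 <- nuisance_columns(rec1, nuisance_spec("short_individual"), "hbo")
  expect_equal(unname(m1), unname(i1))
})

test_that("noiseless data is fitted exactly", {
  ev <- data.frame(onset = c(30, 90), duration = 5,
                   condition = "speech")
  d <- build_design(ev, 1, 200)
  m <- tiny_montage(1, 0)
  y <- 2 * d$X[, "speech"]
  rec <- fnirs_recording(matrix(y, 1), "molar", 1, m, events = ev,
                         rows = data.frame(channel = 1, chroma = "hbo"))
  fit <- fit_glm(rec, d, ar_order = 0)
  row <- fit$results[fit$results$regressor == "speech", ]
  expect_equal(row$beta, 2, tolerance = 1e-9)
  expect_lt(row$se, 1e-9)
  expect_gt(row$p, 0)                        # p stays in (0, 1]
})

test_that("prewhitening recovers AR structure and keeps betas unbiased", {
  set.seed(21)
  ev <- data.frame(onset = seq(20, 1900, by = 25), duration = 5,
                   condition = rep(c("speech", "silence"), length.out = 76))
  n <- 2000
  d <- build_design(ev, 1, n)
  m <- tiny_montage(1, 0)

  # white noise: estimated AR coefficients all near zero
  rec_w <- fnirs_recording(matrix(rnorm(n), 1), "molar", 1, m,
                           events = ev,
                           rows = data.frame(channel = 1, chroma = "hbo"))
  fit_w <- fit_glm(rec_w, d, ar_order = 4)
  expect_lt(max(abs(fit_w$ar$coef)), 0.1)

  # AR(1) noise with a true effect: beta within 2 SE, phi recovered
  phi <- 0.6
  noise <- as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - phi^2)),
                                    phi, method = "recursive"))
  y <- 1.5 * d$X[, "speech"] + noise
  rec_a <- fnirs_recording(matrix(y, 1), "molar", 1, m, events = ev,
                           rows = data.frame(channel = 1, chroma = "hbo"))
  fit_a <- fit_glm(rec_a, d, ar_order = 1)
  row <- fit_a$results[fit_a$results$regressor == "speech", ]
  expect_lt(abs(row$beta - 1.5), 2 * row$se)
  expect_gt(fit_a$ar$coef[1], 0.45)
  expect_lt(fit_a$ar$coef[1], 0.75)
})

test_that("rank-deficient designs fail loudly with the offending columns", {
  ev <- data.frame(onset = 30, duration = 5, condition = "speech")
  d <- build_design(ev, 1, 100)
  d$X <- cbind(d$X, dup = d$X[, "speech"])
  m <- tiny_montage(1, 0)
  rec <- fnirs_recording(matrix(rnorm(100), 1), "molar", 1, m,
                         events = ev,
                         rows = data.frame(channel = 1, chroma = "hbo"))
  expect_error(fit_glm(rec, d), "collinear")
})

test_that("nuisance columns orthogonal to conditions leave betas alone", {
  set.seed(22)
  ev <- data.frame(onset = seq(20, 460, by = 30), duration = 5,
                   condition = rep(c("speech", "noise"), length.out = 15))
  n <- 500
  d <- build_design(ev, 1, n)
  m <- tiny_montage(1, 0)
  y <- 1.2 * d$X[, "speech"] + rnorm(n)
  rec <- fnirs_recording(matrix(y, 1), "molar", 1, m, events = ev,
                         rows = data.frame(channel = 1, chroma = "hbo"))
  f0 <- fit_glm(rec, d, ar_order = 0)

  # orthogonalize a random column against the whole design
  z <- rnorm(n)
  z <- z - d$X %*% qr.coef(qr(d$X), z)
  d2 <- d
  d2$X <- cbind(d$X, extra = as.numeric(z))
  f2 <- fit_glm(rec, d2, ar_order = 0)
  b0 <- f0$results[f0$results$regressor == "speech", "beta"]
  b2 <- f2$results[f2$results$regressor == "speech", "beta"]
  expect_lt(abs(b0 - b2), 1e-9)
})

test_that("ROI pooling is the inverse-SE weighted mean", {
  # hand oracle: (2, se 1) and (4, se 2) pool to (2/1 + 4/2)/(1 + 1/2) = 8/3
  m <- tiny_montage(2, 0)
  fake <- structure(list(
    results = data.frame(
      channel = c(1, 2), label = c("a", "b"), chroma = "hbo",
      regressor = "speech", beta = c(2, 4), se = c(1, 2),
      t = 1, p = 0.5, dof = 10),
    design = list(condition_cols = "speech"),
    montage = m), class = "fnirs_glm")
  po <- pool_roi(fake, "roi_a")
  expect_equal(po$beta, 8 / 3, tolerance = 1e-12)
  expect_equal(po$se, sqrt(1 + 1) / 1.5, tolerance = 1e-12)

  # equal SEs reduce to the simple mean; huge-SE channels lose their say
  fake$results$se <- c(1, 1)
  expect_equal(pool_roi(fake, "roi_a")$beta, 3)
  fake$results$se <- c(1, 1000)
  expect_lt(abs(pool_roi(fake, "roi_a")$beta - 2), 0.01)

  # single-channel ROI is the identity
  fake$montage$roi_map$one <- 1L
  fake$results$se <- c(1, 2)
  expect_equal(pool_roi(fake, "one")$beta, 2)
  expect_equal(pool_roi(fake, "one")$se, 1)

  # inverse-variance option
  fake$results$se <- c(1, 2)
  expect_equal(pool_roi(fake, "roi_a", weighting = "inv_var")$beta,
               (2 / 1 + 4 / 4) / (1 + 1 / 4))
})

test_that("FIR deconvolution recovers the true response shape", {
  # events on the analysis grid, noiseless: FIR betas = response samples
  cfg <- quiet_cfg(isi_bounds = c(35, 45), trials_per_condition = 3,
                   sfreq = 1, seed = 23)
  set.seed(23)
  sch <- generate_events(cfg)
  sch$onset <- round(sch$onset)
  m <- build_paper_montage()
  truth <- generate_neural(cfg, sch, m)
  rec <- fnirs_recording(truth$neural, "molar", 1, m, events = sch,
                         rows = truth$rows)
  d <- build_design(sch, 1, ncol(rec$data), basis = "fir")
  fit <- fit_glm(rec, d, ar_order = 0,
                 channels = m$roi_map$left_STG)
  fw <- fir_waveform(fit, "left_STG")
  sp <- fw[fw$condition == "speech" & fw$chroma == "hbo", ]
  ch <- m$roi_map$left_STG[1]
  true_tr <- truth$neural[truth$rows$channel == ch &
                            truth$rows$chroma == "hbo", ]
  # isolated response at integer delays
  ev1 <- sch$onset[sch$condition == "speech"][1]
  true_resp <- true_tr[ev1 + sp$delay + 1] -
    sum(true_tr[ev1 + sp$delay + 1] * 0)   # trace is zero before onset
  # remove contributions of other events: far apart, so direct read-off
  expect_equal(sp$value, unname(true_resp),
               tolerance = 0.02 * max(true_resp))
  # silence curve is flat
  sil <- fw[fw$condition == "silence" & fw$chroma == "hbo", ]
  expect_lt(max(abs(sil$value)), 0.02 * max(true_resp))
  # canonical fit refuses to deconvolve
  dc <- build_design(sch, 1, ncol(rec$data))
  fc <- fit_glm(rec, dc, ar_order = 0, channels = ch)
  expect_error(fir_waveform(fc, "left_STG"), "FIR-basis")
})
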