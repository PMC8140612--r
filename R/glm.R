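# GLM analysis: design-matrix construction (canonical HRF or FIR bases,
# cosine drifts, short-channel nuisance variants), AR-prewhitened
# least-squares fitting, and inverse-standard-error ROI pooling.

#' Build a GLM design matrix
#'
#' Canonical basis: one regressor per condition, a unit boxcar of
#' `boxcar_dur` seconds (default: each event's own duration) convolved
#' with the canonical HRF and scaled so the response to one isolated
#' event has unit peak - which makes betas directly interpretable as peak
#' response amplitudes in the data's units. FIR basis: `fir_n` regressors
#' per condition, each a one-second stick at integer delays 0 to
#' `fir_n - 1` after onset, deconvolving the response shape without any
#' HRF assumption. Both get a cosine drift set with frequencies
#' `k / (2T) <= drift_hf` plus a constant column.
#'
#' @param schedule events data.frame (`onset`, `duration`, `condition`).
#' @param sfreq sample rate of the data to be fitted (Hz).
#' @param n_samples number of samples in the data.
#' @param basis `"canonical"` or `"fir"`.
#' @param boxcar_dur boxcar duration in s for the canonical basis;
#'   `NULL` (default) uses each event's recorded duration. Must be unset
#'   for the FIR basis.
#' @param fir_n number of FIR components (seconds), default 14.
#' @param drift_hf highest drift frequency in Hz (default 0.01).
#' @param hrf an [hrf_params()] for the canonical basis.
#' @return list of class `fnirs_design`: `X` (samples x regressors, named
#'   columns), `condition_cols`, `basis`, `sfreq`, plus FIR bookkeeping.
#' @export
build_design <- function(schedule, sfreq, n_samples,
                         basis = c("canonical", "fir"), boxcar_dur = NULL,
                         fir_n = 14, drift_hf = 0.01, hrf = hrf_params()) {
  basis <- match.arg(basis)
  schedule <- as_events(schedule)
  if (!nrow(schedule)) stop("design needs at least one event")
  if (!is.null(boxcar_dur)) {
    if (basis == "fir") stop("boxcar_dur does not apply to the FIR basis")
    if (boxcar_dur <= 0) stop("boxcar_dur must be positive")
  }
  conds <- unique(schedule$condition)
  cols <- list()
  if (basis == "canonical") {
    # regressors are built on an oversampled grid (>= ~10 Hz) so that
    # event onsets and the kernel peak are resolved accurately, then
    # decimated to the analysis grid
    L <- max(1L, ceiling(10 / sfreq))
    f_hi <- L * sfreq
    n_hi <- n_samples * L
    for (cond in conds) {
      x <- numeric(n_hi)
      onsets <- schedule$onset[schedule$condition == cond]
      durs <- if (is.null(boxcar_dur))
        schedule$duration[schedule$condition == cond]
      else rep(boxcar_dur, length(onsets))
      for (j in seq_along(onsets)) {
        r <- single_event_response(durs[j], f_hi, hrf)
        i0 <- round(onsets[j] * f_hi) + 1
        if (i0 > n_hi) next
        idx <- i0:min(n_hi, i0 + length(r) - 1)
        x[idx] <- x[idx] + r[seq_along(idx)]
      }
      cols[[cond]] <- x[seq(1, n_hi, by = L)]
    }
  } else {
    stick <- max(1L, round(sfreq))           # one-second stick
    for (cond in conds) {
      onsets <- schedule$onset[schedule$condition == cond]
      for (d in 0:(fir_n - 1)) {
        x <- numeric(n_samples)
        for (onset in onsets) {
          i0 <- round((onset + d) * sfreq) + 1
          if (i0 > n_samples) next
          idx <- i0:min(n_samples, i0 + stick - 1)
          x[idx] <- x[idx] + 1
        }
        cols[[sprintf("%s_delay%02d", cond, d)]] <- x
      }
    }
  }
  condition_cols <- names(cols)
  X <- do.call(cbind, cols)

  T_s <- n_samples / sfreq
  k_max <- floor(2 * T_s * drift_hf)
  if (k_max > 0) {
    tt <- seq_len(n_samples) - 0.5
    for (k in seq_len(k_max))
      X <- cbind(X, drift = cos(pi * k * tt / n_samples))
    colnames(X)[(length(condition_cols) + 1):ncol(X)] <-
      paste0("drift_", seq_len(k_max))
  }
  X <- cbind(X, constant = 1)
  structure(list(X = X, condition_cols = condition_cols, basis = basis,
                 sfreq = sfreq, fir_n = if (basis == "fir") fir_n else NULL,
                 conditions = conds, boxcar_dur = boxcar_dur),
            class = "fnirs_design")
}

#' Short-channel nuisance specification
#'
#' How short-channel information enters the GLM as regressors of no
#' interest: `none`, the `short_mean` over short channels (per
#' chromophore), every `short_individual` short channel, the first `k`
#' principal components (`short_pca`), or all components
#' (`short_pca_all`).
#'
#' @param method one of `"none"`, `"short_mean"`, `"short_individual"`,
#'   `"short_pca"`, `"short_pca_all"`.
#' @param k number of principal components for `"short_pca"`.
#' @return list of class `nuisance_spec`.
#' @export
nuisance_spec <- function(method = c("none", "short_mean",
                                     "short_individual", "short_pca",
                                     "short_pca_all"), k = 1) {
  method <- match.arg(method)
  if (method == "short_pca" && k < 1) stop("k must be >= 1")
  structure(list(method = method, k = as.integer(k)),
            class = "nuisance_spec")
}

#' Build short-channel nuisance columns
#'
#' Extracts the short-channel rows of the given chromophore and turns
#' them into the regressor set named by `spec`. PCA components are the
#' left singular vectors of the centred short-channel matrix (mutually
#' orthogonal time courses).
#'
#' @param rec an `fnirs_recording` that still contains short channels.
#' @param spec a [nuisance_spec()].
#' @param chroma chromophore/wavelength tag to match (e.g. `"hbo"`).
#' @return numeric matrix (possibly zero columns) with named columns.
#' @export
nuisance_columns <- function(rec, spec, chroma) {
  if (spec$method == "none")
    return(matrix(numeric(0), nrow = ncol(rec$data), ncol = 0))
  shorts <- which(channel_kinds(rec$montage) == "short")
  shorts <- intersect(shorts, rec$rows$channel)
  if (!length(shorts)) stop("no short channels available for nuisance")
  ix <- which(rec$rows$channel %in% shorts & rec$rows$chroma == chroma)
  S <- t(rec$data[ix, , drop = FALSE])     # samples x n_short
  switch(spec$method,
    short_mean = {
      out <- matrix(rowMeans(S), ncol = 1)
      colnames(out) <- "short_mean"
      out
    },
    short_individual = {
      colnames(S) <- paste0("short_", seq_len(ncol(S)))
      S
    },
    short_pca = ,
    short_pca_all = {
      if (spec$method == "short_pca" && spec$k > ncol(S))
        stop("requested ", spec$k, " PCs from ", ncol(S),
             " short channels")
      sv <- svd(scale(S, scale = FALSE))
      rank <- sum(sv$d > max(sv$d) * 1e-12)
      k <- if (spec$method == "short_pca_all") rank
           else min(spec$k, rank)
      out <- sv$u[, seq_len(k), drop = FALSE]
      colnames(out) <- paste0("short_pc", seq_len(ncol(out)))
      out
    })
}

#' Fit a prewhitened GLM to every channel
#'
#' Per data row: ordinary least squares, AR(`ar_order`) noise
#' coefficients estimated from the residuals by Yule-Walker, data and
#' design filtered by the whitening filter `1 - sum(a_i z^-i)` (one
#' pass), and OLS refitted on the whitened quantities. Betas, standard
#' errors, t and two-sided p values come from the whitened normal
#' equations with `dof = n_whitened - n_regressors`.
#'
#' @param rec an `fnirs_recording` with `unit = "molar"` (or OD).
#' @param design an [build_design()] object for this recording's length
#'   and sample rate.
#' @param nuisance a [nuisance_spec()]; short-channel columns are drawn
#'   from `rec` separately per chromophore.
#' @param ar_order autoregressive model order (default 4; 0 disables
#'   prewhitening).
#' @param channels channel indices to fit (default: all long channels).
#' @return list of class `fnirs_glm`: `results` (tidy data.frame:
#'   `channel`, `label`, `chroma`, `regressor`, `beta`, `se`, `t`, `p`,
#'   `dof`), `ar` (per-row AR coefficients), `design`, `montage`.
#' @export
fit_glm <- function(rec, design, nuisance = nuisance_spec("none"),
                    ar_order = 4,
                    channels = which(channel_kinds(rec$montage) == "long")) {
  stopifnot(inherits(design, "fnirs_design"))
  if (ncol(rec$data) != nrow(design$X))
    stop("design has ", nrow(design$X), " samples but data has ",
         ncol(rec$data))
  channels <- intersect(channels, rec$rows$channel)
  labels <- channel_labels(rec$montage)
  res <- list()
  ars <- list()
  for (tag in unique(rec$rows$chroma)) {
    Xn <- nuisance_columns(rec, nuisance, tag)
    X <- cbind(design$X, Xn)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("rank-deficient design; collinear columns: ",
           paste(dropped, collapse = ", "))
    }
    for (ch in channels) {
      ri <- rows_idx(rec$rows, ch, tag)
      if (!length(ri)) next
      y <- rec$data[ri, ]
      fit <- whitened_fit(y, X, qrX, ar_order)
      res[[length(res) + 1]] <- data.frame(
        channel = ch, label = labels[ch], chroma = tag,
        regressor = colnames(X), beta = fit$beta, se = fit$se,
        t = fit$t, p = fit$p, dof = fit$dof,
        row.names = NULL, stringsAsFactors = FALSE)
      if (length(fit$ar))
        ars[[length(ars) + 1]] <- data.frame(
          channel = ch, chroma = tag,
          order = seq_along(fit$ar), coef = fit$ar,
          row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  structure(list(results = do.call(rbind, res),
                 ar = do.call(rbind, ars),
                 design = design, montage = rec$montage,
                 ar_order = ar_order, nuisance = nuisance),
            class = "fnirs_glm")
}

whitened_fit <- function(y, X, qrX, ar_order) {
  n <- length(y)
  beta0 <- qr.coef(qrX, y)
  resid <- y - X %*% beta0
  a <- numeric(0)
  if (ar_order > 0 && stats::var(as.numeric(resid)) > 1e-28) {
    arfit <- stats::ar.yw(as.numeric(resid), aic = FALSE,
                          order.max = ar_order, demean = TRUE)
    a <- as.numeric(arfit$ar)
  }
  if (length(a)) {
    yw <- whiten(y, a)
    Xw <- apply(X, 2, whiten, a = a)
  } else {
    yw <- y
    Xw <- X
  }
  qrW <- qr(Xw)
  beta <- qr.coef(qrW, yw)
  dof <- length(yw) - ncol(Xw)
  rw <- yw - Xw %*% beta
  sigma2 <- sum(rw^2) / dof
  XtXinv <- chol2inv(qr.R(qrW))
  se <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
  tval <- ifelse(se > 0, beta / se,
                 ifelse(beta == 0, 0, sign(beta) * Inf))
  p <- 2 * stats::pt(-abs(tval), dof)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(beta = as.numeric(beta), se = se, t = as.numeric(tval),
       p = as.numeric(p), dof = dof, ar = a)
}

# apply whitening filter 1 - sum a_i z^-i and drop the warm-up samples
whiten <- function(x, a) {
  n <- length(x)
  p <- length(a)
  out <- x
  for (i in seq_len(p)) out[(1 + i):n] <- out[(1 + i):n] - a[i] * x[1:(n - i)]
  out[(p + 1):n]
}

#' Pool channel estimates into an ROI
#'
#' Inverse-standard-error weighted average of channel betas:
#' `beta_roi = sum(b_i / se_i) / sum(1 / se_i)`, pooled SE
#' `sqrt(sum(w_i^2 se_i^2)) / sum(w_i)`, p from a normal approximation.
#' `weighting = "inv_var"` uses `1/se^2` weights instead.
#'
#' @param fit an `fnirs_glm`.
#' @param roi ROI name in the fit's montage.
#' @param regressors regressors to pool (default: condition columns).
#' @param weighting `"inv_se"` (default) or `"inv_var"`.
#' @param one_sided if `TRUE`, p values are one-sided for a positive
#'   effect (the directional "response present" convention); default
#'   two-sided.
#' @return data.frame: `roi`, `regressor`, `chroma`, `beta`, `se`, `p`,
#'   `n_channels`.
#' @export
pool_roi <- function(fit, roi, regressors = fit$design$condition_cols,
                     weighting = c("inv_se", "inv_var"),
                     one_sided = FALSE) {
  weighting <- match.arg(weighting)
  chans <- roi_channels(fit$montage, roi)
  if (!length(chans)) stop("ROI ", roi, " has no channels")
  r <- fit$results
  out <- list()
  for (reg in regressors) {
    for (tag in unique(r$chroma)) {
      sel <- r$channel %in% chans & r$chroma == tag & r$regressor == reg
      if (!any(sel)) next
      b <- r$beta[sel]; se <- r$se[sel]
      # exact (zero-SE) fits would give infinite weight; floor the SE so
      # they share weight equally instead of producing Inf/Inf
      se_w <- pmax(se, 1e-12 * max(abs(b), 1))
      w <- if (weighting == "inv_se") 1 / se_w else 1 / se_w^2
      beta <- sum(w * b) / sum(w)
      se_p <- sqrt(sum(w^2 * se^2)) / sum(w)
      z <- beta / se_p
      p <- if (one_sided) stats::pnorm(-z) else 2 * stats::pnorm(-abs(z))
      out[[length(out) + 1]] <- data.frame(
        roi = roi, regressor = reg, chroma = tag, beta = beta, se = se_p,
        p = min(max(p, .Machine$double.xmin), 1), n_channels = sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Deconvolved response curve from a FIR fit
#'
#' ROI-pooled FIR betas indexed by delay: the estimated response shape
#' over 0 to `fir_n - 1` seconds for each condition and chromophore.
#'
#' @param fit an `fnirs_glm` fitted with the FIR basis.
#' @param roi ROI name.
#' @inheritParams pool_roi
#' @return data.frame: `condition`, `chroma`, `delay` (s), `value` (uM),
#'   `se`.
#' @export
fir_waveform <- function(fit, roi, weighting = "inv_se") {
  if (!identical(fit$design$basis, "fir"))
    stop("fir_waveform requires a FIR-basis fit")
  pooled <- pool_roi(fit, roi, regressors = fit$design$condition_cols,
                     weighting = weighting)
  mm <- regmatches(pooled$regressor,
                   regexec("^(.*)_delay([0-9]+)$", pooled$regressor))
  pooled$condition <- vapply(mm, `[`, "", 2)
  pooled$delay <- as.numeric(vapply(mm, `[`, "", 3))
  out <- pooled[order(pooled$condition, pooled$chroma, pooled$delay),
                c("condition", "chroma", "delay", "beta", "se")]
  names(out)[4] <- "value"
  rownames(out) <- NULL
  out
}
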