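# Epoch-averaging analysis: cut epochs around stimulus onsets, linear
# detrend, peak-to-peak rejection, per-condition averaging, ROI
# waveforms, fixed-window amplitude extraction and bootstrap group bands.

#' Cut a recording into stimulus-locked epochs
#'
#' One epoch per event, spanning `window` seconds around onset (default
#' -3 to +14 s, wide enough that the response returns to baseline before
#' the earliest possible next stimulus). A least-squares line is removed
#' from each channel of each epoch when `detrend` is `TRUE`. Epochs
#' running past either end of the recording are dropped and logged.
#' Epochs are not excluded for sharing samples with a following stimulus;
#' the window is chosen so they do not.
#'
#' @param rec an `fnirs_recording` with `unit = "molar"`.
#' @param window epoch window in s relative to onset.
#' @param detrend remove a per-channel linear trend from each epoch
#'   (default `TRUE`).
#' @param baseline optional interval in s (e.g. `c(-3, 0)`) whose mean is
#'   subtracted per channel and epoch. Off by default: the pipeline
#'   relies on the detrend alone, but concentration changes have an
#'   arbitrary baseline, so absolute epoch levels are only meaningful
#'   after this correction.
#' @return list of class `fnirs_epochs`: `data` (epochs x rows x samples
#'   array, uM), `times`, `condition`, `rows`, `montage`, `sfreq`, `log`.
#' @export
epoch_recording <- function(rec, window = c(-3, 14), detrend = TRUE,
                            baseline = NULL) {
  if (rec$unit != "molar")
    stop("epoch_recording expects molar data, got ", rec$unit)
  stopifnot(window[1] < 0, window[2] > 0)
  ev <- rec$events
  if (!nrow(ev)) {
    warning("recording has no events; returning empty epochs")
    return(structure(list(
      data = array(0, c(0, nrow(rec$data), 0)), times = numeric(0),
      condition = character(0), rows = rec$rows, montage = rec$montage,
      sfreq = rec$sfreq, log = character(0)), class = "fnirs_epochs"))
  }
  rel <- seq(ceiling(window[1] * rec$sfreq), floor(window[2] * rec$sfreq))
  times <- rel / rec$sfreq
  n <- ncol(rec$data)
  log <- character(0)
  keep <- logical(nrow(ev))
  idx0 <- round(ev$onset * rec$sfreq) + 1
  for (i in seq_len(nrow(ev))) {
    keep[i] <- idx0[i] + rel[1] >= 1 && idx0[i] + rel[length(rel)] <= n
    if (!keep[i])
      log <- c(log, sprintf(
        "dropped epoch %d (%s at %.1f s): window outside recording",
        i, ev$condition[i], ev$onset[i]))
  }
  ev <- ev[keep, , drop = FALSE]
  idx0 <- idx0[keep]
  dat <- array(0, c(nrow(ev), nrow(rec$data), length(rel)))
  for (i in seq_len(nrow(ev))) {
    seg <- rec$data[, idx0[i] + rel, drop = FALSE]
    if (detrend) {
      tt <- cbind(1, times)
      seg <- seg - t(tt %*% qr.coef(qr(tt), t(seg)))
    }
    if (!is.null(baseline)) {
      bsel <- times >= baseline[1] & times <= baseline[2]
      if (!any(bsel)) stop("baseline interval contains no samples")
      seg <- seg - rowMeans(seg[, bsel, drop = FALSE])
    }
    dat[i, , ] <- seg
  }
  structure(list(data = dat, times = times, condition = ev$condition,
                 rows = rec$rows, montage = rec$montage, sfreq = rec$sfreq,
                 log = log),
            class = "fnirs_epochs")
}

#' @export
print.fnirs_epochs <- function(x, ...) {
  cat("<fnirs_epochs> ", dim(x$data)[1], " epochs x ", dim(x$data)[2],
      " rows x ", dim(x$data)[3], " samples, window [",
      round(min(x$times), 2), ", ", round(max(x$times), 2), "] s\n",
      sep = "")
  print(table(x$condition))
  invisible(x)
}

#' Reject epochs on a peak-to-peak criterion
#'
#' Drops every epoch whose peak-to-peak excursion exceeds `pp_limit` in
#' any channel (100 uM by default). Each rejection is logged with the
#' offending channel and value.
#'
#' @param ep an `fnirs_epochs` object.
#' @param pp_limit peak-to-peak limit in uM.
#' @return the `fnirs_epochs` with offending epochs removed.
#' @export
reject_epochs <- function(ep, pp_limit = 100) {
  ne <- dim(ep$data)[1]
  if (!ne) return(ep)
  keep <- logical(ne)
  for (i in seq_len(ne)) {
    pp <- apply(ep$data[i, , , drop = FALSE], 2, function(x)
      max(x) - min(x))
    keep[i] <- max(pp) <= pp_limit
    if (!keep[i])
      ep$log <- c(ep$log, sprintf(
        "rejected epoch %d (%s): peak-to-peak %.1f uM in row %d",
        i, ep$condition[i], max(pp), which.max(pp)))
  }
  ep$data <- ep$data[keep, , , drop = FALSE]
  ep$condition <- ep$condition[keep]
  ep
}

#' Average epochs per condition
#'
#' Sample-wise mean across retained epochs of each condition, for every
#' channel and chromophore. Conditions with zero retained epochs are
#' flagged missing with a warning.
#'
#' @param ep an `fnirs_epochs` object.
#' @param conditions conditions to average (default: all present).
#' @return list of class `fnirs_evoked`: `waveforms` (named list,
#'   condition -> rows x samples matrix in uM), `n_epochs`, `times`,
#'   `rows`, `montage`.
#' @export
average_epochs <- function(ep, conditions = unique(ep$condition)) {
  wf <- list()
  n_ep <- integer(0)
  for (cond in conditions) {
    sel <- which(ep$condition == cond)
    if (!length(sel)) {
      warning("no retained epochs for condition ", cond)
      next
    }
    m <- ep$data[sel[1], , , drop = TRUE]
    if (length(sel) > 1) {
      m <- apply(ep$data[sel, , , drop = FALSE], c(2, 3), mean)
    }
    wf[[cond]] <- m
    n_ep[cond] <- length(sel)
  }
  structure(list(waveforms = wf, n_epochs = n_ep, times = ep$times,
                 rows = ep$rows, montage = ep$montage),
            class = "fnirs_evoked")
}

#' ROI waveforms from an evoked average
#'
#' Unweighted mean across the retained channels of each ROI, per
#' condition and chromophore.
#'
#' @param avg an `fnirs_evoked` from [average_epochs()].
#' @param rois ROI names (default all in the montage).
#' @return tidy data.frame: `roi`, `condition`, `chroma`, `time`, `value`.
#' @export
roi_waveforms <- function(avg, rois = names(avg$montage$roi_map)) {
  out <- list()
  for (roi in rois) {
    chans <- roi_channels(avg$montage, roi)
    for (cond in names(avg$waveforms)) {
      for (tag in unique(avg$rows$chroma)) {
        ix <- which(avg$rows$channel %in% chans & avg$rows$chroma == tag)
        if (!length(ix)) next
        v <- colMeans(avg$waveforms[[cond]][ix, , drop = FALSE])
        out[[length(out) + 1]] <- data.frame(
          roi = roi, condition = cond, chroma = tag, time = avg$times,
          value = v, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Mean amplitude in a fixed post-onset window
#'
#' Time-mean of the ROI waveform over `window` seconds after onset
#' (default 5-7 s, where block responses to short sentences peak). Since
#' ROI and time means are unweighted, taking the window mean per channel
#' first and then averaging gives the same value.
#'
#' @param avg an `fnirs_evoked`.
#' @param roi ROI name.
#' @param window window in s (default `c(5, 7)`).
#' @return data.frame: `roi`, `condition`, `chroma`, `value` (uM).
#' @export
roi_amplitude <- function(avg, roi, window = c(5, 7)) {
  if (window[1] < min(avg$times) || window[2] > max(avg$times))
    stop("amplitude window [", window[1], ", ", window[2],
         "] s outside epoch window")
  wf <- roi_waveforms(avg, roi)
  sel <- wf$time >= window[1] & wf$time <= window[2]
  out <- stats::aggregate(value ~ roi + condition + chroma,
                          data = wf[sel, ], FUN = mean)
  out[order(out$condition, out$chroma), ]
}

#' Bootstrap group-level confidence band
#'
#' Sample-wise mean waveform across subjects with a percentile bootstrap
#' band (subjects resampled with replacement).
#'
#' @param waveforms subjects x samples matrix (one row per subject).
#' @param n_boot bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list of class `roi_waveform_band`: `mean`, `lower`, `upper`
#'   (numeric vectors), `n_subjects`, `n_boot`.
#' @export
group_band <- function(waveforms, n_boot = 1000, level = 0.95,
                       seed = NULL) {
  waveforms <- as.matrix(waveforms)
  ns <- nrow(waveforms)
  if (ns < 2) stop("group band needs at least 2 subjects")
  if (!is.null(seed)) set.seed(seed)
  mu <- colMeans(waveforms)
  boots <- matrix(0, n_boot, ncol(waveforms))
  for (b in seq_len(n_boot))
    boots[b, ] <- colMeans(waveforms[sample(ns, ns, replace = TRUE), ,
                                     drop = FALSE])
  a <- (1 - level) / 2
  lower <- apply(boots, 2, stats::quantile, probs = a)
  upper <- apply(boots, 2, stats::quantile, probs = 1 - a)
  structure(list(mean = mu, lower = pmin(lower, mu), upper = pmax(upper, mu),
                 n_subjects = ns, n_boot = n_boot),
            class = "roi_waveform_band")
}
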