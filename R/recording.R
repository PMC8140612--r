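# The Recording container: a channels x samples matrix plus montage,
# events, sample rate and per-row chromophore/wavelength tags. Every
# analysis stage consumes and returns one of these, and the `unit` tag
# (raw_intensity -> optical_density -> molar) makes mis-ordered pipelines
# fail loudly.

#' Construct an fNIRS recording
#'
#' @param data numeric matrix, rows = channel x (wavelength or
#'   chromophore), columns = samples.
#' @param unit one of `"raw_intensity"`, `"optical_density"`, `"molar"`.
#'   Molar data are concentration changes in micromolar.
#' @param sfreq sample rate in Hz.
#' @param montage an [fnirs_montage()].
#' @param events data.frame with columns `onset`, `duration` (s) and
#'   `condition`; may have zero rows.
#' @param rows data.frame describing each data row, with columns `channel`
#'   (index into `montage$channels`) and `chroma` (wavelength in nm as a
#'   character string, or `"hbo"` / `"hbr"`). If `NULL`, the canonical
#'   layout is generated: two consecutive rows per channel, one per
#'   wavelength (intensity/OD) or per chromophore (molar).
#' @return An object of class `fnirs_recording`.
#' @export
fnirs_recording <- function(data, unit, sfreq, montage,
                            events = empty_events(), rows = NULL) {
  unit <- match.arg(unit, c("raw_intensity", "optical_density", "molar"))
  data <- as.matrix(data)
  dimnames(data) <- NULL
  stopifnot(is.numeric(data), sfreq > 0, inherits(montage, "fnirs_montage"))
  if (is.null(rows)) {
    nch <- nrow(montage$channels)
    tags <- if (unit == "molar") c("hbo", "hbr")
            else as.character(montage$wavelengths)
    rows <- data.frame(channel = rep(seq_len(nch), each = 2),
                       chroma = rep(tags, nch), stringsAsFactors = FALSE)
  }
  if (nrow(data) != nrow(rows))
    stop("data has ", nrow(data), " rows but row metadata describes ",
         nrow(rows))
  if (unit == "raw_intensity" && any(data <= 0))
    stop("raw intensity must be strictly positive (channel ",
         rows$channel[which(data <= 0, arr.ind = TRUE)[1, 1]], ")")
  events <- as_events(events)
  dur <- ncol(data) / sfreq
  if (nrow(events) && any(events$onset >= dur))
    stop("event onset beyond end of recording")
  structure(list(data = data, unit = unit, sfreq = sfreq,
                 montage = montage, events = events, rows = rows),
            class = "fnirs_recording")
}

empty_events <- function() {
  data.frame(onset = numeric(0), duration = numeric(0),
             condition = character(0), stringsAsFactors = FALSE)
}

as_events <- function(events) {
  stopifnot(all(c("onset", "duration", "condition") %in% names(events)))
  ev <- data.frame(onset = as.numeric(events$onset),
                   duration = as.numeric(events$duration),
                   condition = as.character(events$condition),
                   stringsAsFactors = FALSE)
  if (nrow(ev)) {
    if (any(diff(ev$onset) <= 0)) stop("event onsets must strictly increase")
    if (any(ev$duration <= 0)) stop("event durations must be positive")
  }
  ev
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat("<fnirs_recording> ", nrow(x$data), " rows x ", ncol(x$data),
      " samples (", round(ncol(x$data) / x$sfreq, 1), " s @ ", x$sfreq,
      " Hz), unit = ", x$unit, "\n", sep = "")
  cat(nrow(x$events), "events,",
      length(unique(x$events$condition)), "conditions\n")
  invisible(x)
}

#' Time axis of a recording
#' @param rec an `fnirs_recording`.
#' @return numeric vector of sample times in seconds (first sample at 0).
#' @export
rec_times <- function(rec) (seq_len(ncol(rec$data)) - 1) / rec$sfreq

# Row indices for given channels (all chroma) or for one chroma tag.
rows_for <- function(rec, channels, chroma = NULL) {
  sel <- rec$rows$channel %in% channels
  if (!is.null(chroma)) sel <- sel & rec$rows$chroma %in% chroma
  which(sel)
}

#' Subset a recording to a set of channels
#'
#' Drops all data rows of channels not in `keep` and rebuilds the montage
#' channel list and ROI map with remapped indices.
#'
#' @param rec an `fnirs_recording`.
#' @param keep integer channel indices to retain.
#' @return The subset `fnirs_recording`.
#' @export
subset_channels <- function(rec, keep) {
  keep <- sort(unique(as.integer(keep)))
  if (!length(keep)) stop("subset would drop every channel")
  m <- rec$montage
  new_idx <- match(seq_len(nrow(m$channels)), keep)   # old -> new or NA
  m$channels <- m$channels[keep, , drop = FALSE]
  rownames(m$channels) <- NULL
  m$roi_map <- lapply(m$roi_map, function(ix) {
    v <- new_idx[ix]
    as.integer(v[!is.na(v)])
  })
  sel <- rec$rows$channel %in% keep
  rows <- rec$rows[sel, , drop = FALSE]
  rows$channel <- new_idx[rows$channel]
  rownames(rows) <- NULL
  rec$data <- rec$data[sel, , drop = FALSE]
  rec$rows <- rows
  rec$montage <- m
  rec
}

# ---------------------------------------------------------------------------
# Plain-text I/O: a wide CSV with one column per channel-wavelength named
# S{src}_D{det}_{wl}nm plus a leading time_s column; events in a sidecar
# TSV (onset_s, duration_s, condition); montage geometry in a second
# sidecar CSV. Human-inspectable and round-trip exact to storage precision.

#' Write a raw-intensity recording to a CSV fixture
#'
#' Writes `path` (wide data table), `<path>_events.tsv` (onset_s,
#' duration_s, condition) and `<path>_montage.csv` (optode roles, labels
#' and positions).
#'
#' @param rec an `fnirs_recording` with `unit = "raw_intensity"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  if (rec$unit != "raw_intensity")
    stop("CSV fixtures store raw intensity; got unit ", rec$unit)
  if (ncol(rec$data) == 0) stop("refusing to write zero-length recording")
  m <- rec$montage
  cn <- sprintf("S%d_D%d_%snm",
                match(m$channels$source[rec$rows$channel], m$sources$label),
                match(m$channels$detector[rec$rows$channel], m$detectors$label),
                rec$rows$chroma)
  tab <- data.frame(time_s = rec_times(rec), t(rec$data))
  names(tab) <- c("time_s", cn)
  utils::write.csv(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  ev <- rec$events
  names(ev) <- c("onset_s", "duration_s", "condition")
  utils::write.table(ev, sidecar_path(path, "_events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  opt <- rbind(
    data.frame(role = "source", label = m$sources$label,
               x = m$sources$x, y = m$sources$y, z = m$sources$z),
    data.frame(role = "detector", label = m$detectors$label,
               x = m$detectors$x, y = m$detectors$y, z = m$detectors$z))
  utils::write.csv(format(opt, digits = 15, trim = TRUE),
                   sidecar_path(path, "_montage.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

sidecar_path <- function(path, suffix) {
  sub("\\.csv$", suffix, path)
}

#' Read a recording from a CSV fixture
#'
#' Counterpart of [write_recording_csv()]. A missing events sidecar yields
#' an empty event table with a warning. Channel pairing, wavelengths and
#' short/long classification are reconstructed from the column names and
#' the montage sidecar; ROI membership is re-derived for the bundled
#' auditory montage when the optode labels match it.
#'
#' @param path CSV path written by [write_recording_csv()].
#' @param montage optional `fnirs_montage` to attach instead of the one
#'   reconstructed from the sidecar (used to restore ROI maps).
#' @return An `fnirs_recording` with `unit = "raw_intensity"`.
#' @export
read_recording_csv <- function(path, montage = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(tab)[1], "time_s"))
    stop("malformed fixture: first column must be time_s")
  cn <- names(tab)[-1]
  mm <- regmatches(cn, regexec("^S([0-9]+)_D([0-9]+)_([0-9.]+)nm$", cn))
  if (any(lengths(mm) != 4))
    stop("malformed fixture: bad channel column name")
  si <- as.integer(vapply(mm, `[`, "", 2))
  di <- as.integer(vapply(mm, `[`, "", 3))
  wl <- vapply(mm, `[`, "", 4)
  dt <- diff(tab$time_s)
  sfreq <- 1 / stats::median(dt)

  pair_id <- paste(si, di)
  uniq <- !duplicated(pair_id)
  chan_of <- match(pair_id, pair_id[uniq])
  if (is.null(montage)) {
    mpath <- sidecar_path(path, "_montage.csv")
    if (!file.exists(mpath)) stop("montage sidecar missing: ", mpath)
    opt <- utils::read.csv(mpath, stringsAsFactors = FALSE)
    sources <- opt[opt$role == "source", c("label", "x", "y", "z")]
    detectors <- opt[opt$role == "detector", c("label", "x", "y", "z")]
    rownames(sources) <- rownames(detectors) <- NULL
    chans <- data.frame(source = sources$label[si[uniq]],
                        detector = detectors$label[di[uniq]],
                        stringsAsFactors = FALSE)
    montage <- fnirs_montage(sources, detectors, chans,
                             wavelengths = sort(unique(as.numeric(wl))))
    ref <- tryCatch(build_paper_montage(), error = function(e) NULL)
    if (!is.null(ref) &&
        identical(paste(chans$source, chans$detector),
                  paste(ref$channels$source, ref$channels$detector)))
      montage$roi_map <- ref$roi_map
  }
  rows <- data.frame(channel = chan_of, chroma = wl,
                     stringsAsFactors = FALSE)

  epath <- sidecar_path(path, "_events.tsv")
  if (file.exists(epath)) {
    ev <- utils::read.table(epath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    names(ev) <- c("onset", "duration", "condition")
  } else {
    warning("no events sidecar found; recording has an empty event table")
    ev <- empty_events()
  }
  fnirs_recording(t(as.matrix(tab[, -1, drop = FALSE])), "raw_intensity",
                  sfreq, montage, events = ev, rows = rows)
}
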