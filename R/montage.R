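# Optode geometry and channel bookkeeping.
#
# Positions are stored in metres in a right-handed RAS-like head frame
# (x: left -> right, y: posterior -> anterior, z: inferior -> superior).
# Channels are indexed from 1 internally; all times are seconds.

# Scalp coordinates (m) for the 10-05 electrode labels used by the auditory
# montage, taken from a standard 10-05 position table for a nominal adult
# head (~9 cm radius).
.pos_1005 <- local({
  p <- rbind(
    AF7 = c(-0.054840,  0.068572, -0.010590),
    F3  = c(-0.050244,  0.053111,  0.042192),
    F7  = c(-0.070263,  0.042474, -0.011420),
    FC5 = c(-0.077215,  0.018643,  0.024460),
    T7  = c(-0.084161, -0.016019, -0.009346),
    CP5 = c(-0.079592, -0.046551,  0.030949),
    O1  = c(-0.029413, -0.112449,  0.008839),
    POz = c( 0.000216, -0.102178,  0.050608),
    O2  = c( 0.029843, -0.112156,  0.008800),
    Iz  = c( 0.000004, -0.118565, -0.023078),
    CP6 = c( 0.083322, -0.046101,  0.031206),
    T8  = c( 0.085080, -0.015020, -0.009490),
    F5  = c(-0.064466,  0.048035,  0.016921),
    C5  = c(-0.080280, -0.013760,  0.029160),
    TP7 = c(-0.084830, -0.046022, -0.007056),
    CP3 = c(-0.063556, -0.047009,  0.065624),
    P5  = c(-0.067272, -0.076291,  0.028382),
    PO3 = c(-0.036511, -0.100853,  0.037167),
    PO4 = c( 0.036782, -0.100849,  0.036397),
    Oz  = c( 0.000108, -0.114892,  0.014657),
    P6  = c( 0.067888, -0.075904,  0.028091),
    CP4 = c( 0.066612, -0.046637,  0.065580),
    TP8 = c( 0.085549, -0.045545, -0.007130),
    C6  = c( 0.083456, -0.012776,  0.029208))
  colnames(p) <- c("x", "y", "z")
  p
})

#' Construct an fNIRS montage
#'
#' A montage holds optode positions, the source-detector pairing of every
#' channel, the nominal wavelengths, and named region-of-interest (ROI)
#' channel groups. Positions are in metres.
#'
#' @param sources data.frame with columns `label`, `x`, `y`, `z`.
#' @param detectors data.frame with columns `label`, `x`, `y`, `z`.
#' @param channels data.frame with columns `source`, `detector` (labels).
#' @param wavelengths numeric(2), nominal wavelengths in nm.
#' @param roi_map named list of integer channel indices.
#' @return An object of class `fnirs_montage`.
#' @export
fnirs_montage <- function(sources, detectors, channels,
                          wavelengths = c(760, 850), roi_map = list()) {
  stopifnot(is.data.frame(sources), is.data.frame(detectors),
            all(c("label", "x", "y", "z") %in% names(sources)),
            all(c("label", "x", "y", "z") %in% names(detectors)),
            all(c("source", "detector") %in% names(channels)),
            length(wavelengths) == 2, all(wavelengths > 0))
  if (!all(channels$source %in% sources$label))
    stop("channel references unknown source optode")
  if (!all(channels$detector %in% detectors$label))
    stop("channel references unknown detector optode")
  bad <- unlist(roi_map)
  if (length(bad) && (any(bad < 1) || any(bad > nrow(channels))))
    stop("roi_map lists an invalid channel index")
  m <- structure(list(
    sources = sources, detectors = detectors,
    channels = data.frame(source = as.character(channels$source),
                          detector = as.character(channels$detector),
                          stringsAsFactors = FALSE),
    wavelengths = as.numeric(wavelengths),
    roi_map = lapply(roi_map, as.integer)),
    class = "fnirs_montage")
  if (any(sd_distance(m) <= 0))
    stop("source-detector distance must be strictly positive")
  m
}

#' Source-detector separation
#'
#' Euclidean distance (m) between the source and detector optode of each
#' channel.
#'
#' @param montage an `fnirs_montage`.
#' @param channel optional integer channel index (or vector); default all.
#' @return numeric vector of distances in metres.
#' @export
sd_distance <- function(montage, channel = NULL) {
  ch <- montage$channels
  if (is.null(channel)) channel <- seq_len(nrow(ch))
  if (any(channel < 1 | channel > nrow(ch)))
    stop("unknown channel index")
  si <- match(ch$source[channel], montage$sources$label)
  di <- match(ch$detector[channel], montage$detectors$label)
  sp <- as.matrix(montage$sources[si, c("x", "y", "z")])
  dp <- as.matrix(montage$detectors[di, c("x", "y", "z")])
  unname(sqrt(rowSums((sp - dp)^2)))
}

#' Channel midpoints
#'
#' Midpoint between source and detector of each channel; used to define
#' "nearest short channel" for systemic regression.
#'
#' @inheritParams sd_distance
#' @return matrix n_channels x 3 (m).
#' @export
channel_midpoints <- function(montage) {
  si <- match(montage$channels$source, montage$sources$label)
  di <- match(montage$channels$detector, montage$detectors$label)
  sp <- as.matrix(montage$sources[si, c("x", "y", "z")])
  dp <- as.matrix(montage$detectors[di, c("x", "y", "z")])
  (sp + dp) / 2
}

#' Classify channels as short or long
#'
#' A channel is "short" when its source-detector separation is below
#' `short_max` (1 cm by convention): such channels sample only superficial,
#' systemic physiology and serve as nuisance references.
#'
#' @inheritParams sd_distance
#' @param short_max separation threshold in m (default 0.01).
#' @return character vector, `"short"` or `"long"` per channel.
#' @export
channel_kinds <- function(montage, short_max = 0.01) {
  ifelse(sd_distance(montage) < short_max, "short", "long")
}

#' Channel display labels ("S-D" pairs)
#' @inheritParams sd_distance
#' @return character vector.
#' @export
channel_labels <- function(montage) {
  paste(montage$channels$source, montage$channels$detector, sep = "-")
}

#' Build the auditory block-design montage
#'
#' Constructs the 12-source / 12-detector montage with eight co-located
#' short-channel detectors used for passive auditory block experiments:
#' 24 long channels grouped into four ROIs (left inferior frontal gyrus,
#' left and right superior temporal gyrus, occipital lobe) plus 8 short
#' channels. Optode positions come from a bundled standard 10-05
#' coordinate table; `scale` applies a global head-size factor.
#'
#' Short-channel detectors sit 8 mm from their host source along the scalp
#' tangent, giving every short channel a separation below the 1 cm
#' threshold.
#'
#' @param scale global scale factor on all optode positions (default 1.0,
#'   a nominal adult head for which all long channels fall in 20-40 mm).
#' @return An `fnirs_montage` with 32 channels (24 long + 8 short) and a
#'   `roi_map` with entries `left_IFG`, `left_STG`, `right_STG`,
#'   `occipital`.
#' @export
build_paper_montage <- function(scale = 1.0) {
  stopifnot(is.numeric(scale), scale > 0)
  pos <- .pos_1005 * scale
  src_labels <- c("AF7", "F3", "F7", "FC5", "T7", "CP5",
                  "O1", "POz", "O2", "Iz", "CP6", "T8")
  det_labels <- c("F5", "C5", "TP7", "CP3", "P5", "PO3",
                  "PO4", "Oz", "P6", "CP4", "TP8", "C6")
  short_hosts <- c("AF7", "F7", "T7", "CP5", "O1", "O2", "CP6", "T8")

  sources <- data.frame(label = src_labels,
                        pos[src_labels, , drop = FALSE],
                        row.names = NULL, stringsAsFactors = FALSE)

  # short detectors: 8 mm from the host source, tangent to the scalp
  short_pos <- t(vapply(short_hosts, function(lab) {
    p <- pos[lab, ]
    radial <- p / sqrt(sum(p^2))
    tang <- c(-radial[2], radial[1], 0)        # horizontal tangent
    if (sqrt(sum(tang^2)) < 1e-6) tang <- c(1, 0, 0)
    tang <- tang / sqrt(sum(tang^2))
    p + 0.008 * tang
  }, numeric(3)))
  detectors <- rbind(
    data.frame(label = det_labels, pos[det_labels, , drop = FALSE],
               row.names = NULL, stringsAsFactors = FALSE),
    data.frame(label = paste0("Sh", short_hosts),
               x = short_pos[, 1], y = short_pos[, 2], z = short_pos[, 3],
               stringsAsFactors = FALSE))

  pair <- function(s, d) data.frame(source = s, detector = d,
                                    stringsAsFactors = FALSE)
  long_channels <- rbind(
    # left inferior frontal gyrus
    pair("AF7", "F5"), pair("F3", "F5"), pair("F7", "F5"), pair("FC5", "F5"),
    # left superior temporal gyrus
    pair("T7", "C5"), pair("T7", "TP7"), pair("CP5", "C5"),
    pair("CP5", "TP7"), pair("CP5", "CP3"), pair("CP5", "P5"),
    # right superior temporal gyrus
    pair("CP6", "P6"), pair("CP6", "TP8"), pair("CP6", "CP4"),
    pair("CP6", "C6"), pair("T8", "TP8"), pair("T8", "C6"),
    # occipital lobe
    pair("O1", "PO3"), pair("O1", "Oz"), pair("POz", "PO3"),
    pair("POz", "Oz"), pair("POz", "PO4"), pair("Iz", "Oz"),
    pair("O2", "Oz"), pair("O2", "PO4"))
  short_channels <- pair(short_hosts, paste0("Sh", short_hosts))
  channels <- rbind(long_channels, short_channels)

  roi_map <- list(
    left_IFG  = 1:4,
    left_STG  = 5:10,
    right_STG = 11:16,
    occipital = 17:24)

  fnirs_montage(sources, detectors, channels,
                wavelengths = c(760, 850), roi_map = roi_map)
}

#' @export
print.fnirs_montage <- function(x, ...) {
  kinds <- channel_kinds(x)
  cat("<fnirs_montage> ", nrow(x$channels), " channels (",
      sum(kinds == "long"), " long, ", sum(kinds == "short"), " short), ",
      nrow(x$sources), " sources, ", nrow(x$detectors), " detectors\n",
      sep = "")
  cat("wavelengths:", paste(x$wavelengths, collapse = "/"), "nm\n")
  if (length(x$roi_map))
    cat("ROIs:", paste(sprintf("%s[%d]", names(x$roi_map),
                               lengths(x$roi_map)), collapse = ", "), "\n")
  invisible(x)
}

# ROI channel indices, restricted to channels present in `keep` if given.
roi_channels <- function(montage, roi) {
  if (!roi %in% names(montage$roi_map))
    stop("unknown ROI: ", roi)
  montage$roi_map[[roi]]
}
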