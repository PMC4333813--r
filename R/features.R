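# Event features. Each marker gets: amp (ridge amplitude), sigma (spectral
# sigma index), freq (normalized ridge frequency), med (normalized
# anterior-posterior position of the dominant PCA channel), stage (hypnogram
# code at the marker) and expert (co-occurrence with an expert annotation on
# Fz, Cz or Pz).

#' Ridge amplitude feature
#'
#' The ridge value `d(t_max)` at each marker.
#'
#' @param rt A `"ridge_trace"`.
#' @param markers Integer marker indices.
#' @return Numeric vector of amplitudes.
#' @export
amp_feature <- function(rt, markers) {
  stopifnot(inherits(rt, "ridge_trace"))
  markers <- as.integer(markers)
  if (any(markers < 1L | markers > length(rt$d)))
    stop("marker index out of range")
  rt$d[markers]
}

.sigma_bands <- list(low = c(4, 10), sigma = c(10.5, 16), high = c(20, 40))

band_rows <- function(frequencies, band, tol = 1e-9) {
  which(frequencies >= band[1] - tol & frequencies <= band[2] + tol)
}

#' Sigma index
#'
#' Ratio of narrow-band spindle activity to its spectral surround at the
#' marker's instant: `2 * max|W|(10.5-16 Hz) / (mean|W|(4-10 Hz) +
#' mean|W|(20-40 Hz))`, band edges inclusive. Values grow with narrow-band
#' activity peaking in the sigma band and are invariant to global signal
#' scaling.
#'
#' @param tf Either a `"tf_map"` over (at least) 4-40 Hz, or a modulus matrix
#'   from [marker_spectra()] (frequencies x events, with the grid attached as
#'   attribute `"frequencies"`).
#' @param markers Marker sample indices (columns of the map). Ignored when
#'   `tf` is already a per-marker spectra matrix.
#' @param bands List with elements `low`, `sigma`, `high`: band edges in Hz.
#' @return Numeric vector of sigma indices, one per marker.
#' @export
sigma_index <- function(tf, markers = NULL, bands = .sigma_bands) {
  if (inherits(tf, "tf_map")) {
    if (is.null(markers)) stop("markers required with a tf_map input")
    markers <- as.integer(markers)
    if (any(markers < 1L | markers > ncol(tf$coefficients)))
      stop("marker index out of range")
    spectra <- Mod(tf$coefficients[, markers, drop = FALSE])
    freqs <- tf$frequencies
  } else {
    spectra <- as.matrix(tf)
    freqs <- attr(tf, "frequencies")
    if (is.null(freqs)) stop("spectra matrix must carry a 'frequencies' attribute")
  }
  rows <- lapply(bands, band_rows, frequencies = freqs)
  if (any(lengths(rows) == 0L))
    stop("frequency grid does not cover the sigma-index bands (4-10, 10.5-16, 20-40 Hz)")
  a_sig <- apply(spectra[rows$sigma, , drop = FALSE], 2L, max)
  a_low <- colMeans(spectra[rows$low, , drop = FALSE])
  a_high <- colMeans(spectra[rows$high, , drop = FALSE])
  den <- a_low + a_high
  if (any(den <= 0))
    stop("undefined sigma index: zero spectrum at marker(s) ",
         paste(which(den <= 0), collapse = ", "))
  2 * a_sig / den
}

#' Normalized frequency feature
#'
#' The grid frequency maximizing the wavelet modulus at the marker column
#' (ties toward the lower frequency), mapped linearly to \[0, 1\] over the
#' ridge band: `freq = (f_max - f_1) / (f_Nf - f_1)`.
#'
#' @param rt A `"ridge_trace"` over the spindle band.
#' @param markers Integer marker indices.
#' @return Data frame with columns `freq` (in \[0, 1\]) and `f_max` (Hz).
#' @export
freq_feature <- function(rt, markers) {
  stopifnot(inherits(rt, "ridge_trace"))
  markers <- as.integer(markers)
  if (any(markers < 1L | markers > length(rt$d)))
    stop("marker index out of range")
  f1 <- rt$frequencies[1L]
  fN <- rt$frequencies[length(rt$frequencies)]
  f_max <- rt$frequencies[rt$argfreq[markers]]
  data.frame(freq = (f_max - f1) / (fN - f1), f_max = f_max)
}

#' Medial (anterior-posterior) position feature
#'
#' The leading eigenvector of the channel covariance of a short multichannel
#' window centered on the marker (channels mean-centered over the window; no
#' variance normalization) gives a topography; the channel with maximal
#' absolute weight represents the event's scalp location. The feature is that
#' channel's layout `y`-coordinate plus 0.5, clamped to \[0, 1\], so that
#' anterior events map high and posterior events low.
#'
#' @param recording An [eeg_recording()] (>= 2 channels).
#' @param markers Integer marker sample indices.
#' @param window Window length in seconds (default 0.5), truncated at record
#'   edges.
#' @return Data frame with columns `med` (in \[0, 1\]) and `channel` (the
#'   representative channel name).
#' @export
med_feature <- function(recording, markers, window = 0.5) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(recording$samples) < 2L)
    stop("med feature requires at least 2 channels")
  markers <- as.integer(markers)
  nt <- n_samples(recording)
  if (any(markers < 1L | markers > nt)) stop("marker index out of range")
  half <- max(1L, round(window / 2 * recording$fs))
  xy <- layout_xy(recording$layout, recording$channel_names)
  med <- numeric(length(markers))
  chan <- character(length(markers))
  for (k in seq_along(markers)) {
    lo <- max(1L, markers[k] - half)
    hi <- min(nt, markers[k] + half)
    if (hi - lo < 1L) stop("window covers fewer than 2 samples at marker ", markers[k])
    X <- recording$samples[, lo:hi, drop = FALSE]
    Xc <- X - rowMeans(X)
    C <- tcrossprod(Xc) / (ncol(Xc) - 1L)
    if (max(abs(C)) <= 0)
      stop("undefined med feature: constant window at marker ", markers[k])
    v <- eigen(C, symmetric = TRUE)$vectors[, 1L]
    i <- which.max(abs(v))
    chan[k] <- recording$channel_names[i]
    med[k] <- min(1, max(0, xy[i, "y"] + 0.5))
  }
  data.frame(med = med, channel = chan, stringsAsFactors = FALSE)
}

#' Sleep stage at marker times
#'
#' Stage code of the hypnogram epoch containing each time; epochs are
#' half-open `[k L, (k+1) L)`.
#'
#' @param hyp A [hypnogram()].
#' @param time_s Marker times in seconds.
#' @return Integer stage codes.
#' @export
stage_feature <- function(hyp, time_s) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (any(time_s < 0) || any(time_s >= hypnogram_span(hyp)))
    stop("marker time outside the hypnogram span")
  hyp$stages[floor(time_s / hyp$epoch_length) + 1L]
}

#' Expert co-occurrence flag
#'
#' 1 when the marker time lies within (closed interval) an expert annotation
#' window on one of the scoring channels, else 0.
#'
#' @param annotations An [annotation_set()].
#' @param time_s Marker times in seconds.
#' @param channels Scoring channels honored (default Fz, Cz, Pz).
#' @return Integer vector of 0/1 flags.
#' @export
expert_feature <- function(annotations, time_s, channels = c("Fz", "Cz", "Pz")) {
  out <- integer(length(time_s))
  if (is.null(annotations) || nrow(annotations) == 0L) return(out)
  ann <- annotations[annotations$channel %in% channels, , drop = FALSE]
  for (k in seq_len(nrow(ann))) {
    out[time_s >= ann$onset[k] & time_s <= ann$onset[k] + ann$duration[k]] <- 1L
  }
  out
}
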