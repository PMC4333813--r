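# Ridge extraction and event segmentation. The ridge d(t) is the per-sample
# maximum wavelet modulus over the spindle-band grid; its local maxima are the
# instantaneous event markers that segment the whole record.

new_ridge_trace <- function(d, argfreq, frequencies, fs, coi = 0L) {
  structure(list(d = d, argfreq = as.integer(argfreq),
                 frequencies = frequencies, fs = fs, coi = as.integer(coi)),
            class = "ridge_trace")
}

#' @export
print.ridge_trace <- function(x, ...) {
  cat(sprintf("ridge trace: %d samples at %g Hz over %.1f-%.1f Hz (coi %d samples)\n",
              length(x$d), x$fs, min(x$frequencies), max(x$frequencies), x$coi))
  invisible(x)
}

#' Wavelet ridge of a time-frequency map
#'
#' For every time sample, the maximum modulus over the frequency rows,
#' `d(t_j) = max_i |w_{i,j}|`, with ties resolved toward the lower frequency.
#'
#' @param tf A `"tf_map"` from [cwt()], restricted to the spindle band.
#' @return An object of class `"ridge_trace"`: list with `d` (ridge
#'   amplitude), `argfreq` (index of the maximizing frequency row),
#'   `frequencies`, `fs` and `coi`.
#' @export
ridge <- function(tf) {
  stopifnot(inherits(tf, "tf_map"))
  if (length(tf$frequencies) < 1L || ncol(tf$coefficients) < 1L)
    stop("empty time-frequency map")
  mx <- col_max_lowtie(Mod(tf$coefficients))
  new_ridge_trace(mx$max, mx$arg, tf$frequencies, tf$fs, tf$coi)
}

#' Event markers: local maxima of the ridge
#'
#' Interior samples where the forward difference of `d` changes sign from
#' positive to non-positive. A plateau of equal values counts as a single
#' maximum, placed at its first sample, provided the plateau is higher than
#' both neighbouring values. Boundary samples are never markers.
#'
#' @param rt A `"ridge_trace"` (or a plain numeric vector, for which a trace
#'   with unit sampling is assumed).
#' @param drop_coi Drop markers within the cone-of-influence margin at the two
#'   record edges (default TRUE).
#' @param artifact_mask Optional two-column matrix/data frame of (start_s,
#'   end_s) intervals; markers inside any interval (closed) are dropped.
#' @return Integer vector of strictly increasing marker sample indices.
#' @export
#' @examples
#' local_maxima(c(0, 1, 0))  # 2
local_maxima <- function(rt, drop_coi = TRUE, artifact_mask = NULL) {
  if (is.numeric(rt) && !inherits(rt, "ridge_trace"))
    rt <- new_ridge_trace(rt, rep.int(1L, length(rt)), 1, 1, 0L)
  stopifnot(inherits(rt, "ridge_trace"))
  d <- rt$d
  n <- length(d)
  if (n < 3L) stop("ridge must contain at least 3 samples")
  # run-length view: a run is a maximum iff it is interior and both
  # neighbouring runs are strictly lower; the marker is the run's first sample
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  idx <- integer(0)
  if (nr >= 3L) {
    im <- 2:(nr - 1L)
    is_max <- r$values[im] > r$values[im - 1L] & r$values[im] > r$values[im + 1L]
    idx <- starts[im][is_max]
  }
  if (drop_coi && rt$coi > 0L)
    idx <- idx[idx > rt$coi & idx <= n - rt$coi]
  if (!is.null(artifact_mask) && length(idx)) {
    m <- as.matrix(artifact_mask)
    if (ncol(m) < 2L) stop("artifact_mask needs (start_s, end_s) columns")
    t_s <- (idx - 1L) / rt$fs
    bad <- rep(FALSE, length(idx))
    for (k in seq_len(nrow(m)))
      bad <- bad | (t_s >= m[k, 1L] & t_s <= m[k, 2L])
    idx <- idx[!bad]
  }
  idx
}

#' Marker table
#'
#' Event markers with their time, ridge frequency and ridge amplitude, in the
#' exportable delimited layout.
#'
#' @param rt A `"ridge_trace"`.
#' @param markers Integer marker indices from [local_maxima()].
#' @return Data frame with columns `sample_index`, `time_s`, `frequency_hz`,
#'   `ridge_amplitude`.
#' @export
marker_table <- function(rt, markers) {
  stopifnot(inherits(rt, "ridge_trace"))
  markers <- as.integer(markers)
  if (any(markers < 1L | markers > length(rt$d))) stop("marker index out of range")
  data.frame(sample_index = markers,
             time_s = (markers - 1L) / rt$fs,
             frequency_hz = rt$frequencies[rt$argfreq[markers]],
             ridge_amplitude = rt$d[markers])
}
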