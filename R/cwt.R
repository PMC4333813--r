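# Continuous wavelet transform via frequency-domain multiplication.
#
# Each analysis frequency f_i is reached by the scale a_i = w_p / (2 pi f_i /
# fs), where w_p is the Morse peak angular frequency, so that the scaled
# window peaks exactly at f_i. The signal block is zero-padded to a fast FFT
# length; negative frequencies and the Nyquist bin are zeroed (analytic
# wavelet). Long signals are processed in overlapping blocks and each sample
# takes its coefficients from the block where it is most interior, bounding
# memory at one block's map.

cwt_check <- function(signal, fs, frequencies) {
  if (length(signal) < 2L) stop("signal must contain at least 2 samples")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (any(diff(frequencies) <= 0)) stop("frequencies must be strictly increasing")
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  if (any(frequencies >= fs / 2))
    stop("analysis frequencies must be below the Nyquist frequency fs/2")
}

# complex CWT of one signal segment; rows follow `frequencies`
cwt_kernel <- function(x, fs, frequencies, beta, gamma) {
  n <- length(x)
  nfft <- stats::nextn(max(n, 16L), c(2L, 3L, 5L))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  k <- seq_len(nfft) - 1L
  omega <- 2 * pi * k / nfft                 # rad per sample
  pos <- k >= 1L & k < nfft / 2              # strictly positive, sub-Nyquist
  wp <- morse_peak_omega(beta, gamma)
  W <- matrix(0 + 0i, nrow = length(frequencies), ncol = n)
  win <- numeric(nfft)
  for (i in seq_along(frequencies)) {
    a <- wp / (2 * pi * frequencies[i] / fs)
    win[] <- 0
    win[pos] <- morse_window(a * omega[pos], beta, gamma)
    row <- stats::fft(X * win, inverse = TRUE) / nfft
    W[i, ] <- row[seq_len(n)]
  }
  W
}

# overlapping block layout: each row gives the block extent [start, end] and
# the sample range [own_start, own_end] whose coefficients it contributes
block_plan <- function(n, fs, block_s, overlap_s) {
  block <- max(16L, round(block_s * fs))
  step <- block - max(1L, round(overlap_s * fs))
  if (n <= block || step <= 0)
    return(data.frame(start = 1L, end = n, own_start = 1L, own_end = n))
  starts <- seq.int(1L, n - block + 1L, by = step)
  if (starts[length(starts)] < n - block + 1L)
    starts <- c(starts, n - block + 1L)
  ends <- pmin(starts + block - 1L, n)
  nb <- length(starts)
  bounds <- integer(nb - 1L)
  for (j in seq_len(nb - 1L)) {
    ov_lo <- starts[j + 1L]
    ov_hi <- ends[j]
    bounds[j] <- ov_lo + (ov_hi - ov_lo + 1L) %/% 2L
  }
  own_start <- c(1L, bounds)
  own_end <- c(bounds - 1L, n)
  data.frame(start = starts, end = ends,
             own_start = own_start, own_end = own_end)
}

coi_margin_samples <- function(fs, frequencies, beta, gamma) {
  wp <- morse_peak_omega(beta, gamma)
  a_max <- wp / (2 * pi * min(frequencies) / fs)
  ceiling(2 * morse_efold_samples(a_max, beta, gamma))
}

#' Continuous wavelet transform (Morse wavelets)
#'
#' Complex wavelet coefficients of a univariate signal over a frequency grid.
#' Long signals are processed in overlapping blocks (coefficients taken from
#' the block where each sample is most interior), so the returned map is
#' seamless. The result carries a cone-of-influence margin (`coi`, in samples)
#' covering boundary effects at the two record edges: two envelope e-folding
#' times of the largest analysis scale.
#'
#' @param signal Numeric vector (microvolts), length >= 2.
#' @param fs Sampling rate (Hz).
#' @param frequencies Ascending analysis frequencies (Hz), all below `fs/2`.
#'   See [frequency_grid()].
#' @param beta,gamma Morse parameters (defaults 10 and 20).
#' @param block_s,overlap_s Block length and overlap in seconds for blockwise
#'   processing of long signals.
#' @return An object of class `"tf_map"`: list with `coefficients` (complex
#'   matrix, frequencies x time), `frequencies`, `fs`, `coi`.
#' @export
#' @examples
#' t <- seq(0, 4, by = 1 / 256)
#' tf <- cwt(sin(2 * pi * 13 * t), 256, frequency_grid(10, 16, 0.1))
#' dim(tf$coefficients)
cwt <- function(signal, fs, frequencies, beta = 10, gamma = 20,
                block_s = 60, overlap_s = 5) {
  cwt_check(signal, fs, frequencies)
  n <- length(signal)
  plan <- block_plan(n, fs, block_s, overlap_s)
  W <- matrix(0 + 0i, nrow = length(frequencies), ncol = n)
  for (j in seq_len(nrow(plan))) {
    seg <- signal[plan$start[j]:plan$end[j]]
    Wb <- cwt_kernel(seg, fs, frequencies, beta, gamma)
    own <- plan$own_start[j]:plan$own_end[j]
    W[, own] <- Wb[, own - plan$start[j] + 1L, drop = FALSE]
  }
  structure(list(coefficients = W, frequencies = frequencies, fs = fs,
                 coi = coi_margin_samples(fs, frequencies, beta, gamma)),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("time-frequency map: %d frequencies (%.1f-%.1f Hz) x %d samples at %g Hz; coi %d samples\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              ncol(x$coefficients), x$fs, x$coi))
  invisible(x)
}

#' Wavelet ridge of a signal without materializing the full map
#'
#' Computes, blockwise, the per-sample maximum wavelet modulus over the
#' frequency grid (the ridge `d(t)`) together with the index of the maximizing
#' frequency row (ties toward the lower frequency). Equivalent to
#' `ridge(cwt(...))` but with memory bounded by one block.
#'
#' @inheritParams cwt
#' @return An object of class `"ridge_trace"`; see [ridge()].
#' @export
cwt_ridge <- function(signal, fs, frequencies, beta = 10, gamma = 20,
                      block_s = 60, overlap_s = 5) {
  cwt_check(signal, fs, frequencies)
  n <- length(signal)
  plan <- block_plan(n, fs, block_s, overlap_s)
  d <- numeric(n)
  argfreq <- integer(n)
  for (j in seq_len(nrow(plan))) {
    seg <- signal[plan$start[j]:plan$end[j]]
    Wb <- cwt_kernel(seg, fs, frequencies, beta, gamma)
    own <- plan$own_start[j]:plan$own_end[j]
    mod <- Mod(Wb[, own - plan$start[j] + 1L, drop = FALSE])
    mx <- col_max_lowtie(mod)
    d[own] <- mx$max
    argfreq[own] <- mx$arg
  }
  new_ridge_trace(d, argfreq, frequencies, fs,
                  coi_margin_samples(fs, frequencies, beta, gamma))
}

#' Instantaneous wavelet spectra at selected samples
#'
#' Blockwise evaluation of the wavelet modulus `|W|` over a (typically wide,
#' 4-40 Hz) frequency grid, returned only at the requested sample indices.
#' Used for the sigma index, which needs the instantaneous spectrum at each
#' event marker.
#'
#' @inheritParams cwt
#' @param at Integer sample indices (1-based) at which spectra are needed.
#' @return Numeric matrix `length(frequencies)` x `length(at)` of moduli, with
#'   `frequencies` attached as attribute `"frequencies"`.
#' @export
marker_spectra <- function(signal, fs, frequencies, at, beta = 10, gamma = 20,
                           block_s = 60, overlap_s = 5) {
  cwt_check(signal, fs, frequencies)
  at <- as.integer(at)
  if (any(at < 1L | at > length(signal))) stop("marker index out of range")
  plan <- block_plan(length(signal), fs, block_s, overlap_s)
  out <- matrix(NA_real_, nrow = length(frequencies), ncol = length(at))
  for (j in seq_len(nrow(plan))) {
    sel <- which(at >= plan$own_start[j] & at <= plan$own_end[j])
    if (!length(sel)) next
    seg <- signal[plan$start[j]:plan$end[j]]
    Wb <- cwt_kernel(seg, fs, frequencies, beta, gamma)
    out[, sel] <- Mod(Wb[, at[sel] - plan$start[j] + 1L, drop = FALSE])
  }
  attr(out, "frequencies") <- frequencies
  out
}

# column-wise max and argmax with ties resolved toward the lower row index
col_max_lowtie <- function(mod) {
  d <- mod[1L, ]
  arg <- rep.int(1L, ncol(mod))
  if (nrow(mod) > 1L) {
    for (i in 2:nrow(mod)) {
      upd <- mod[i, ] > d
      if (any(upd)) {
        d[upd] <- mod[i, upd]
        arg[upd] <- i
      }
    }
  }
  list(max = d, arg = arg)
}
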