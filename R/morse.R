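#' Ascending frequency grid
#'
#' Regular grid `{f_min, f_min + df, ..., f_max}` inclusive of both ends
#' (the upper end is included when `f_max - f_min` is a multiple of `df`).
#'
#' @param f_min,f_max Band edges in Hz (`f_min < f_max`).
#' @param df Grid resolution in Hz (> 0).
#' @return Numeric vector of frequencies in Hz.
#' @export
#' @examples
#' length(frequency_grid(10, 16, 0.1))  # 61
frequency_grid <- function(f_min, f_max, df) {
  if (!is.numeric(df) || length(df) != 1L || df <= 0)
    stop("df must be a positive scalar (Hz)")
  if (!(f_min < f_max)) stop("f_min must be < f_max")
  n <- floor((f_max - f_min) / df + 1e-9) + 1L
  f_min + df * (seq_len(n) - 1L)
}

#' Generalized Morse spectral window
#'
#' The analytic Morse wavelet in the frequency domain,
#' `Psi(w) = H(w) c w^beta exp(-w^gamma)`, with the normalization constant `c`
#' fixed so that the peak value is 1 (peak normalization). The peak sits at
#' `w = (beta/gamma)^(1/gamma)`. Peak normalization makes the wavelet modulus
#' of a unit sinusoid approximately `1/2` at the matching scale, uniformly
#' across analysis frequencies.
#'
#' @param omega Angular frequencies (any real values; the window is zero for
#'   `omega <= 0`).
#' @param beta,gamma Morse shape parameters (> 0); the detector defaults are
#'   `beta = 10`, `gamma = 20`.
#' @return Nonnegative window values, peak value 1.
#' @export
#' @examples
#' w <- seq(0, 2, by = 1e-3)
#' max(morse_window(w, 10, 20))  # 1
morse_window <- function(omega, beta, gamma) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) stop("beta must be > 0")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) stop("gamma must be > 0")
  out <- numeric(length(omega))
  pos <- is.finite(omega) & omega > 0
  wp <- morse_peak_omega(beta, gamma)
  log_peak <- beta * log(wp) - wp^gamma
  out[pos] <- exp(beta * log(omega[pos]) - omega[pos]^gamma - log_peak)
  out
}

#' Peak angular frequency of the Morse window
#'
#' Closed form `(beta/gamma)^(1/gamma)`, from setting the derivative of
#' `beta log(w) - w^gamma` to zero.
#'
#' @inheritParams morse_window
#' @return Angular frequency of the window maximum.
#' @export
morse_peak_omega <- function(beta, gamma) (beta / gamma)^(1 / gamma)

# Gaussian curvature approximation of the window around its peak; used to
# derive the time-domain e-folding scale for the cone-of-influence margin.
morse_curvature <- function(beta, gamma) {
  wp <- morse_peak_omega(beta, gamma)
  beta / wp^2 + gamma * (gamma - 1) * wp^(gamma - 2)
}

# e-folding time (samples) of the wavelet envelope at scale a (Gaussian
# approximation: time std = a * sqrt(k2), envelope falls to 1/e at sqrt(2) std)
morse_efold_samples <- function(a, beta, gamma) {
  sqrt(2) * a * sqrt(morse_curvature(beta, gamma))
}
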