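#' Montage: weighted channel mixture
#'
#' A montage is a nonnegative, L1-normalized weight vector over channel names.
#' Mixing a recording with a montage produces one virtual channel
#' `s = m' S` (weights times the channel x sample matrix).
#'
#' @param weights Named numeric vector of nonnegative channel weights. Weights
#'   are required to sum to 1 within `1e-9`; use `normalize = TRUE` to rescale
#'   (a warning is issued when the sum deviates from 1 by more than `1e-6`).
#' @param normalize Rescale weights to sum to 1.
#' @return An object of class `"montage"` (named numeric vector).
#' @export
#' @examples
#' m <- montage(c(Cz = 0.5, Pz = 0.5))
montage <- function(weights, normalize = FALSE) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("montage weights must be a named vector")
  if (anyDuplicated(names(weights))) stop("duplicate channel names in montage")
  nm <- names(weights)
  w <- as.numeric(weights)
  names(w) <- nm
  if (length(w) == 0L) stop("montage must be nonempty")
  if (any(!is.finite(w)) || any(w < 0))
    stop("montage weights must be finite and nonnegative")
  s <- sum(w)
  if (normalize) {
    if (s <= 0) stop("montage weights sum to zero; cannot normalize")
    if (abs(s - 1) > 1e-6)
      warning(sprintf("montage weights sum to %.8f; normalizing to 1", s))
    w <- w / s
  } else if (abs(s - 1) > 1e-9) {
    stop(sprintf("montage weights must sum to 1 (got %.10f)", s))
  }
  structure(w, class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("montage over", length(x), "channel(s):\n")
  print(unclass(x))
  invisible(x)
}

.preset_montage_channels <- list(
  m1 = c("Fp1", "Fp2", "F7", "F8"),
  m2 = c("O1", "O2", "Oz"),
  m3 = c("F3", "F4", "C3", "C4", "P3", "P4", "Fz", "Cz", "Pz"),
  m4 = "Fz",
  m5 = "Cz",
  m6 = "Pz"
)

#' Preset detection montages m1-m6
#'
#' Equal-weight (1/N) montages over fixed channel sets: `m1` prefrontal/frontal
#' (Fp1, Fp2, F7, F8), `m2` occipital (O1, O2, Oz), `m3` fronto-centro-parietal
#' (F3, F4, C3, C4, P3, P4, Fz, Cz, Pz), and `m4`/`m5`/`m6` the single channels
#' Fz, Cz and Pz. `m3` is the default detection montage.
#'
#' @param name One of `"m1"` ... `"m6"`.
#' @param available_channels Optional character vector; when given, every
#'   montage channel must be present in it.
#' @return A [montage()].
#' @export
#' @examples
#' preset_montage("m5")
preset_montage <- function(name, available_channels = NULL) {
  name <- match.arg(name, names(.preset_montage_channels))
  chans <- .preset_montage_channels[[name]]
  if (!is.null(available_channels)) {
    missing <- setdiff(chans, available_channels)
    if (length(missing))
      stop("montage ", name, " requires missing channel(s): ",
           paste(missing, collapse = ", "))
  }
  montage(stats::setNames(rep(1 / length(chans), length(chans)), chans))
}

#' Read a montage file
#'
#' Whitespace-delimited `name weight` rows, no header. Weights are normalized
#' on load, with a warning when their sum deviates from 1 by more than 1e-6.
#'
#' @param path Path to the montage file.
#' @return A [montage()].
#' @export
read_montage <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("name", "weight"),
                           stringsAsFactors = FALSE)
  montage(stats::setNames(tab$weight, tab$name), normalize = TRUE)
}

#' Mix a recording into one virtual channel
#'
#' Computes the weighted channel sum `s[t] = sum_c w_c * S[c, t]`.
#'
#' @param recording An [eeg_recording()].
#' @param mont A [montage()], a preset name (`"m1"`..`"m6"`), or a named weight
#'   vector.
#' @return Numeric vector of length `N_t` (microvolts).
#' @export
#' @examples
#' rec <- eeg_recording(rbind(Cz = rep(1, 10), Pz = rep(3, 10)),
#'                      c("Cz", "Pz"), fs = 256)
#' mix(rec, montage(c(Cz = 0.5, Pz = 0.5)))  # constant 2
mix <- function(recording, mont) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.character(mont) && length(mont) == 1L)
    mont <- preset_montage(mont, recording$channel_names)
  if (!inherits(mont, "montage")) mont <- montage(mont)
  idx <- match(names(mont), recording$channel_names)
  if (anyNA(idx))
    stop("montage names missing from recording: ",
         paste(names(mont)[is.na(idx)], collapse = ", "))
  as.numeric(crossprod(recording$samples[idx, , drop = FALSE], as.numeric(mont)))
}
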