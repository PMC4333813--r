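#' Multichannel EEG recording
#'
#' Bundles a channels x samples matrix (microvolts) with channel names, the
#' sampling rate and a flat scalp layout.
#'
#' @param samples Numeric matrix, `N_c` channels x `N_t` samples.
#' @param channel_names Character vector of length `N_c`; unique, and every
#'   name must be present in `layout`.
#' @param fs Sampling rate in Hz.
#' @param layout Channel layout data frame (see [default_layout()]).
#' @return An object of class `"eeg_recording"`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 512), 2), c("Cz", "Pz"), fs = 256)
#' rec
eeg_recording <- function(samples, channel_names, fs, layout = default_layout()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  channel_names <- as.character(channel_names)
  if (nrow(samples) < 1L || ncol(samples) < 1L)
    stop("recording needs at least one channel and one sample")
  if (length(channel_names) != nrow(samples))
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", nrow(samples), ")")
  if (anyDuplicated(channel_names))
    stop("duplicate channel names")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  layout <- validate_layout(layout)
  missing <- setdiff(channel_names, layout$name)
  if (length(missing))
    stop("channels absent from layout: ", paste(missing, collapse = ", "))
  rownames(samples) <- channel_names
  structure(list(samples = samples, channel_names = channel_names,
                 fs = fs, layout = layout),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording:", nrow(x$samples), "channels x", ncol(x$samples),
      sprintf("samples (%.1f s at %g Hz)\n", ncol(x$samples) / x$fs, x$fs))
  cat("channels:", paste(x$channel_names, collapse = " "), "\n")
  invisible(x)
}

n_samples <- function(recording) ncol(recording$samples)

#' Hypnogram (per-epoch sleep stages)
#'
#' Stage codes follow the convention 0 = wake, 1-4 = NREM1-4, 5 = REM, over
#' fixed-length epochs.
#'
#' @param stages Integer vector of stage codes in `0:5`.
#' @param epoch_length Epoch length in seconds (default 20).
#' @return An object of class `"hypnogram"`.
#' @export
hypnogram <- function(stages, epoch_length = 20) {
  stages <- as.integer(stages)
  if (length(stages) < 1L) stop("hypnogram must contain at least one epoch")
  if (any(is.na(stages)) || any(!stages %in% 0:5))
    stop("stage codes must be integers in 0..5")
  if (!is.numeric(epoch_length) || length(epoch_length) != 1L || epoch_length <= 0)
    stop("epoch_length must be a positive scalar (s)")
  structure(list(stages = stages, epoch_length = epoch_length),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("hypnogram:", length(x$stages), "epochs of", x$epoch_length, "s\n")
  print(table(factor(x$stages, levels = 0:5,
                     labels = c("wake", "N1", "N2", "N3", "N4", "REM"))))
  invisible(x)
}

hypnogram_span <- function(h) length(h$stages) * h$epoch_length

#' Expert spindle annotations
#'
#' @param channel Character vector of channel names.
#' @param onset Onset times in seconds (>= 0).
#' @param duration Durations in seconds (> 0).
#' @return A data frame of class `"annotation_set"` with columns
#'   `channel`, `onset`, `duration`.
#' @export
annotation_set <- function(channel = character(), onset = numeric(),
                           duration = numeric()) {
  channel <- as.character(channel)
  onset <- as.numeric(onset)
  duration <- as.numeric(duration)
  if (length(unique(c(length(channel), length(onset), length(duration)))) != 1L)
    stop("channel, onset and duration must have equal lengths")
  if (any(onset < 0)) stop("annotation onsets must be >= 0")
  if (any(duration <= 0)) stop("annotation durations must be > 0")
  structure(data.frame(channel = channel, onset = onset, duration = duration,
                       stringsAsFactors = FALSE),
            class = c("annotation_set", "data.frame"))
}
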