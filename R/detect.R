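# Two-phase spindle detector: mix -> CWT ridge -> markers -> features ->
# REM-null thresholds + selection (sensitivity) -> clustering + supervised
# class selection (specificity) -> by-event evaluation.

#' Detector configuration
#'
#' All defaults are the detector's published operating point: Morse wavelet
#' `beta = 10`, `gamma = 20`; ridge band 10-16 Hz at 0.1 Hz; sigma-index bands
#' 4-10 / 10.5-16 / 20-40 Hz; montage `m3`; selection level `alpha = 0.1`;
#' medial-feature window 0.5 s; cut ratio `r = 0.6`; expert coverage 0.8.
#'
#' @param montage Preset montage name (`"m1"`..`"m6"`), a [montage()], or a
#'   named weight vector.
#' @param alpha Sensitivity-phase significance level in (0, 1).
#' @param beta,gamma Morse wavelet parameters.
#' @param ridge_band `c(f_min, f_max)` of the ridge grid (Hz).
#' @param ridge_df Ridge grid resolution (Hz).
#' @param sigma_bands List of `low`, `sigma`, `high` band edges (Hz).
#' @param med_window Medial-feature window length (s).
#' @param r Dendrogram cut ratio in (0, 1].
#' @param coverage Expert coverage target in (0, 1].
#' @param stages Tested (NREM) stage codes.
#' @param min_null Minimum REM events needed for the null model.
#' @param block_s,overlap_s CWT block processing parameters (s).
#' @return A list of class `"spindle_config"`.
#' @export
spindle_config <- function(montage = "m3", alpha = 0.1, beta = 10, gamma = 20,
                           ridge_band = c(10, 16), ridge_df = 0.1,
                           sigma_bands = list(low = c(4, 10),
                                              sigma = c(10.5, 16),
                                              high = c(20, 40)),
                           med_window = 0.5, r = 0.6, coverage = 0.8,
                           stages = 1:4, min_null = 50,
                           block_s = 60, overlap_s = 5) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, gamma > 0,
            ridge_band[1] < ridge_band[2], ridge_df > 0,
            r > 0, r <= 1, coverage > 0, coverage <= 1, med_window > 0)
  structure(list(montage = montage, alpha = alpha, beta = beta, gamma = gamma,
                 ridge_band = ridge_band, ridge_df = ridge_df,
                 sigma_bands = sigma_bands, med_window = med_window,
                 r = r, coverage = coverage, stages = stages,
                 min_null = min_null, block_s = block_s,
                 overlap_s = overlap_s),
            class = "spindle_config")
}

#' Run the two-phase spindle detector
#'
#' Fits the detector to a recording: segments the montage-mixed signal into
#' events at ridge local maxima, computes the event features, learns the
#' amplitude/sigma thresholds from the REM null and selects NREM candidates
#' (sensitivity phase), then — when expert annotations are available — clusters
#' the candidates on (freq, med), cuts the dendrogram by the class-size ratio
#' rule, keeps the classes covering the expert events, and evaluates the
#' by-event metrics of both phases. Without annotations the detector stops
#' after the sensitivity phase with a notice (the specificity phase is
#' supervised).
#'
#' @param recording An [eeg_recording()].
#' @param hyp A [hypnogram()] covering the recording.
#' @param annotations Optional [annotation_set()] of expert-scored spindles.
#' @param config A [spindle_config()].
#' @param artifact_mask Optional (start_s, end_s) intervals to exclude.
#' @return An object of class `"spindle_detection"`; see the methods
#'   [print.spindle_detection()], [summary.spindle_detection()],
#'   [plot.spindle_detection()], [coef.spindle_detection()]. Key elements:
#'   `events` (per-event feature table with selection flags and class labels),
#'   `null`, `thresholds`, `selection`, `dendrogram`, `partition`,
#'   `class_selection`, `metrics` (list with `sensitivity` and `specificity`
#'   reports when annotations were supplied), `config`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_psg(sim_config(duration_s = 600, seed = 42))
#' fit <- detect_spindles(sim$recording, sim$hypnogram, sim$annotations)
#' summary(fit)
#' }
detect_spindles <- function(recording, hyp, annotations = NULL,
                            config = spindle_config(), artifact_mask = NULL) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(hyp, "hypnogram"))
  cfg <- config
  if (hypnogram_span(hyp) < n_samples(recording) / recording$fs - 1e-9)
    stop("hypnogram (", hypnogram_span(hyp), " s) does not cover the recording")

  signal <- mix(recording, cfg$montage)

  grid <- frequency_grid(cfg$ridge_band[1], cfg$ridge_band[2], cfg$ridge_df)
  rt <- cwt_ridge(signal, recording$fs, grid, cfg$beta, cfg$gamma,
                  cfg$block_s, cfg$overlap_s)
  markers <- local_maxima(rt, drop_coi = TRUE, artifact_mask = artifact_mask)
  if (length(markers) < 3L) stop("segmentation produced fewer than 3 events")

  time_s <- (markers - 1L) / recording$fs
  wide <- frequency_grid(cfg$sigma_bands$low[1], cfg$sigma_bands$high[2],
                         cfg$ridge_df)
  spectra <- marker_spectra(signal, recording$fs, wide, markers,
                            cfg$beta, cfg$gamma, cfg$block_s, cfg$overlap_s)
  ff <- freq_feature(rt, markers)
  events <- data.frame(
    sample_index = markers,
    time_s = time_s,
    amp = amp_feature(rt, markers),
    sigma = sigma_index(spectra, bands = cfg$sigma_bands),
    freq = ff$freq,
    f_max = ff$f_max,
    stage = stage_feature(hyp, time_s),
    expert = expert_feature(annotations, time_s)
  )

  null <- build_null(events, cfg$min_null)
  thr <- null_thresholds(null, cfg$alpha)
  sel <- select_events(events, thr, cfg$stages)
  events$selected_sensitivity <- sel$selected

  out <- list(events = events, null = null, thresholds = thr, selection = sel,
              dendrogram = NULL, partition = NULL, class_selection = NULL,
              metrics = list(), config = cfg, fs = recording$fs,
              n_markers = length(markers), notice = NULL)
  class(out) <- "spindle_detection"

  tested <- events[events$stage %in% cfg$stages, , drop = FALSE]
  if (!is.null(annotations)) {
    cc1 <- confusion_counts(tested$selected_sensitivity, tested$expert)
    out$metrics$sensitivity <- list(confusion = cc1,
                                    report = detection_metrics(cc1))
  }

  cand <- which(events$selected_sensitivity)
  if (is.null(annotations) || sum(events$expert[cand]) == 0L) {
    out$notice <- if (is.null(annotations))
      "no expert annotations supplied; stopping after the sensitivity phase (the specificity phase is supervised)"
    else
      "no expert events among selected candidates; stopping after the sensitivity phase"
    message(out$notice)
    return(out)
  }
  if (length(cand) < 2L) {
    out$notice <- "fewer than 2 selected candidates; specificity phase skipped"
    message(out$notice)
    return(out)
  }

  med <- med_feature(recording, events$sample_index[cand], cfg$med_window)
  events$med <- NA_real_
  events$med[cand] <- med$med
  events$med_channel <- NA_character_
  events$med_channel[cand] <- med$channel

  dendro <- ahc(cbind(freq = events$freq[cand], med = events$med[cand]))
  part <- cut_rratio(dendro, cfg$r)
  csel <- select_classes(part, events$expert[cand], cfg$coverage)
  events$class <- NA_integer_
  events$class[cand] <- part$labels
  events$selected_specificity <- FALSE
  events$selected_specificity[cand] <- csel$keep_event

  out$events <- events
  out$dendrogram <- dendro
  out$partition <- part
  out$class_selection <- csel

  tested <- events[events$stage %in% cfg$stages, , drop = FALSE]
  cc2 <- confusion_counts(tested$selected_specificity, tested$expert)
  out$metrics$specificity <- list(confusion = cc2,
                                  report = detection_metrics(cc2))
  out
}

#' @export
print.spindle_detection <- function(x, ...) {
  cat("two-phase spindle detection\n")
  cat(sprintf("  events segmented: %d   tested (NREM): %d\n",
              x$n_markers, x$selection$n_tested))
  cat(sprintf("  sensitivity: %d selected (P%% = %.4f, FDr bound %.3g, alpha = %g)\n",
              x$selection$n_selected, x$selection$P_pct,
              x$selection$fdr_upper, x$thresholds$alpha))
  if (!is.null(x$partition))
    cat(sprintf("  specificity: %d classes, kept %s -> %d events\n",
                x$partition$n_classes,
                paste(x$class_selection$kept, collapse = ","),
                sum(x$events$selected_specificity, na.rm = TRUE)))
  if (!is.null(x$notice)) cat("  note:", x$notice, "\n")
  invisible(x)
}

#' Summary of a spindle detection
#'
#' @param object A `"spindle_detection"`.
#' @param ... Unused.
#' @export
summary.spindle_detection <- function(object, ...) {
  print(object)
  print(object$thresholds)
  if (!is.null(object$partition)) {
    print(object$partition)
    print(object$class_selection)
  }
  if (!is.null(object$metrics$sensitivity)) {
    cat("sensitivity-phase metrics (NREM pool):\n")
    print(object$metrics$sensitivity$confusion)
    print(object$metrics$sensitivity$report)
  }
  if (!is.null(object$metrics$specificity)) {
    cat("specificity-phase metrics (NREM pool):\n")
    print(object$metrics$specificity$confusion)
    print(object$metrics$specificity$report)
  }
  invisible(object)
}

#' Learned detector parameters
#'
#' @param object A `"spindle_detection"`.
#' @param ... Unused.
#' @return Named vector with the learned thresholds and the fixed selection
#'   parameters.
#' @export
coef.spindle_detection <- function(object, ...) {
  c(tau_amp = object$thresholds$tau_amp,
    tau_sigma = object$thresholds$tau_sigma,
    alpha = object$thresholds$alpha,
    r = object$config$r,
    coverage = object$config$coverage)
}

#' Plot a spindle detection
#'
#' Scatter of the clustered candidates in the (freq, med) plane, colored by
#' class, with kept classes drawn as filled points. Falls back to the
#' amplitude/sigma scatter of the sensitivity phase when no clustering was
#' performed.
#'
#' @param x A `"spindle_detection"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spindle_detection <- function(x, ...) {
  ev <- x$events
  if (!is.null(x$partition)) {
    cl <- ev$class
    keep <- ev$selected_specificity
    ok <- !is.na(cl)
    graphics::plot(ev$freq[ok], ev$med[ok],
                   col = grDevices::hcl.colors(max(cl, na.rm = TRUE), "Dark 2")[cl[ok]],
                   pch = ifelse(keep[ok], 19, 1),
                   xlab = "normalized frequency", ylab = "medial position",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::legend("topright", legend = c("kept", "rejected"),
                     pch = c(19, 1), bty = "n")
  } else {
    graphics::plot(ev$amp, ev$sigma, col = ifelse(ev$selected_sensitivity, 2, 1),
                   pch = ifelse(ev$selected_sensitivity, 19, 1), log = "xy",
                   xlab = "ridge amplitude (uV)", ylab = "sigma index", ...)
    graphics::abline(v = x$thresholds$tau_amp, h = x$thresholds$tau_sigma,
                     lty = 2)
  }
  invisible(x)
}
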