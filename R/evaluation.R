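# By-event evaluation: confusion accounting of detector flags against expert
# flags, the standard metric suite, p-value sweep curves, and sleep-cycle
# distribution of events.

#' By-event confusion counts
#'
#' Tallies the four conjunctions of the detector flag and the expert flag per
#' event: TP (both 1), TN (both 0), FP (selected only), FN (expert only). The
#' counts always sum to the number of evaluated events.
#'
#' @param selected Detector flags (0/1 or logical), one per event.
#' @param expert Expert flags (0/1 or logical), same length.
#' @return An object of class `"confusion_counts"` with fields `TP`, `TN`,
#'   `FP`, `FN`, `N`.
#' @export
confusion_counts <- function(selected, expert) {
  s <- as.logical(selected)
  e <- as.logical(expert)
  if (length(s) != length(e)) stop("selected and expert flags must have equal length")
  if (anyNA(s) || anyNA(e)) stop("flags must be defined (non-NA) on every event")
  structure(list(TP = sum(s & e), TN = sum(!s & !e),
                 FP = sum(s & !e), FN = sum(!s & e), N = length(s)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("events: %d   TP %d  FP %d  FN %d  TN %d\n",
              x$N, x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Detection performance metrics
#'
#' Computes, from by-event confusion counts: sensitivity `Se = TP/(TP+FN)`,
#' specificity `Sp = TN/(TN+FP)`, false positive rate `FPr = 100 - Sp`, false
#' discovery rate `FDr = FP/(FP+TP)`, false positive proportion
#' `FPp = FP/(FN+TP)` (all as percentages on the 0-100 scale), plus Matthews'
#' correlation coefficient, the F1 score, and Cohen's kappa on their usual
#' \[-1, 1\] / \[0, 1\] scales. Metrics with a zero denominator are reported
#' as `NA` rather than 0.
#'
#' @param cc A `"confusion_counts"` object (or a list with `TP`, `TN`, `FP`,
#'   `FN`).
#' @return A list of class `"metrics_report"` with fields `Se`, `Sp`, `FPr`,
#'   `FDr`, `FPp`, `MCC`, `F1`, `kappa`.
#' @export
detection_metrics <- function(cc) {
  tp <- as.numeric(cc$TP); tn <- as.numeric(cc$TN)
  fp <- as.numeric(cc$FP); fn <- as.numeric(cc$FN)
  n <- tp + tn + fp + fn
  if (n == 0) {
    return(structure(list(Se = NA_real_, Sp = NA_real_, FPr = NA_real_,
                          FDr = NA_real_, FPp = NA_real_, MCC = NA_real_,
                          F1 = NA_real_, kappa = NA_real_),
                     class = "metrics_report"))
  }
  rat <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  se <- rat(tp, tp + fn)
  sp <- rat(tn, tn + fp)
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  structure(list(Se = se, Sp = sp, FPr = if (is.na(sp)) NA_real_ else 100 - sp,
                 FDr = rat(fp, fp + tp), FPp = rat(fp, fn + tp),
                 MCC = mcc, F1 = f1, kappa = kappa),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", v)
  cat(sprintf("Se %s  Sp %s  FPr %s  FDr %s  FPp %s\n",
              pct(x$Se), pct(x$Sp), pct(x$FPr), pct(x$FDr), pct(x$FPp)))
  cat(sprintf("MCC %.3f  F1 %.3f  kappa %.3f\n", x$MCC, x$F1, x$kappa))
  invisible(x)
}

#' Sensitivity/specificity sweep over the selection p-value
#'
#' Re-runs thresholding and selection for a descending sequence of `alpha`
#' values, evaluates the by-event metrics at each, and locates the crossing
#' point where Se = Sp by linear interpolation between adjacent alphas.
#'
#' @param events Tested-pool data frame with columns `amp`, `sigma`, `stage`,
#'   `expert`.
#' @param null A `"null_model"`.
#' @param alphas Descending vector of significance levels in (0, 1).
#' @param stages Tested stage codes (default NREM 1-4).
#' @return A list of class `"pvalue_sweep"`: `table` (one row per alpha with
#'   counts and metrics) and `crossing` (list with `alpha`, `value` where
#'   Se = Sp, or NULLs when no crossing occurs).
#' @export
pvalue_sweep <- function(events, null, alphas, stages = 1:4) {
  stopifnot(inherits(null, "null_model"))
  if (any(alphas <= 0 | alphas >= 1)) stop("alphas must lie in (0, 1)")
  if (is.unsorted(rev(alphas))) stop("alphas must be in descending order")
  pool <- events[events$stage %in% stages, , drop = FALSE]
  rows <- lapply(alphas, function(a) {
    thr <- null_thresholds(null, a)
    sel <- pool$amp >= thr$tau_amp & pool$sigma >= thr$tau_sigma
    cc <- confusion_counts(sel, pool$expert)
    m <- detection_metrics(cc)
    data.frame(alpha = a, n_selected = sum(sel), TP = cc$TP, FP = cc$FP,
               FN = cc$FN, TN = cc$TN, Se = m$Se, Sp = m$Sp, FPr = m$FPr,
               FDr = m$FDr, FPp = m$FPp, MCC = m$MCC, F1 = m$F1,
               kappa = m$kappa)
  })
  tab <- do.call(rbind, rows)
  crossing <- list(alpha = NA_real_, value = NA_real_)
  gap <- tab$Se - tab$Sp
  for (i in seq_len(nrow(tab) - 1L)) {
    if (is.na(gap[i]) || is.na(gap[i + 1L])) next
    if (gap[i] == 0) {
      crossing <- list(alpha = tab$alpha[i], value = tab$Se[i])
      break
    }
    if (gap[i] * gap[i + 1L] < 0) {
      w <- gap[i] / (gap[i] - gap[i + 1L])
      crossing <- list(alpha = tab$alpha[i] + w * (tab$alpha[i + 1L] - tab$alpha[i]),
                       value = tab$Se[i] + w * (tab$Se[i + 1L] - tab$Se[i]))
      break
    }
  }
  structure(list(table = tab, crossing = crossing), class = "pvalue_sweep")
}

#' @export
print.pvalue_sweep <- function(x, ...) {
  print(x$table[, c("alpha", "n_selected", "Se", "Sp", "FDr")], row.names = FALSE)
  if (!is.na(x$crossing$alpha))
    cat(sprintf("Se = Sp = %.1f%% at alpha = %.4g (interpolated)\n",
                x$crossing$value, x$crossing$alpha))
  invisible(x)
}

#' Sleep cycles from a hypnogram
#'
#' A cycle is a NREM period followed by a REM period. The NREM period starts
#' at the first NREM epoch and ends at the first REM epoch; the REM period
#' ends at the last REM epoch followed by at least 15 minutes free of REM
#' epochs (or at the end of the record).
#'
#' @param hyp A [hypnogram()].
#' @param rem_gap_min REM-free gap (minutes) terminating a REM period
#'   (default 15).
#' @return Data frame with one row per cycle: `nrem_start_epoch`,
#'   `rem_start_epoch`, `end_epoch` (1-based, inclusive).
#' @export
sleep_cycles <- function(hyp, rem_gap_min = 15) {
  stopifnot(inherits(hyp, "hypnogram"))
  st <- hyp$stages
  n <- length(st)
  gap_epochs <- ceiling(rem_gap_min * 60 / hyp$epoch_length)
  is_nrem <- st %in% 1:4
  is_rem <- st == 5L
  cycles <- list()
  i <- 1L
  repeat {
    nrem_start <- i - 1L + which(is_nrem[i:n])[1L]
    if (is.na(nrem_start)) break
    rem_start <- if (nrem_start < n)
      nrem_start + which(is_rem[(nrem_start + 1L):n])[1L] else NA_integer_
    if (is.na(rem_start)) break
    # extend the REM period while further REM epochs occur within the gap
    end <- rem_start
    j <- rem_start + 1L
    while (j <= n) {
      nxt <- j - 1L + which(is_rem[j:n])[1L]
      if (is.na(nxt) || nxt - end > gap_epochs) break
      end <- nxt
      j <- nxt + 1L
    }
    cycles[[length(cycles) + 1L]] <- c(nrem_start, rem_start, end)
    i <- end + 1L
    if (i > n) break
  }
  if (!length(cycles))
    return(data.frame(nrem_start_epoch = integer(), rem_start_epoch = integer(),
                      end_epoch = integer()))
  m <- do.call(rbind, cycles)
  data.frame(nrem_start_epoch = m[, 1L], rem_start_epoch = m[, 2L],
             end_epoch = m[, 3L])
}

#' Per-cycle event distribution
#'
#' For each class label, the proportion of events falling in each of the first
#' `n_cycles` sleep cycles, normalized to sum to 1 per class. Events outside
#' every cycle are ignored.
#'
#' @param time_s Event times (seconds).
#' @param cycles Cycle table from [sleep_cycles()].
#' @param labels Class label per event (any atomic type).
#' @param hyp The [hypnogram()] the cycles were derived from.
#' @param n_cycles Number of leading cycles to report (default 4).
#' @return Matrix: one row per class, `n_cycles` columns of proportions.
#' @export
per_cycle_distribution <- function(time_s, cycles, labels, hyp, n_cycles = 4) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (nrow(cycles) < 1L) stop("at least one sleep cycle required")
  if (nrow(cycles) < n_cycles) {
    warning("only ", nrow(cycles), " cycles available; reporting those")
    n_cycles <- nrow(cycles)
  }
  epoch <- floor(time_s / hyp$epoch_length) + 1L
  cyc <- rep(NA_integer_, length(time_s))
  for (k in seq_len(n_cycles)) {
    inside <- epoch >= cycles$nrem_start_epoch[k] & epoch <= cycles$end_epoch[k]
    cyc[inside] <- k
  }
  keep <- !is.na(cyc)
  classes <- sort(unique(labels))
  out <- matrix(0, nrow = length(classes), ncol = n_cycles,
                dimnames = list(as.character(classes),
                                paste0("cycle", seq_len(n_cycles))))
  for (ci in seq_along(classes)) {
    sel <- keep & labels == classes[ci]
    counts <- tabulate(cyc[sel], nbins = n_cycles)
    if (sum(counts) > 0) out[ci, ] <- counts / sum(counts)
  }
  out
}
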