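# Sensitivity phase: build the non-spindle null from REM events, threshold
# amplitude and sigma at the (1 - alpha) percentile of the null, and keep the
# NREM events exceeding both thresholds.

#' Build the REM null model
#'
#' The null (non-spindle) sample consists of the amplitude and sigma-index
#' values of all events in REM epochs (stage 5), where spindles are assumed
#' absent.
#'
#' @param events Data frame with at least columns `amp`, `sigma`, `stage`.
#' @param min_null Minimum number of REM events required (default 50).
#' @return An object of class `"null_model"`: sorted `amp_null` and
#'   `sigma_null` samples and their common size `n_null`.
#' @export
build_null <- function(events, min_null = 50) {
  stopifnot(all(c("amp", "sigma", "stage") %in% names(events)))
  rem <- events[events$stage == 5L, , drop = FALSE]
  if (nrow(rem) < min_null)
    stop("insufficient REM null sample: ", nrow(rem), " events (need >= ",
         min_null, ")")
  if (any(!is.finite(rem$amp)) || any(!is.finite(rem$sigma)))
    stop("non-finite feature values in REM null sample")
  structure(list(amp_null = sort(rem$amp), sigma_null = sort(rem$sigma),
                 n_null = nrow(rem)),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat("REM null model:", x$n_null, "events\n")
  cat(sprintf("  amp   median %.4g  90th pct %.4g\n",
              stats::median(x$amp_null), empirical_quantile(x$amp_null, 0.9)))
  cat(sprintf("  sigma median %.4g  90th pct %.4g\n",
              stats::median(x$sigma_null), empirical_quantile(x$sigma_null, 0.9)))
  invisible(x)
}

# inverse-CDF (type-1) empirical quantile: smallest sample value v with at
# least ceiling(p * n) sample values <= v
empirical_quantile <- function(sorted_x, p) {
  n <- length(sorted_x)
  k <- min(n, max(1L, ceiling(p * n - 1e-9)))
  sorted_x[k]
}

#' Percentile thresholds from the null model
#'
#' Each threshold is the empirical `(1 - alpha)` quantile of its null sample,
#' computed independently per feature with the inverse-CDF (type-1) rule: the
#' smallest null value `v` such that at least `ceiling((1 - alpha) n)` null
#' values are `<= v`. Under the `>=` selection rule, at most a proportion
#' `alpha + 1/n` of the null exceeds its own marginal threshold; the joint
#' (amp AND sigma) pass proportion is smaller still.
#'
#' @param null A `"null_model"` from [build_null()].
#' @param alpha Significance level in (0, 1); default 0.1.
#' @return An object of class `"spindle_thresholds"`: `tau_amp`, `tau_sigma`,
#'   `alpha`.
#' @export
#' @examples
#' nm <- structure(list(amp_null = 1:100, sigma_null = 1:100, n_null = 100),
#'                 class = "null_model")
#' null_thresholds(nm, 0.1)$tau_amp  # 90
null_thresholds <- function(null, alpha = 0.1) {
  stopifnot(inherits(null, "null_model"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  structure(list(tau_amp = empirical_quantile(null$amp_null, 1 - alpha),
                 tau_sigma = empirical_quantile(null$sigma_null, 1 - alpha),
                 alpha = alpha),
            class = "spindle_thresholds")
}

#' @export
print.spindle_thresholds <- function(x, ...) {
  cat(sprintf("thresholds (alpha = %g): tau_amp = %.6g, tau_sigma = %.6g\n",
              x$alpha, x$tau_amp, x$tau_sigma))
  invisible(x)
}

#' Sensitivity-phase selection
#'
#' Events in the tested (NREM) pool whose amplitude AND sigma index both meet
#' their thresholds (`>=`, so exact equality passes) are selected. `P_pct` is
#' the proportion of the tested pool not rejected, and `fdr_upper = alpha /
#' P_pct` is the upper bound on the expected false discovery rate (the true
#' FDr equals `alpha * kappa / P_pct` with `kappa`, the unknown proportion of
#' false events in the tested pool, not estimable and reported as `NA`).
#'
#' @param events Data frame with columns `amp`, `sigma`, `stage`.
#' @param thr A `"spindle_thresholds"`.
#' @param stages Stage codes forming the tested pool (default NREM 1-4).
#' @return An object of class `"selection_report"`: logical `selected` (over
#'   all events; FALSE outside the tested pool), `tested` (logical pool
#'   membership), `n_tested`, `n_selected`, `P_pct`, `fdr_upper`, `kappa`,
#'   `thresholds`.
#' @export
select_events <- function(events, thr, stages = 1:4) {
  stopifnot(inherits(thr, "spindle_thresholds"),
            all(c("amp", "sigma", "stage") %in% names(events)))
  tested <- events$stage %in% stages
  pass <- events$amp >= thr$tau_amp & events$sigma >= thr$tau_sigma
  selected <- tested & pass
  n_tested <- sum(tested)
  if (n_tested == 0L) {
    warning("empty tested pool; P_pct undefined")
    P_pct <- NA_real_
    fdr_upper <- NA_real_
  } else {
    P_pct <- sum(selected) / n_tested
    fdr_upper <- if (P_pct > 0) thr$alpha / P_pct else NA_real_
  }
  structure(list(selected = selected, tested = tested,
                 n_tested = n_tested, n_selected = sum(selected),
                 P_pct = P_pct, fdr_upper = fdr_upper, kappa = NA_real_,
                 thresholds = thr),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("sensitivity selection: %d of %d tested events selected (P%% = %.4f)\n",
              x$n_selected, x$n_tested, x$P_pct))
  cat(sprintf("  FDr upper bound alpha/P%% = %.4g (kappa unknown)\n", x$fdr_upper))
  print(x$thresholds)
  invisible(x)
}
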