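# Specificity phase: agglomerative clustering of selected candidates on the
# (freq, med) plane, dendrogram cut by the class-size ratio rule, and
# supervised selection of the classes covering most expert events.

#' Ascending hierarchical classification (Euclidean, average linkage)
#'
#' Iteratively merges the two classes with minimal average pairwise Euclidean
#' distance until a single class remains. Ties in merge order are broken
#' deterministically (smallest class-id pair, as ordered by
#' [stats::hclust()]).
#'
#' @param points Two-column matrix or data frame of (freq, med) pairs, both in
#'   \[0, 1\].
#' @return A `"spindle_dendrogram"`: the underlying [stats::hclust] object
#'   plus `n` (number of items).
#' @export
#' @examples
#' pts <- rbind(cbind(runif(10, 0, .1), runif(10, 0, .1)),
#'              cbind(runif(10, .9, 1), runif(10, .9, 1)))
#' ahc(pts)
ahc <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 2L) stop("clustering requires at least 2 events")
  if (any(!is.finite(pts))) stop("non-finite clustering features")
  h <- stats::hclust(stats::dist(pts, method = "euclidean"), method = "average")
  if (is.unsorted(h$height))
    message("average-linkage height inversion(s) present; cutting in merge order")
  structure(list(hclust = h, n = nrow(pts)), class = "spindle_dendrogram")
}

#' @export
print.spindle_dendrogram <- function(x, ...) {
  cat("average-linkage dendrogram over", x$n, "events;",
      "merge heights", sprintf("%.4g", min(x$hclust$height)), "-",
      sprintf("%.4g", max(x$hclust$height)), "\n")
  invisible(x)
}

#' Cut a dendrogram by the class-size ratio rule
#'
#' Descends from the root, splitting one merge at a time (in decreasing merge
#' order, i.e. maximal inter-class dissimilarity first), and stops at the
#' first partition with at least 2 classes whose second-largest to largest
#' class-size ratio is `>= r`. The rule favors partitions with homogeneous
#' class sizes. If no partition before all-singletons qualifies, the
#' all-singletons partition is returned with a warning (it always satisfies
#' the ratio trivially).
#'
#' @param dendro A `"spindle_dendrogram"` from [ahc()].
#' @param r Ratio bound in (0, 1\]; default 0.6.
#' @return A `"spindle_partition"`: integer `labels` (class ids 1..k in
#'   [stats::cutree()] numbering), `n_classes`, `class_sizes`, `r`.
#' @export
cut_rratio <- function(dendro, r = 0.6) {
  stopifnot(inherits(dendro, "spindle_dendrogram"))
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1)
    stop("r must lie in (0, 1]")
  h <- dendro$hclust
  for (k in 2:dendro$n) {
    labels <- stats::cutree(h, k = k)
    sizes <- sort(tabulate(labels, nbins = k), decreasing = TRUE)
    if (sizes[2L] / sizes[1L] >= r) {
      if (k == dendro$n)
        warning("no coarser partition satisfied the ratio rule; returning singletons")
      return(structure(list(labels = labels, n_classes = k,
                            class_sizes = tabulate(labels, nbins = k), r = r),
                       class = "spindle_partition"))
    }
  }
  # unreachable for n >= 2 (singletons have ratio 1) but kept as a guard
  labels <- seq_len(dendro$n)
  warning("no partition satisfied the ratio rule; returning singletons")
  structure(list(labels = labels, n_classes = dendro$n,
                 class_sizes = rep(1L, dendro$n), r = r),
            class = "spindle_partition")
}

#' @export
print.spindle_partition <- function(x, ...) {
  cat("partition into", x$n_classes, "classes (r =", x$r, "); sizes:",
      paste(x$class_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Supervised class selection
#'
#' Classes are ordered by descending expert-event count (ties: larger class
#' first, then lower class id) and the smallest prefix whose cumulative share
#' of expert events reaches the coverage target is kept.
#'
#' @param partition A `"spindle_partition"`.
#' @param expert Integer/logical vector of expert flags, one per clustered
#'   event.
#' @param coverage Required expert-event coverage in (0, 1\]; default 0.8.
#' @return A `"class_selection"`: `ordering` (class ids by descending expert
#'   count), `n_class` (number kept), `kept` (kept class ids), `coverage`
#'   (achieved fraction), `keep_event` (logical per event).
#' @export
select_classes <- function(partition, expert, coverage = 0.8) {
  stopifnot(inherits(partition, "spindle_partition"))
  expert <- as.integer(as.logical(expert))
  if (length(expert) != length(partition$labels))
    stop("expert flags must match the number of clustered events")
  n_exp <- sum(expert)
  if (n_exp == 0L)
    stop("no expert events among clustered candidates; class selection undefined")
  k <- partition$n_classes
  exp_count <- vapply(seq_len(k), function(cl) sum(expert[partition$labels == cl]),
                      integer(1))
  sizes <- partition$class_sizes
  ordering <- order(-exp_count, -sizes, seq_len(k))
  cum <- cumsum(exp_count[ordering]) / n_exp
  n_class <- which(cum >= coverage - 1e-12)[1L]
  kept <- ordering[seq_len(n_class)]
  structure(list(ordering = ordering, n_class = n_class, kept = kept,
                 coverage = cum[n_class],
                 expert_counts = exp_count,
                 keep_event = partition$labels %in% kept),
            class = "class_selection")
}

#' @export
print.class_selection <- function(x, ...) {
  cat("kept", x$n_class, "class(es) [",
      paste(x$kept, collapse = ", "), "] covering",
      sprintf("%.1f%%", 100 * x$coverage), "of expert events\n")
  invisible(x)
}

#' Partial-scoring bootstrap
#'
#' Repeats the supervised class selection using random subsets of the expert
#' events (as if the expert had scored only `n_scored` spindles) and reports
#' the mean and standard deviation of the sensitivity and specificity
#' differentials (partial minus exhaustive scoring). Metrics are evaluated on
#' the full tested pool against the complete expert flags.
#'
#' @param events Data frame over the tested pool with columns `expert`
#'   (0/1 against the full scoring) and `clustered` (logical: event entered
#'   the clustering), plus any others.
#' @param partition A `"spindle_partition"` over the clustered events (in the
#'   order they appear in `events[events$clustered, ]`).
#' @param n_scored Vector of expert subset sizes, e.g. `c(1, 2, 4, 8, 16, 32,
#'   64, 128)`.
#' @param reps Bootstrap repetitions per subset size (default 500).
#' @param coverage Coverage target passed to [select_classes()].
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with one row per `n_scored`: mean/sd of the Se and Sp
#'   differentials (percentage points).
#' @export
subsample_expert <- function(events, partition, n_scored, reps = 500,
                             coverage = 0.8, seed = NULL) {
  stopifnot(all(c("expert", "clustered") %in% names(events)))
  if (!is.null(seed)) set.seed(seed)
  clustered <- events$clustered
  expert_cl <- events$expert[clustered]
  exp_idx <- which(expert_cl == 1L)
  if (length(exp_idx) == 0L) stop("no expert events among clustered candidates")
  if (any(n_scored > length(exp_idx)))
    stop("n_scored exceeds the ", length(exp_idx), " available expert events")
  full_sel <- select_classes(partition, expert_cl, coverage)
  base <- phase2_metrics(events, full_sel$keep_event)
  out <- data.frame(n_scored = n_scored, dSe_mean = NA_real_, dSe_sd = NA_real_,
                    dSp_mean = NA_real_, dSp_sd = NA_real_)
  for (i in seq_along(n_scored)) {
    dse <- numeric(reps)
    dsp <- numeric(reps)
    for (rrep in seq_len(reps)) {
      sub <- sample(exp_idx, n_scored[i])
      flags <- integer(length(expert_cl))
      flags[sub] <- 1L
      sel <- select_classes(partition, flags, coverage)
      m <- phase2_metrics(events, sel$keep_event)
      dse[rrep] <- m["Se"] - base["Se"]
      dsp[rrep] <- m["Sp"] - base["Sp"]
    }
    out$dSe_mean[i] <- mean(dse)
    out$dSe_sd[i] <- stats::sd(dse)
    out$dSp_mean[i] <- mean(dsp)
    out$dSp_sd[i] <- stats::sd(dsp)
  }
  out
}

# Se/Sp over the full tested pool for a given kept-event rule on the
# clustered subset (non-clustered events count as rejected)
phase2_metrics <- function(events, keep_event) {
  selected <- logical(nrow(events))
  selected[which(events$clustered)] <- keep_event
  cc <- confusion_counts(selected, events$expert)
  m <- detection_metrics(cc)
  c(Se = m$Se, Sp = m$Sp)
}
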