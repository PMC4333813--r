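# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# column-wise ridge by explicit loops
oracle_ridge <- function(mod) {
  d <- numeric(ncol(mod))
  arg <- integer(ncol(mod))
  for (j in seq_len(ncol(mod))) {
    best <- -Inf
    for (i in seq_len(nrow(mod))) {
      if (mod[i, j] > best) {
        best <- mod[i, j]
        arg[j] <- i
      }
    }
    d[j] <- best
  }
  list(d = d, arg = arg)
}

# local maxima by explicit scan with the plateau rule: a run of equal values
# is one maximum at its first sample iff both neighbouring values are lower
oracle_local_maxima <- function(d) {
  n <- length(d)
  out <- integer(0)
  j <- 2L
  while (j <= n - 1L) {
    if (d[j] > d[j - 1L]) {
      e <- j
      while (e < n && d[e + 1L] == d[j]) e <- e + 1L
      if (e < n && d[e + 1L] < d[j]) out <- c(out, j)
      j <- e + 1L
    } else j <- j + 1L
  }
  out
}

# sigma index by explicit band loops
oracle_sigma <- function(spectrum, freqs) {
  in_band <- function(f, lo, hi) f >= lo - 1e-9 & f <= hi + 1e-9
  a_sig <- -Inf
  lo_sum <- 0; lo_n <- 0
  hi_sum <- 0; hi_n <- 0
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    if (in_band(f, 10.5, 16) && spectrum[i] > a_sig) a_sig <- spectrum[i]
    if (in_band(f, 4, 10)) { lo_sum <- lo_sum + spectrum[i]; lo_n <- lo_n + 1 }
    if (in_band(f, 20, 40)) { hi_sum <- hi_sum + spectrum[i]; hi_n <- hi_n + 1 }
  }
  2 * a_sig / (lo_sum / lo_n + hi_sum / hi_n)
}

# average-linkage agglomeration by double-loop recomputation at every step;
# returns the sequence of merge heights
oracle_average_linkage_heights <- function(pts) {
  classes <- lapply(seq_len(nrow(pts)), identity)
  d_item <- as.matrix(stats::dist(pts))
  heights <- numeric(0)
  while (length(classes) > 1L) {
    best <- Inf
    pair <- c(NA, NA)
    for (a in seq_along(classes)) {
      for (b in seq_along(classes)) {
        if (b <= a) next
        s <- 0
        for (xa in classes[[a]]) for (xb in classes[[b]])
          s <- s + d_item[xa, xb]
        L <- s / (length(classes[[a]]) * length(classes[[b]]))
        if (L < best) { best <- L; pair <- c(a, b) }
      }
    }
    heights <- c(heights, best)
    classes[[pair[1]]] <- c(classes[[pair[1]]], classes[[pair[2]]])
    classes[[pair[2]]] <- NULL
  }
  heights
}

# metric formulas coded independently from the confusion counts
oracle_metrics <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  n <- tp + tn + fp + fn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  list(
    Se = 100 * tp / (fn + tp),
    Sp = 100 * tn / (fp + tn),
    FPr = 100 * fp / (fp + tn),
    FDr = 100 * fp / (fp + tp),
    FPp = 100 * fp / (fn + tp),
    MCC = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
    F1 = 2 * tp / (2 * tp + fp + fn),
    kappa = (po - pe) / (1 - pe)
  )
}

# mean silhouette width for a 2-group labelling, coded directly
oracle_silhouette <- function(pts, labels) {
  d <- as.matrix(stats::dist(pts))
  s <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- mean(d[i, own])
    b <- mean(d[i, !own & seq_len(nrow(pts)) != i])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small shared simulated recording, built once per test run
sim_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$sim)) {
      env$sim <- simulate_psg(sim_config(duration_s = 300, amplitude = 50,
                                         seed = 2024))
    }
    env$sim
  }
})
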