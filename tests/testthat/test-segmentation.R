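make_tf <- function(mod, fs = 100, freqs = NULL) {
  if (is.null(freqs)) freqs <- 10 + 0.1 * (seq_len(nrow(mod)) - 1)
  structure(list(coefficients = mod + 0i, frequencies = freqs, fs = fs,
                 coi = 0L), class = "tf_map")
}

test_that("ridge is the column maximum modulus with low-frequency ties", {
  expect_equal(ridge(make_tf(matrix(c(1, 2, 3, 4), 1)))$d, c(1, 2, 3, 4))
  two <- make_tf(rbind(rep(1, 5), rep(3, 5)))
  expect_equal(ridge(two)$d, rep(3, 5))
  expect_equal(ridge(two)$argfreq, rep(2L, 5))
  tied <- make_tf(rbind(rep(2, 4), rep(2, 4)))
  expect_equal(ridge(tied)$argfreq, rep(1L, 4))

  set.seed(17)
  mod <- matrix(runif(5 * 20), 5, 20)
  got <- ridge(make_tf(mod))
  want <- oracle_ridge(mod)
  expect_equal(got$d, want$d)
  expect_equal(got$argfreq, want$arg)
})

test_that("local maxima match the brute-force scan, including plateaus", {
  expect_equal(local_maxima(c(0, 1, 0)), 2L)
  expect_length(local_maxima(1:10), 0)
  expect_length(local_maxima(10:1), 0)
  # plateau higher than both neighbours: one marker at its first sample
  expect_equal(local_maxima(c(0, 2, 2, 2, 1)), 2L)
  # rising plateau is not a maximum
  expect_length(local_maxima(c(0, 1, 1, 2, 3)), 0)
  expect_equal(local_maxima(c(0, 1, 1, 2, 0)), 4L)

  set.seed(23)
  for (rep in 1:20) {
    d <- if (rep %% 2) rnorm(200) else sample(0:5, 200, replace = TRUE)
    expect_equal(local_maxima(d), oracle_local_maxima(d))
  }
})

test_that("markers dominate their neighbours and are sparse", {
  set.seed(31)
  for (rep in 1:10) {
    d <- cumsum(rnorm(300))
    mk <- local_maxima(d)
    expect_true(all(d[mk] >= d[mk - 1] & d[mk] >= d[mk + 1]))
    expect_lte(length(mk), floor(length(d) / 2))
    expect_true(all(diff(mk) > 0))
  }
})

test_that("segmentation is translation-equivariant", {
  set.seed(37)
  d <- abs(rnorm(400))
  k <- 50L
  shifted <- c(rep(0, k), d)
  mk <- local_maxima(d)
  mk_s <- local_maxima(shifted)
  # interior markers of the original appear shifted by k
  expect_true(all((mk + k) %in% mk_s))
})

test_that("cone-of-influence and artifact-mask markers are discarded", {
  d <- rep(0, 100)
  d[c(5, 50, 95)] <- 1
  rt <- spindler:::new_ridge_trace(d, rep(1L, 100), 13, fs = 10, coi = 10L)
  expect_equal(local_maxima(rt), 50L)
  expect_equal(local_maxima(rt, drop_coi = FALSE), c(5L, 50L, 95L))
  # sample 50 is at time 4.9 s under fs = 10
  expect_length(local_maxima(rt, artifact_mask = cbind(4, 6)), 0)
})

test_that("marker tables carry time, frequency and amplitude", {
  d <- c(0, 2, 0, 5, 0)
  rt <- spindler:::new_ridge_trace(d, c(1L, 2L, 1L, 3L, 1L),
                                   c(10, 11, 12), fs = 2, coi = 0L)
  tab <- marker_table(rt, local_maxima(rt))
  expect_equal(tab$sample_index, c(2L, 4L))
  expect_equal(tab$time_s, c(0.5, 1.5))
  expect_equal(tab$frequency_hz, c(11, 12))
  expect_equal(tab$ridge_amplitude, c(2, 5))
})
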