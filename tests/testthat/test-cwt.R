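test_that("frequency grids include both ends at the stated resolution", {
  expect_length(frequency_grid(10, 16, 0.1), 61)
  expect_length(frequency_grid(4, 40, 0.1), 361)
  expect_equal(frequency_grid(10, 10.1, 0.1), c(10, 10.1))
  expect_error(frequency_grid(10, 16, 0), "positive")
  expect_error(frequency_grid(16, 10, 0.1), "f_min")
})

test_that("Morse window is zero at the origin, peak-normalized, peaked at the closed form", {
  expect_identical(morse_window(0, 10, 20), 0)
  expect_identical(morse_window(-3, 10, 20), 0)
  w <- seq(1e-4, 3, by = 1e-4)
  for (bg in list(c(10, 20), c(3, 5), c(2, 1.5))) {
    v <- morse_window(w, bg[1], bg[2])
    expect_equal(max(v), 1, tolerance = 1e-6)
    expect_equal(w[which.max(v)], morse_peak_omega(bg[1], bg[2]),
                 tolerance = 1e-4)
  }
  expect_equal(morse_peak_omega(10, 20), 0.5^(1 / 20))
})

test_that("CWT is linear and its modulus ignores sign flips", {
  fs <- 128
  grid <- frequency_grid(10, 16, 0.5)
  set.seed(3)
  x <- rnorm(512)
  expect_equal(cwt(numeric(512) , fs, grid)$coefficients,
               matrix(0 + 0i, length(grid), 512))
  W1 <- cwt(x, fs, grid)$coefficients
  W2 <- cwt(2 * x, fs, grid)$coefficients
  expect_equal(W2, 2 * W1, tolerance = 1e-12)
  expect_equal(Mod(cwt(-x, fs, grid)$coefficients), Mod(W1), tolerance = 1e-12)
  y <- rnorm(512)
  Wy <- cwt(y, fs, grid)$coefficients
  Wxy <- cwt(0.5 * x + 2 * y, fs, grid)$coefficients
  expect_equal(Wxy, 0.5 * W1 + 2 * Wy, tolerance = 1e-10)
})

test_that("a pure sinusoid localizes at its own grid frequency", {
  fs <- 256
  t <- seq(0, 6, by = 1 / fs)
  grid <- frequency_grid(10, 16, 0.1)
  for (f0 in 11:15) {
    tf <- cwt(sin(2 * pi * f0 * t), fs, grid)
    mid <- floor(length(t) / 4):floor(3 * length(t) / 4)
    avg <- rowMeans(Mod(tf$coefficients[, mid]))
    expect_equal(grid[which.max(avg)], f0, tolerance = 0.11)
    # per-time argmax away from edges stays within one grid step
    am <- apply(Mod(tf$coefficients[, mid]), 2, which.max)
    expect_true(all(abs(grid[am] - f0) <= 0.1 + 1e-9))
  }
  # peak-normalized wavelet: unit sinusoid gives |W| ~ 1/2 at the ridge
  tf <- cwt(sin(2 * pi * 13 * t), fs, grid)
  expect_equal(max(Mod(tf$coefficients[, 800])), 0.5, tolerance = 0.01)
})

test_that("analysis frequencies at or above Nyquist are rejected", {
  expect_error(cwt(rnorm(64), 64, c(10, 40)), "Nyquist")
  expect_error(cwt(rnorm(1), 64, 10), "2 samples")
})

test_that("blockwise processing is seamless", {
  fs <- 128
  set.seed(9)
  t <- seq(0, 130, by = 1 / fs)
  x <- rnorm(length(t)) + sin(2 * pi * 12 * t)
  grid <- frequency_grid(10, 16, 0.5)
  whole <- cwt(x, fs, grid, block_s = 1e6)
  blocked <- cwt(x, fs, grid, block_s = 30, overlap_s = 5)
  interior <- (2 * fs):(length(x) - 2 * fs)
  err <- max(abs(Mod(whole$coefficients[, interior]) -
                 Mod(blocked$coefficients[, interior])))
  expect_lt(err, 1e-4)

  rt <- cwt_ridge(x, fs, grid, block_s = 30, overlap_s = 5)
  expect_equal(rt$d, ridge(blocked)$d)
  expect_equal(rt$argfreq, ridge(blocked)$argfreq)

  at <- c(500L, 5000L, 12000L)
  sp <- marker_spectra(x, fs, grid, at, block_s = 30, overlap_s = 5)
  expect_equal(unname(sp), unname(Mod(blocked$coefficients[, at])),
               tolerance = 1e-10, ignore_attr = TRUE)
})
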