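wide_grid <- frequency_grid(4, 40, 0.1)

spectra_mat <- function(x, freqs = wide_grid) {
  m <- matrix(x, nrow = length(freqs))
  attr(m, "frequencies") <- freqs
  m
}

test_that("amplitude feature returns the ridge value at the marker", {
  rt <- spindler:::new_ridge_trace(c(0, 2, 0), c(1L, 1L, 1L), 13, 10, 0L)
  expect_equal(amp_feature(rt, 2L), 2)
  expect_error(amp_feature(rt, 4L), "out of range")
  set.seed(41)
  mod <- matrix(runif(4 * 15), 4)
  tf <- structure(list(coefficients = mod + 0i, frequencies = 10:13, fs = 10,
                       coi = 0L), class = "tf_map")
  rt2 <- ridge(tf)
  expect_equal(amp_feature(rt2, 7L), oracle_ridge(mod)$d[7])
})

test_that("sigma index matches constructed spectra and the band-loop oracle", {
  s <- rep(1, length(wide_grid))
  s[which.min(abs(wide_grid - 13))] <- 5
  expect_equal(sigma_index(spectra_mat(s)), 5)
  expect_equal(sigma_index(spectra_mat(rep(0.37, length(wide_grid)))), 1)

  set.seed(43)
  for (rep in 1:10) {
    sp <- runif(length(wide_grid), 0.01, 2)
    expect_equal(sigma_index(spectra_mat(sp)), oracle_sigma(sp, wide_grid))
  }
  # scale invariance
  sp <- runif(length(wide_grid), 0.01, 2)
  expect_equal(sigma_index(spectra_mat(7.3 * sp)), sigma_index(spectra_mat(sp)))
  expect_error(sigma_index(spectra_mat(rep(0, length(wide_grid)))), "undefined")
})

test_that("band edges are inclusive: 10 Hz feeds the low band, 10.5 Hz the sigma band", {
  s <- rep(1, length(wide_grid))
  s[which.min(abs(wide_grid - 10.5))] <- 9
  expect_equal(sigma_index(spectra_mat(s)), 2 * 9 / (1 + 1))
  s2 <- rep(1, length(wide_grid))
  s2[which.min(abs(wide_grid - 10.0))] <- 9   # low band only; sigma max stays 1
  lo <- wide_grid >= 4 - 1e-9 & wide_grid <= 10 + 1e-9
  expect_equal(sigma_index(spectra_mat(s2)),
               2 * 1 / (mean(s2[lo]) + 1))
})

test_that("frequency feature maps the band linearly to [0, 1] with low ties", {
  freqs <- frequency_grid(10, 16, 0.1)
  af <- c(31L, 1L, 61L)  # 13, 10, 16 Hz
  rt <- spindler:::new_ridge_trace(rep(1, 3), af, freqs, 10, 0L)
  got <- freq_feature(rt, 1:3)
  expect_equal(got$freq, c(0.5, 0, 1))
  expect_equal(got$f_max, c(13, 10, 16))

  set.seed(47)
  mod <- matrix(runif(61 * 8), 61)
  mod[20, 3] <- mod[40, 3] <- 3  # tie: lower frequency must win
  tf <- structure(list(coefficients = mod + 0i, frequencies = freqs, fs = 10,
                       coi = 0L), class = "tf_map")
  rt2 <- ridge(tf)
  expect_equal(freq_feature(rt2, 3L)$f_max, freqs[20])
  for (j in c(1L, 5L, 8L)) {
    expect_equal(freq_feature(rt2, j)$f_max, freqs[oracle_ridge(mod)$arg[j]])
  }
})

test_that("medial feature finds the dominant channel and is sign-invariant", {
  lay <- default_layout()
  ch <- c("Fz", "Cz", "Pz", "Oz")
  S <- matrix(0, 4, 300)
  S[2, ] <- sin(2 * pi * 13 * (0:299) / 256)  # activity only on Cz
  rec <- eeg_recording(S + 1e-9 * matrix(rnorm(1200), 4), ch, 256, lay)
  got <- med_feature(rec, 150L)
  expect_equal(got$channel, "Cz")
  expect_equal(got$med, lay$y[lay$name == "Cz"] + 0.5)
  # flipping the signal flips the eigenvector sign but not the feature
  rec2 <- eeg_recording(-S + 1e-9 * matrix(rnorm(1200), 4), ch, 256, lay)
  expect_equal(med_feature(rec2, 150L)$med, got$med)
})

test_that("bundled layout spans ~0.15 (occipital) to ~0.9 (prefrontal)", {
  lay <- default_layout()
  med_of <- function(chan) {
    ch <- c(chan, "Cz", "T3")
    S <- matrix(rnorm(3 * 200, sd = 1e-6), 3, 200)
    S[1, ] <- sin(2 * pi * 12 * (0:199) / 256)
    med_feature(eeg_recording(S, ch, 256, lay), 100L)$med
  }
  expect_equal(med_of("Fp1"), 0.9, tolerance = 0.02)
  expect_equal(med_of("Oz"), 0.15, tolerance = 0.02)
})

test_that("simulated frontal bursts map anterior, parietal bursts posterior", {
  lay <- default_layout()
  chans <- lay$name
  xy <- cbind(lay$x, lay$y)
  burst_rec <- function(peak) {
    pk <- which(chans == peak)
    w <- exp(-((xy[, 1] - xy[pk, 1])^2 + (xy[, 2] - xy[pk, 2])^2) / 0.25^2)
    t <- (0:511) / 256
    set.seed(53)
    S <- matrix(rnorm(length(chans) * 512, sd = 0.5), length(chans))
    S <- S + outer(w, 20 * sin(2 * pi * 13 * t) * sin(pi * t / 2)^2)
    eeg_recording(S, chans, 256, lay)
  }
  expect_gt(med_feature(burst_rec("Fz"), 256L)$med, 0.5)
  expect_lt(med_feature(burst_rec("Pz"), 256L)$med, 0.5)
})

test_that("degenerate windows raise an undefined-feature error", {
  rec <- eeg_recording(matrix(1, 2, 100), c("Cz", "Pz"), 256)
  expect_error(med_feature(rec, 50L), "constant window")
})

test_that("stage lookup uses half-open 20 s epochs", {
  h <- hypnogram(c(2, 5), epoch_length = 20)
  expect_equal(stage_feature(h, 25), 5L)
  expect_equal(stage_feature(h, 0), 2L)
  expect_equal(stage_feature(h, 19.999), 2L)
  expect_equal(stage_feature(h, 20), 5L)
  expect_error(stage_feature(h, 40), "span")
})

test_that("expert flag honors closed windows on Fz/Cz/Pz only", {
  ann <- annotation_set("Cz", 10, 1)
  expect_equal(expert_feature(ann, 10.5), 1L)
  expect_equal(expert_feature(ann, c(10, 11)), c(1L, 1L))  # closed ends
  expect_equal(expert_feature(ann, 11.5), 0L)
  expect_equal(expert_feature(annotation_set("O1", 10, 1), 10.5), 0L)
  expect_equal(expert_feature(NULL, 10.5), 0L)
})
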