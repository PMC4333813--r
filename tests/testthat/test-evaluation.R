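test_that("confusion counts tally the four conjunctions and conserve events", {
  cc <- confusion_counts(c(1, 0), c(1, 0))
  expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), c(1, 1, 0, 0))
  expect_equal(confusion_counts(1, 0)$FP, 1)

  set.seed(101)
  for (rep in 1:10) {
    s <- rbinom(100, 1, 0.3)
    e <- rbinom(100, 1, 0.1)
    cc <- confusion_counts(s, e)
    expect_equal(cc$TP, sum(s == 1 & e == 1))
    expect_equal(cc$TN, sum(s == 0 & e == 0))
    expect_equal(cc$FP, sum(s == 1 & e == 0))
    expect_equal(cc$FN, sum(s == 0 & e == 1))
    expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 100)
  }
  expect_error(confusion_counts(c(1, NA), c(0, 0)), "non-NA")
})

test_that("metrics match independently coded formulas", {
  m <- detection_metrics(list(TP = 1, TN = 1, FP = 1, FN = 1))
  expect_equal(m$MCC, 0)

  m2 <- detection_metrics(list(TP = 7, TN = 0, FP = 93, FN = 0))
  expect_equal(m2$FDr, 93)

  m3 <- detection_metrics(list(TP = 10, TN = 50, FP = 0, FN = 0))
  expect_equal(m3$Se, 100)
  expect_equal(m3$Sp, 100)
  expect_equal(m3$MCC, 1)
  expect_equal(m3$F1, 1)
  expect_equal(m3$kappa, 1)

  set.seed(103)
  for (rep in 1:25) {
    tp <- sample(1:200, 1); tn <- sample(1:200, 1)
    fp <- sample(1:200, 1); fn <- sample(1:200, 1)
    got <- detection_metrics(list(TP = tp, TN = tn, FP = fp, FN = fn))
    want <- oracle_metrics(tp, tn, fp, fn)
    for (k in names(want))
      expect_equal(got[[k]], want[[k]], tolerance = 1e-12)
    # identities
    expect_equal(got$FPr + got$Sp, 100, tolerance = 1e-12)
    precision <- 100 * tp / (tp + fp)
    expect_equal(got$FDr + precision, 100, tolerance = 1e-12)
  }
})

test_that("undefined metrics are reported as NA, not zero", {
  m <- detection_metrics(list(TP = 0, TN = 10, FP = 0, FN = 0))
  expect_true(is.na(m$Se))
  expect_true(is.na(m$FDr))
  expect_true(all(is.na(unlist(detection_metrics(list(TP = 0, TN = 0, FP = 0,
                                                      FN = 0))))))
})

test_that("p-value sweep is monotone in Se and finds the Se = Sp crossing", {
  set.seed(107)
  n <- 2000
  expert <- rbinom(n, 1, 0.05)
  # expert events have shifted features so Se rises with alpha
  amp <- rlnorm(n) * ifelse(expert == 1, 3, 1)
  sigma <- rlnorm(n) * ifelse(expert == 1, 3, 1)
  ev <- data.frame(amp = amp, sigma = sigma, stage = 2L, expert = expert)
  nullev <- data.frame(amp = rlnorm(1000), sigma = rlnorm(1000), stage = 5L,
                       expert = 0L)
  nm <- build_null(rbind(ev, nullev))
  alphas <- c(0.9, 0.5, 0.3, 0.2, 0.1, 0.05, 0.02, 0.01)
  sw <- pvalue_sweep(rbind(ev, nullev), nm, alphas)
  expect_equal(nrow(sw$table), length(alphas))
  expect_true(all(diff(sw$table$Se) <= 1e-9))      # Se non-increasing
  expect_gt(sw$table$Se[1], 95)                    # alpha near 1: almost all selected
  # crossing agrees with a dense grid search
  dense <- pvalue_sweep(rbind(ev, nullev), nm,
                        seq(0.9, 0.01, by = -0.002))
  expect_equal(sw$crossing$value, dense$crossing$value, tolerance = 2)
  expect_equal(sw$crossing$alpha, dense$crossing$alpha, tolerance = 0.05)
  expect_error(pvalue_sweep(ev, nm, c(0.1, 0.5)), "descending")
})

test_that("sleep cycles follow the NREM-then-REM rule with a 15 min REM gap", {
  h <- hypnogram(c(rep(2, 45), rep(5, 15), rep(2, 45), rep(5, 15)), 20)
  cyc <- sleep_cycles(h)
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$nrem_start_epoch, c(1, 61))
  expect_equal(cyc$rem_start_epoch, c(46, 106))
  expect_equal(cyc$end_epoch, c(60, 120))

  # REM runs separated by 10 min: one cycle
  h10 <- hypnogram(c(rep(2, 30), rep(5, 5), rep(2, 30), rep(5, 5), rep(2, 50)), 20)
  expect_equal(nrow(sleep_cycles(h10)), 1)
  expect_equal(sleep_cycles(h10)$end_epoch, 70)

  # separated by 20 min: two cycles
  h20 <- hypnogram(c(rep(2, 30), rep(5, 5), rep(2, 60), rep(5, 5), rep(2, 10)), 20)
  expect_equal(nrow(sleep_cycles(h20)), 2)

  expect_equal(nrow(sleep_cycles(hypnogram(rep(0, 10)))), 0)
})

test_that("per-cycle proportions are normalized per class", {
  h <- hypnogram(rep(c(rep(2, 45), rep(5, 15)), 4), 20)
  cyc <- sleep_cycles(h)
  expect_equal(nrow(cyc), 4)
  # all events of class "a" in cycle 1
  t_a <- c(100, 200, 300)
  t_b <- c(100, 1300, 2500, 3700)
  p <- per_cycle_distribution(c(t_a, t_b), cyc, rep(c("a", "b"), c(3, 4)), h)
  expect_equal(unname(p["a", ]), c(1, 0, 0, 0))
  expect_equal(unname(p["b", ]), rep(0.25, 4))
  expect_equal(unname(rowSums(p)), c(1, 1))
  expect_warning(per_cycle_distribution(t_a, cyc[1:2, ], rep("a", 3), h),
                 "2 cycles")
})
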