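two_groups <- function(n1 = 10, n2 = 10, seed = 71) {
  set.seed(seed)
  rbind(cbind(runif(n1, 0.05, 0.15), runif(n1, 0.05, 0.15)),
        cbind(runif(n2, 0.75, 0.85), runif(n2, 0.75, 0.85)))
}

test_that("AHC merges match a brute-force average-linkage oracle", {
  pts <- matrix(c(0, 0, 1, 1), 2, byrow = TRUE)
  dd <- ahc(pts)
  expect_equal(dd$hclust$height, sqrt(2))

  set.seed(73)
  pairs <- rbind(cbind(runif(2, 0, .01), runif(2, 0, .01)),
                 cbind(runif(2, .99, 1), runif(2, .99, 1)))
  h <- ahc(pairs)$hclust
  expect_lt(h$height[2], 0.1)        # both tight pairs merge first
  expect_gt(h$height[3], 1)

  for (rep in 1:100) {
    n <- sample(3:10, 1)
    pts <- cbind(runif(n), runif(n))
    expect_equal(ahc(pts)$hclust$height,
                 oracle_average_linkage_heights(pts), tolerance = 1e-10)
  }
  expect_error(ahc(matrix(0.5, 1, 2)), "at least 2")
})

test_that("the ratio cut stops at the coarsest partition satisfying r", {
  part <- cut_rratio(ahc(two_groups(10, 10)), r = 0.6)
  expect_equal(part$n_classes, 2)
  expect_equal(sort(part$class_sizes), c(10, 10))

  part2 <- cut_rratio(ahc(two_groups(12, 8)), r = 0.6)   # 8/12 = 0.67
  expect_equal(part2$n_classes, 2)

  part3 <- cut_rratio(ahc(two_groups(18, 2)), r = 0.6)   # 2/18 < 0.6
  expect_gt(part3$n_classes, 2)

  # r -> 0 accepts the first split on any dendrogram
  set.seed(79)
  for (rep in 1:5) {
    pts <- cbind(runif(12), runif(12))
    expect_equal(cut_rratio(ahc(pts), r = 1e-9)$n_classes, 2)
  }
  expect_error(cut_rratio(ahc(two_groups()), r = 0), "r must")
})

test_that("class selection keeps the smallest prefix reaching coverage", {
  fake_part <- function(labels) {
    k <- max(labels)
    structure(list(labels = labels, n_classes = k,
                   class_sizes = tabulate(labels, k), r = 0.6),
              class = "spindle_partition")
  }
  p <- fake_part(rep(1:2, c(100, 100)))
  ex <- c(rep(1, 90), rep(0, 10), rep(1, 10), rep(0, 90))
  s <- select_classes(p, ex, coverage = 0.8)
  expect_equal(s$kept, 1)
  expect_equal(s$coverage, 0.9)

  p3 <- fake_part(rep(1:3, c(60, 50, 20)))
  ex3 <- c(rep(1, 50), rep(0, 10), rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 10))
  s3 <- select_classes(p3, ex3, coverage = 0.8)
  expect_equal(s3$kept, c(1, 2))
  expect_equal(s3$coverage, 0.9)

  # exactly-at-coverage counts ("at least 80%")
  p2 <- fake_part(rep(1:2, c(100, 100)))
  ex2 <- c(rep(1, 80), rep(0, 20), rep(1, 20), rep(0, 80))
  expect_equal(select_classes(p2, ex2, coverage = 0.8)$kept, 1)

  # minimality: dropping the last kept class would fall below coverage
  set.seed(83)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    labels <- sample(seq_len(k), 120, replace = TRUE)
    ex <- rbinom(120, 1, 0.3)
    if (sum(ex) == 0) ex[1] <- 1
    s <- select_classes(fake_part(labels), ex, coverage = 0.8)
    expect_gte(s$coverage, 0.8)
    if (s$n_class > 1) {
      kept_but_last <- s$kept[-s$n_class]
      cov <- sum(ex[labels %in% kept_but_last]) / sum(ex)
      expect_lt(cov, 0.8)
    }
  }
  expect_error(select_classes(fake_part(rep(1:2, 5)), rep(0, 10)),
               "no expert events")
})

test_that("partial-scoring bootstrap is reproducible and exact at full scoring", {
  pts <- two_groups(25, 20, seed = 89)
  part <- cut_rratio(ahc(pts), 0.6)
  expert <- c(rbinom(25, 1, 0.8), rbinom(20, 1, 0.05))
  if (sum(expert[1:25]) == 0) expert[1] <- 1
  events <- data.frame(expert = c(expert, rep(0, 30)),
                       clustered = c(rep(TRUE, 45), rep(FALSE, 30)))
  n_exp <- sum(expert)

  full <- subsample_expert(events, part, n_scored = n_exp, reps = 3, seed = 7)
  expect_equal(full$dSe_mean, 0)
  expect_equal(full$dSp_mean, 0)

  a <- subsample_expert(events, part, n_scored = c(1, 2), reps = 5, seed = 11)
  b <- subsample_expert(events, part, n_scored = c(1, 2), reps = 5, seed = 11)
  expect_identical(a, b)
  expect_error(subsample_expert(events, part, n_scored = n_exp + 1, reps = 1),
               "exceeds")
})

test_that("partial-scoring differentials shrink with more scored events", {
  set.seed(97)
  pts <- rbind(cbind(runif(60, 0.0, 0.2), runif(60, 0.0, 0.2)),
               cbind(runif(60, 0.7, 0.9), runif(60, 0.7, 0.9)))
  part <- cut_rratio(ahc(pts), 0.6)
  expert <- c(rbinom(60, 1, 0.7), rbinom(60, 1, 0.1))
  events <- data.frame(expert = expert, clustered = rep(TRUE, 120))
  tab <- subsample_expert(events, part, n_scored = c(1, 8, 32), reps = 60,
                          seed = 13)
  dev <- abs(tab$dSe_mean) + abs(tab$dSp_mean)
  expect_lte(dev[3], dev[1])
})
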