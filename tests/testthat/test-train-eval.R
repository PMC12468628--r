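test_that("fold splitting is a deterministic near-equal partition", {
  ids <- sprintf("bm_%03d", 1:463)
  f1 <- splitFolds(ids, 10L, seed = 7)
  f2 <- splitFolds(ids, 10L, seed = 7)
  expect_identical(f1, f2)
  sizes <- as.vector(table(f1))
  expect_true(all(sizes %in% c(46L, 47L)))
  expect_equal(sum(sizes), 463L)
  expect_setequal(names(f1), ids)
  # partition property holds across seeds
  for (seed in 1:5) {
    f <- splitFolds(ids, 10L, seed)
    expect_equal(sort(unique(f)), 1:10)
    expect_equal(length(f), 463L)
  }
  # degenerate single fold
  expect_true(all(splitFolds(ids, 1L, 1) == 1L))
  expect_error(splitFolds(ids[1:5], 10L, 1), "fewer lesions")
})

test_that("the learning-rate schedule follows its closed form", {
  cfg <- trainConfig()
  expect_equal(learningRateAt(cfg, 0), 0.001)
  expect_equal(learningRateAt(cfg, 199), 0.001)
  expect_equal(learningRateAt(cfg, 400), 0.001 * 0.93^2)
  expect_equal(learningRateAt(cfg, 12345), 0.001 * 0.93^(12345 %/% 200))
  cfg2 <- trainConfig(lr_initial = 0.01, lr_decay_factor = 0.5,
                      lr_decay_every = 10L)
  expect_equal(learningRateAt(cfg2, 35), 0.01 * 0.5^3)
})

test_that("perfect predictions give zero errors and unit Dice", {
  spec <- smallPhantomSpec(seed = 31, n = 4)
  spaces <- extractCohortSpaces(generateCohort(spec))
  preds <- setNames(lapply(spaces, function(s) s@dose_norm),
                    vapply(spaces, function(s) s@lesion_id, character(1)))
  rec <- evaluatePredictions(preds, spaces)
  expect_true(all(rec$error == 0))
  expect_true(all(rec$abs_error == 0))
  expect_true(all(rec$dsc_100 == 1 & rec$dsc_50 == 1))
  expect_true(all(rec$abs_error == abs(rec$error)))
  tab <- maeTable(rec)
  expect_true(all(tab$mae == 0))
})

test_that("signed errors follow the predicted-minus-truth convention", {
  # a prediction covering 99.39% against a 100% truth must report a
  # coverage error of -0.61 percentage points
  edge <- 12L
  tum <- array(FALSE, rep(edge, 3))
  tum[3:8, 3:8, 3:8] <- TRUE # 216 voxels
  truth <- array(0, rep(edge, 3)); truth[tum] <- 1.0
  pred <- truth
  miss <- which(tum)[1:round(0.0061 * sum(tum))]
  pred[miss] <- 0.99
  sp <- tumorSpace("bm1", ifelse(tum, 2L, 0L) * 1L, truth, 16)
  rec <- evaluatePredictions(list(bm1 = pred), list(sp))
  cov <- rec[rec$metric == "coverage", ]
  expect_equal(cov$error, -100 * length(miss) / sum(tum))
  expect_equal(round(cov$error, 2), -0.46) # 1/216 granularity fixture
  expect_equal(cov$abs_error, abs(cov$error))
})

test_that("box statistics match a direct sort-based computation", {
  x <- c(5, 1, 4, 2, 100)
  b <- boxStats(x)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(b$median, q[2])
  expect_equal(b$mean, mean(x))
  expect_equal(b$q1, q[1])
  expect_equal(b$q3, q[3])
  iqr <- q[3] - q[1]
  inside <- x[x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr]
  expect_equal(b$whisker_low, min(inside))
  expect_equal(b$whisker_high, max(inside))
  expect_equal(b$outliers, 100)
  set.seed(8)
  y <- rnorm(101)
  b2 <- boxStats(y)
  expect_true(b2$whisker_low >= b2$q1 - 1.5 * (b2$q3 - b2$q1) - 1e-12)
  expect_true(all(b2$outliers < b2$whisker_low |
                    b2$outliers > b2$whisker_high))
})

test_that("exact Wilcoxon matches brute-force sign enumeration", {
  # all-positive n = 6, one-sided: p = 1 / 2^6
  d <- c(0.3, 0.1, 0.5, 0.2, 0.4, 0.6)
  r <- pairedWilcoxon(d, rep(0, 6), alternative = "greater")
  expect_equal(r$p.value, 1 / 64)
  expect_equal(r$method, "exact")
  # identical vectors: p = 1 with warning
  expect_warning(r0 <- pairedWilcoxon(1:5, 1:5), "zero")
  expect_equal(r0$p.value, 1.0)
  # symmetric +/- pairs: high two-sided p
  d2 <- c(0.2, -0.2, 0.35, -0.35, 0.5, -0.5)
  r2 <- pairedWilcoxon(d2, rep(0, 6))
  expect_gt(r2$p.value, 0.5)

  # exhaustive enumeration oracle for random fixtures, n <= 10
  enumP <- function(d, alternative) {
    d <- d[d != 0]
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    n <- length(d)
    signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    ws <- signs %*% r
    switch(alternative,
           greater = mean(ws >= w_obs),
           less = mean(ws <= w_obs),
           two.sided = min(1, 2 * min(mean(ws >= w_obs),
                                      mean(ws <= w_obs))))
  }
  set.seed(10)
  for (rep in 1:8) {
    n <- sample(4:10, 1)
    a <- round(rnorm(n), 1)
    b <- round(rnorm(n), 1) # rounding induces ties and zeros
    for (alt in c("two.sided", "greater", "less")) {
      got <- suppressWarnings(pairedWilcoxon(a, b, alt))
      if (got$n == 0) next
      expect_equal(got$p.value, enumP(a - b, alt), tolerance = 1e-12)
    }
  }
})

test_that("exact Wilcoxon agrees with the reference implementation", {
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(6:20, 1)
    a <- rnorm(n)
    b <- rnorm(n) # continuous: no ties, wilcox.test can be exact
    for (alt in c("two.sided", "greater", "less")) {
      ours <- pairedWilcoxon(a, b, alt)
      ref <- wilcox.test(a, b, paired = TRUE, alternative = alt,
                         exact = TRUE)
      expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-12)
    }
  }
  # large-n path: normal approximation with tie correction
  set.seed(12)
  a <- round(rnorm(60), 1)
  b <- round(rnorm(60), 1)
  ours <- suppressWarnings(pairedWilcoxon(a, b, "two.sided"))
  ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                      correct = TRUE))
  expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-9)
})

test_that("method comparison battery aligns records and reports groups", {
  spec <- smallPhantomSpec(seed = 41, n = 5)
  spaces <- extractCohortSpaces(generateCohort(spec))
  truth <- setNames(lapply(spaces, function(s) s@dose_norm),
                    vapply(spaces, function(s) s@lesion_id, character(1)))
  noisy <- lapply(truth, function(d) d * 0.97)
  rec_a <- evaluatePredictions(noisy, spaces)
  rec_b <- evaluatePredictions(truth, spaces)
  cmp <- suppressWarnings(compareMethods(rec_b, rec_a))
  expect_true(all(c("p_signed_two_sided", "p_abs_one_sided") %in%
                    names(cmp)))
  expect_true(all(cmp$p_signed_two_sided >= 0 &
                    cmp$p_signed_two_sided <= 1))
})
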