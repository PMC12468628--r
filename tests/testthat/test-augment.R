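test_that("p_augment = 0 is the identity for all seeds", {
  sp <- gaussianSpace(edge = 16, sigma_mm = 1.5, peak = 1.4)
  pol <- augmentPolicy(p_augment = 0)
  for (seed in 1:5) {
    out <- withr::with_seed(seed, augmentPair(sp@input_mask, sp@dose_norm,
                                              pol))
    expect_identical(out$mask, sp@input_mask)
    expect_identical(out$dose, sp@dose_norm)
    expect_equal(out$transform$kind, "none")
  }
})

test_that("grid rotations compose and invert exactly", {
  set.seed(9)
  v <- array(runif(16^3), c(16, 16, 16))
  expect_identical(rotateVolumeZ(rotateVolumeZ(v, 180), 180), v)
  expect_equal(rotateVolumeZ(rotateVolumeZ(v, 90), 270), v)
  r4 <- v
  for (i in 1:4) r4 <- rotateVolumeZ(r4, 90)
  expect_equal(r4, v)
  expect_identical(flipLR(flipLR(v)), v)
})

test_that("empirical transform frequencies match the augmentation policy", {
  pol <- augmentPolicy(translation_max_voxels = 1L)
  edge <- 8L
  mask <- array(0L, rep(edge, 3)); mask[4:5, 4:5, 4:5] <- 2L
  dose <- array(0.2, rep(edge, 3)); dose[4:5, 4:5, 4:5] <- 1.2
  n <- 10000L
  kinds <- character(n); flips <- logical(n)
  withr::with_seed(2024, {
    for (i in seq_len(n)) {
      out <- augmentPair(mask, dose, pol)
      kinds[i] <- out$transform$kind
      flips[i] <- isTRUE(out$transform$flip)
    }
  })
  se <- function(p) sqrt(p * (1 - p) / n)
  # untouched 25%, translate 37.5%, rotate 37.5%
  expect_lt(abs(mean(kinds == "none") - 0.25), 3 * se(0.25))
  expect_lt(abs(mean(kinds == "translate") - 0.375), 3 * se(0.375))
  expect_lt(abs(mean(kinds == "rotate") - 0.375), 3 * se(0.375))
  # flip in 50% of augmented samples, never in untouched ones
  aug <- kinds != "none"
  expect_lt(abs(mean(flips[aug]) - 0.5), 3 * sqrt(0.25 / sum(aug)))
  expect_true(all(!flips[!aug]))
})

test_that("grid isometries leave plan metrics exactly unchanged", {
  sp <- gaussianSpace(edge = 24, sigma_mm = 2, peak = 1.5)
  m0 <- planMetrics(sp@dose_norm, sp@input_mask == 2L, 0.125)
  for (tf in list(function(v, nn) rotateVolumeZ(v, 90, if (nn) "nearest"
                                                else "trilinear"),
                  function(v, nn) rotateVolumeZ(v, 180, if (nn) "nearest"
                                                else "trilinear"),
                  function(v, nn) flipLR(v),
                  function(v, nn) translateVolume(v, c(2, -1, 3)))) {
    d2 <- tf(sp@dose_norm, FALSE)
    m2 <- tf(sp@input_mask, TRUE)
    mm <- planMetrics(d2, m2 == 2L, 0.125)
    expect_same_metrics(m0, mm)
  }
})

test_that("45-degree rotations perturb metrics of mid-size lesions < 2%", {
  # group-2-sized lesion (> 33.5 mm^3)
  sp <- gaussianSpace(edge = 32, sigma_mm = 3, peak = 1.5)
  expect_gte(sum(sp@input_mask == 2L) * 0.125, 33.5)
  m0 <- planMetrics(sp@dose_norm, sp@input_mask == 2L, 0.125)
  for (ang in c(45, 135, 225, 315)) {
    d2 <- rotateVolumeZ(sp@dose_norm, ang, "trilinear")
    m2 <- rotateVolumeZ(sp@input_mask, ang, "nearest")
    mm <- planMetrics(d2, m2 == 2L, 0.125)
    expect_lt(abs(mm@coverage - m0@coverage) / m0@coverage, 0.02)
    expect_lt(abs(mm@selectivity - m0@selectivity) / m0@selectivity, 0.02)
    expect_lt(abs(mm@gi - m0@gi) / m0@gi, 0.02)
    expect_lt(abs(mm@ci50 - m0@ci50) / m0@ci50, 0.02)
  }
})

test_that("mask and dose always receive the same transform", {
  pol <- augmentPolicy(translation_max_voxels = 2L)
  sp <- gaussianSpace(edge = 16, sigma_mm = 1.5, peak = 1.4)
  for (seed in 1:20) {
    out <- withr::with_seed(seed,
                            augmentPair(sp@input_mask, sp@dose_norm, pol))
    # replay the recorded transform on each volume independently
    replay <- function(v, nn) {
      tf <- out$transform
      if (tf$kind == "translate") v <- translateVolume(v, tf$shift)
      if (tf$kind == "rotate")
        v <- rotateVolumeZ(v, tf$angle, if (nn) "nearest" else "trilinear")
      if (isTRUE(tf$flip)) v <- flipLR(v)
      v
    }
    m2 <- replay(sp@input_mask, TRUE)
    storage.mode(m2) <- "integer"
    expect_identical(out$mask, m2)
    expect_equal(out$dose, replay(sp@dose_norm, FALSE))
  }
})

test_that("tumor voxels are conserved under augmentation", {
  pol <- augmentPolicy(translation_max_voxels = 4L)
  sp <- gaussianSpace(edge = 16, sigma_mm = 1.5, peak = 1.4)
  n_tum <- sum(sp@input_mask == 2L)
  for (seed in 1:20) {
    out <- withr::with_seed(seed,
                            augmentPair(sp@input_mask, sp@dose_norm, pol))
    if (out$transform$kind != "rotate" ||
        out$transform$angle %% 90 == 0)
      expect_identical(sum(out$mask == 2L), n_tum)
  }
})
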