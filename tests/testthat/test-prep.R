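test_that("normalization identity and 30% zeroing hold exactly", {
  sp <- gaussianSpace(edge = 32, sigma_mm = 2, peak = 1.6)
  rx <- 16
  dose_gy <- sp@dose_norm * rx
  tum <- sp@input_mask == 2L
  ts <- extractTumorSpace(dose_gy, tum, array(FALSE, dim(tum)),
                          rx_gy = rx, window = 32L)
  # max(dose_norm) * Rx == max(dose) exactly (peak is above 0.3 Rx)
  expect_identical(max(ts@dose_norm) * rx, max(dose_gy))
  # nothing below the 30% level survives; everything at/above does
  kept <- ts@dose_norm[ts@dose_norm > 0]
  expect_true(all(kept >= 0.3))
  expect_equal(sum(ts@dose_norm >= 0.3), sum(dose_gy >= 0.3 * rx))
})

test_that("all-subthreshold dose gives a zero space with a warning", {
  edge <- 16L
  tum <- array(FALSE, rep(edge, 3)); tum[8:9, 8:9, 8:9] <- TRUE
  dose <- array(0.1, rep(edge, 3)) # far below 0.3 * Rx = 4.8 Gy
  expect_warning(
    ts <- extractTumorSpace(dose, tum, array(FALSE, rep(edge, 3)),
                            rx_gy = 16, window = 16L),
    "below the tumor-space threshold")
  expect_true(all(ts@dose_norm == 0))
})

test_that("the retained 30% region of a Gaussian matches the closed form", {
  spacing <- 0.5
  sigma <- 2
  rx <- 16
  dose <- gaussianShotDose(rep(64L, 3), spacing, rep(32.5, 3), sigma,
                           2 * rx) # peak 2 Rx
  tum <- dose >= rx
  ts <- extractTumorSpace(dose, tum, array(FALSE, dim(dose)), rx_gy = rx,
                          window = 64L)
  r <- sigma * sqrt(2 * log(2 / 0.3))
  analytic <- 4 / 3 * pi * r^3
  counted <- sum(ts@dose_norm > 0) * spacing^3
  expect_lt(abs(counted - analytic) / analytic, 0.05)
})

test_that("input mask codes and truncation contract", {
  edge <- 24L
  tum <- array(FALSE, rep(edge, 3)); tum[10:14, 10:14, 10:14] <- TRUE
  skull <- array(FALSE, rep(edge, 3)); skull[1:2, , ] <- TRUE
  m <- buildInputMask(tum, skull, window = 16L)
  expect_true(all(m %in% c(0L, 1L, 2L)))
  expect_equal(sum(m == 2L), sum(tum))
  # deep window without skull: codes {0, 2} only
  m2 <- buildInputMask(tum, array(FALSE, rep(edge, 3)), window = 16L)
  expect_true(all(m2 %in% c(0L, 2L)))
  # superficial lesion abutting skull: code-1 voxels present
  skull2 <- array(FALSE, rep(edge, 3)); skull2[8, , ] <- TRUE
  m3 <- buildInputMask(tum, skull2, window = 16L)
  expect_gt(sum(m3 == 1L), 0)
  # overlap resolves to tumor
  skull3 <- skull2; skull3[10:14, 10:14, 10:14] <- TRUE
  m4 <- buildInputMask(tum, skull3, window = 16L)
  expect_equal(sum(m4 == 2L), sum(tum))
  # window past the grid edge: out-of-grid voxels are code 0
  tum_edge <- array(FALSE, rep(edge, 3)); tum_edge[1:3, 1:3, 1:3] <- TRUE
  m5 <- buildInputMask(tum_edge, skull, window = 16L)
  expect_equal(dim(m5), rep(16L, 3))
  expect_true(all(m5[1:4, , ] %in% 0:2)) # simply defined, zero-padded
})

test_that("the input mask is independent of the dose", {
  # mask channel must be constructible from geometry alone: the mask from
  # extractTumorSpace equals buildInputMask on the same window
  sp_fix <- gaussianSpace(edge = 32, sigma_mm = 2, peak = 1.5)
  tum <- sp_fix@input_mask == 2L
  skull <- array(FALSE, dim(tum)); skull[1, , ] <- TRUE
  rx <- 16
  ts <- extractTumorSpace(sp_fix@dose_norm * rx, tum, skull, rx_gy = rx,
                          window = 32L)
  expect_identical(ts@input_mask, buildInputMask(tum, skull, window = 32L))
})

test_that("clipping the tumor space window raises a counted warning", {
  spacing <- 0.5
  dose <- gaussianShotDose(rep(48L, 3), spacing, rep(24.5, 3), 3, 32)
  tum <- dose >= 16
  expect_warning(
    extractTumorSpace(dose, tum, array(FALSE, dim(dose)), rx_gy = 16,
                      window = 16L),
    "clipped.*voxels lost")
})

test_that("metrics survive the extraction round trip", {
  spec <- smallPhantomSpec(seed = 21, n = 3)
  cases <- generateCohort(spec)
  spaces <- extractCohortSpaces(cases)
  for (i in seq_along(cases)) {
    m0 <- cases[[i]]@true_metrics
    m1 <- planMetrics(spaces[[i]]@dose_norm, spaces[[i]]@input_mask == 2L,
                      0.125)
    expect_same_metrics(m0, m1)
    expect_gte(max(spaces[[i]]@dose_norm), 1.0) # peak >= Rx given coverage
  }
})

test_that("near-OAR exclusion implements the two-condition rule", {
  rules <- data.frame(organ_name = c("optical_pathway", "brainstem"),
                      tolerance_gy = c(8, 12),
                      endpoint_kind = c("D2cc", "Dmax"))
  # (a) fails: organ outside the tumor space, endpoint high
  r <- filterNearOAR(c(optical_pathway = FALSE),
                     c(optical_pathway = 0.9 * 8), rules)
  expect_true(r$keep)
  # both conditions hold -> exclude
  r <- filterNearOAR(c(optical_pathway = TRUE),
                     c(optical_pathway = 0.6 * 8), rules)
  expect_false(r$keep)
  # (b) fails: organ inside but endpoint at 40% of tolerance
  r <- filterNearOAR(c(optical_pathway = TRUE),
                     c(optical_pathway = 0.4 * 8), rules)
  expect_true(r$keep)
  # brainstem exception retains the case
  r <- filterNearOAR(c(brainstem = TRUE), c(brainstem = 11), rules,
                     brainstem_exception = TRUE)
  expect_true(r$keep)
  r <- filterNearOAR(c(brainstem = TRUE), c(brainstem = 11), rules)
  expect_false(r$keep)
  # missing endpoint: conservative exclusion
  expect_message(r <- filterNearOAR(c(optical_pathway = TRUE),
                                    c(other = 1), rules), "conservatively")
  expect_false(r$keep)
})

test_that("adjacency flags overlap of prescription and half-Rx regions", {
  gs <- c(64L, 16L, 16L)
  mk <- function(cx, sigma, peak)
    gaussianShotDose(gs, 0.5, c(cx, 8.5, 8.5), sigma, peak)
  rx <- 16
  # two lesions far apart with 2 mm kernels: independent
  a <- mk(10, 2, 1.2 * rx); b <- mk(54, 2, 1.2 * rx)
  expect_false(filterAdjacent(a, b, rx, rx)$adjacent)
  # identical co-located doses: ambiguous
  expect_true(filterAdjacent(a, a, rx, rx)$adjacent)
  # two 8 mm shots 6 mm apart with peak Rx: brute-force voxel check
  sig <- GKDosePredict:::fwhmToSigma(8)
  a2 <- mk(26, sig, rx); b2 <- mk(38, sig, rx)
  f <- filterAdjacent(a2, b2, rx, rx)
  expect_identical(f$piv_overlap, any(a2 >= rx & b2 >= rx))
  expect_identical(f$piv50_overlap,
                   any(a2 >= rx / 2 & b2 >= rx / 2))
  expect_identical(f$adjacent, f$piv_overlap || f$piv50_overlap)
})

test_that("the shipped tolerance table carries the optical pathway entry", {
  tab <- oarToleranceTable()
  i <- match("optical_pathway", tab$organ_name)
  expect_false(is.na(i))
  expect_equal(tab$tolerance_gy[i], 8)
})
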