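# Shared fixtures, built in code at test time.

# independent brute-force plan-metric counter: explicit voxel loops, no
# vectorized set operations, used as the oracle for the metric engine
bruteForceMetrics <- function(dose_norm, tumor_mask, voxel_volume) {
  dims <- dim(dose_norm)
  n_tv <- 0L; n_piv <- 0L; n_piv50 <- 0L; n_int <- 0L
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
    for (i in seq_len(dims[1])) {
      d <- dose_norm[i, j, k]
      t <- tumor_mask[i, j, k] != 0
      if (t) n_tv <- n_tv + 1L
      if (d >= 1.0) {
        n_piv <- n_piv + 1L
        if (t) n_int <- n_int + 1L
      }
      if (d >= 0.5) n_piv50 <- n_piv50 + 1L
    }
  list(coverage = n_int / n_tv,
       selectivity = if (n_piv > 0) n_int / n_piv else NA_real_,
       gi = if (n_piv > 0) n_piv50 / n_piv else NA_real_,
       ci50 = n_piv50 / n_tv,
       tv_mm3 = n_tv * voxel_volume)
}

# small phantom spec for fast cohort tests (32^3 grid, group 1-2 lesions)
smallPhantomSpec <- function(seed = 11L, n = 10L)
  phantomSpec(seed = seed, n_lesions = n,
              volume_range_mm3 = c(14.875, 120),
              collimator_mm = c(4, 8), rx_menu_gy = c(18, 17, 16, 15, 14),
              grid_shape = 32L, depth_range_mm = c(3, 10))

# deterministic tumor space with a centred Gaussian dose; the tumor sits
# slightly inside the prescription isodose (margin < 1) so fixtures are
# not knife-edge degenerate
gaussianSpace <- function(edge = 32L, sigma_mm = 2, peak = 1.3,
                          spacing = 0.5, id = "fixture", margin = 0.85) {
  ctr <- rep((edge + 1) / 2, 3)
  dose <- gaussianShotDose(rep(edge, 3L), spacing, ctr, sigma_mm, peak)
  r_rx <- margin * sigma_mm * sqrt(2 * log(peak / 1.0))
  d2 <- array(0, rep(edge, 3L))
  ax <- ((seq_len(edge) - ctr[1]) * spacing)^2
  d2 <- outer(outer(ax, ax, "+"), ax, "+")
  mask <- array(0L, rep(edge, 3L))
  mask[d2 <= r_rx^2] <- 2L
  tumorSpace(id, mask, dose, rx_gy = 16, spacing_mm = spacing)
}

expect_same_metrics <- function(m1, m2, tol = 0) {
  expect_equal(m1@coverage, m2@coverage, tolerance = tol)
  expect_equal(m1@selectivity, m2@selectivity, tolerance = tol)
  expect_equal(m1@gi, m2@gi, tolerance = tol)
  expect_equal(m1@ci50, m2@ci50, tolerance = tol)
}
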