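# Synthetic Gamma-Knife-like lesion and dose generator. Each case lives on
# its own lesion-centred grid; doses are superpositions of isotropic
# Gaussian kernels whose FWHM equals the collimator diameter (times a
# configurable scale), with shot weights calibrated so that a chosen
# quantile of the in-target dose equals the prescription.

withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Draw lesion volumes from the phantom's log-uniform volume model
#'
#' @param spec a [PhantomSpec-class].
#' @param n number of draws (uses the current RNG state).
#' @return Numeric vector of volumes in mm^3 within the spec's range.
#' @export
sampleLesionVolumes <- function(spec, n) {
  lo <- spec@volume_range_mm3[1]
  hi <- spec@volume_range_mm3[2]
  exp(runif(n, log(lo), log(hi)))
}

# prescriptions biased so that larger lesions receive lower doses, the
# familiar clinical volume-dose trade-off
drawPrescription <- function(spec, volume_mm3) {
  menu <- sort(spec@rx_menu_gy, decreasing = TRUE)
  m <- length(menu)
  lo <- spec@volume_range_mm3[1]
  hi <- spec@volume_range_mm3[2]
  p <- if (hi > lo) log(volume_mm3 / lo) / log(hi / lo) else 0.5
  idx <- 1L + floor(p * m * 0.9999)
  idx <- idx + sample(c(-1L, 0L, 1L), 1L, prob = c(0.15, 0.7, 0.15))
  menu[min(max(idx, 1L), m)]
}

# squared distance of every voxel centre (mm) from a point, as an array
gridDist2 <- function(grid_shape, spacing_mm, center_mm) {
  ax <- (seq_len(grid_shape[1]) * spacing_mm - center_mm[1])^2
  ay <- (seq_len(grid_shape[2]) * spacing_mm - center_mm[2])^2
  az <- (seq_len(grid_shape[3]) * spacing_mm - center_mm[3])^2
  outer(outer(ax, ay, "+"), az, "+")
}

#' Sample one lesion geometry
#'
#' Rasterizes a randomly oriented ellipsoid (axis ratios drawn in
#' [0.6, 1], volume log-uniform over the spec's range) near the centre of
#' the case grid, places it at a random depth below the inner surface of a
#' spherical skull, and draws a prescription dose from the menu with larger
#' lesions biased toward lower prescriptions. Uses the caller's RNG state;
#' seed externally (or via [generateCohort()]) for reproducibility.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `tumor_mask`, `skull_mask` (logical arrays), `rx_gy`,
#'   `volume_mm3` (requested continuous volume), `depth_mm` and
#'   `semi_axes_mm`.
#' @export
sampleLesionGeometry <- function(spec) {
  gs <- spec@grid_shape
  sp <- spec@spacing_mm
  vol <- sampleLesionVolumes(spec, 1)
  r2 <- runif(1, 0.6, 1)
  r3 <- runif(1, 0.6, 1)
  a <- (3 * vol / (4 * pi * r2 * r3))^(1 / 3)
  semi <- c(a, a * r2, a * r3)
  # random proper rotation from a QR decomposition
  qrd <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]

  grid_center <- (gs + 1) / 2 * sp
  placed <- FALSE
  for (attempt in seq_len(100)) {
    center <- grid_center + runif(3, -1, 1) * sp
    margin <- max(semi) / sp + 1.5
    if (all(center / sp - margin >= 1) &&
        all(center / sp + margin <= gs)) { placed <- TRUE; break }
  }
  if (!placed) stop("lesion does not fit inside the case grid")

  # rasterize within the bounding box of the ellipsoid
  lo <- pmax(1L, floor(center / sp - max(semi) / sp - 1))
  hi <- pmin(gs, ceiling(center / sp + max(semi) / sp + 1))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  pts <- as.matrix(expand.grid(x = ix * sp - center[1],
                               y = iy * sp - center[2],
                               z = iz * sp - center[3]))
  local_coords <- pts %*% R
  q <- (local_coords[, 1] / semi[1])^2 + (local_coords[, 2] / semi[2])^2 +
    (local_coords[, 3] / semi[3])^2
  tumor <- array(FALSE, gs)
  tumor[ix, iy, iz] <- array(q <= 1, dim = c(length(ix), length(iy),
                                             length(iz)))
  if (!any(tumor)) { # sub-voxel lesion: keep at least the centre voxel
    cv <- pmin(pmax(round(center / sp), 1), gs)
    tumor[cv[1], cv[2], cv[3]] <- TRUE
  }

  # spherical skull at a sampled lesion depth below its inner surface
  Rin <- spec@skull_inner_radius_mm
  depth <- runif(1, spec@depth_range_mm[1], spec@depth_range_mm[2])
  depth <- max(depth, max(semi) + 1)
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  brain_center <- center - u * (Rin - depth)
  d2 <- gridDist2(gs, sp, brain_center)
  skull <- d2 >= Rin^2 & d2 <= (Rin + spec@skull_thickness_mm)^2
  skull[tumor] <- FALSE

  list(tumor_mask = tumor, skull_mask = skull,
       rx_gy = drawPrescription(spec, vol), volume_mm3 = vol,
       depth_mm = depth, semi_axes_mm = semi)
}

# integer offsets within a ball of given voxel radius
ballOffsets <- function(radius_vox) {
  r <- max(0L, floor(radius_vox))
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= radius_vox^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Dose of a single isotropic Gaussian shot
#'
#' `peak * exp(-r^2 / (2 sigma^2))` around a voxel centre, truncated at
#' 4.5 sigma. The v-level isodose of an isolated shot of peak P is the
#' sphere of radius `sigma * sqrt(2 * log(P / v))`, which the tests use as
#' a closed-form oracle for voxel-counted isodose volumes.
#'
#' @param grid_shape integer length-3 grid.
#' @param spacing_mm voxel spacing.
#' @param center_vox shot centre in (possibly fractional) voxel index.
#' @param sigma_mm Gaussian standard deviation in mm.
#' @param peak dose at the kernel peak (Gy).
#' @return 3D dose array.
#' @export
gaussianShotDose <- function(grid_shape, spacing_mm, center_vox, sigma_mm,
                             peak = 1) {
  dose <- array(0, grid_shape)
  rmax <- 4.5 * sigma_mm / spacing_mm
  lo <- pmax(1L, floor(center_vox - rmax))
  hi <- pmin(grid_shape, ceiling(center_vox + rmax))
  if (any(lo > hi)) return(dose)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  ax <- ((ix - center_vox[1]) * spacing_mm)^2
  ay <- ((iy - center_vox[2]) * spacing_mm)^2
  az <- ((iz - center_vox[3]) * spacing_mm)^2
  d2 <- outer(outer(ax, ay, "+"), az, "+")
  block <- peak * exp(-d2 / (2 * sigma_mm^2))
  block[d2 > (4.5 * sigma_mm)^2] <- 0
  dose[ix, iy, iz] <- block
  dose
}

#' Compose a shot-based dose distribution for a target
#'
#' Greedy largest-first packing: for each collimator size in descending
#' order, candidate isocentres are taken from a jittered grid of tumor
#' voxels where the full kernel half-maximum ball fits inside the target;
#' shots are added at the candidate covering the most still-uncovered
#' target voxels until no candidate adds a meaningful fraction of a
#' kernel. Every shot contributes an isotropic Gaussian with
#' FWHM = `kernel_fwhm_scale` x collimator diameter. A single global
#' weight factor is then calibrated so that the `coverage_target` quantile
#' of in-target dose equals the prescription. A target smaller than the
#' smallest kernel receives one centred smallest-collimator shot.
#'
#' @param tumor_mask logical 3D array (non-empty).
#' @param spec a [PhantomSpec-class].
#' @param rx_gy prescription dose in Gy.
#' @return list with `dose` (3D array, Gy) and `shots` (data.frame with
#'   voxel-index centres, collimator_mm, sigma_mm and weight columns).
#' @export
composeShotDose <- function(tumor_mask, spec, rx_gy) {
  if (!any(tumor_mask)) stop("empty tumor mask")
  gs <- dim(tumor_mask)
  sp <- spec@spacing_mm
  covered <- array(FALSE, gs)
  shots <- list()

  tum_idx <- which(tumor_mask)
  tum_arr <- which(tumor_mask, arr.ind = TRUE)

  for (diam in sort(spec@collimator_mm, decreasing = TRUE)) {
    fwhm <- spec@kernel_fwhm_scale * diam
    rfit <- fwhm / 2 / sp # voxel radius of the half-maximum ball
    offs <- ballOffsets(rfit)
    step <- max(1L, floor(rfit))
    jit <- c(sample.int(step, 1), sample.int(step, 1), sample.int(step, 1))
    on_grid <- (tum_arr[, 1] %% step == jit[1] %% step) &
      (tum_arr[, 2] %% step == jit[2] %% step) &
      (tum_arr[, 3] %% step == jit[3] %% step)
    cand <- tum_arr[on_grid, , drop = FALSE]
    if (nrow(cand) == 0) next
    # keep candidates whose half-maximum ball fits inside the target
    fits <- vapply(seq_len(nrow(cand)), function(i) {
      p <- sweep(offs, 2, cand[i, ], "+")
      if (any(p < 1) || any(p[, 1] > gs[1] | p[, 2] > gs[2] | p[, 3] > gs[3]))
        return(FALSE)
      all(tumor_mask[p])
    }, logical(1))
    cand <- cand[fits, , drop = FALSE]
    min_new <- max(1, 0.05 * nrow(offs))
    while (nrow(cand) > 0) {
      newcov <- vapply(seq_len(nrow(cand)), function(i) {
        p <- sweep(offs, 2, cand[i, ], "+")
        sum(tumor_mask[p] & !covered[p])
      }, numeric(1))
      best <- which.max(newcov)
      if (newcov[best] < min_new) break
      ctr <- cand[best, ]
      p <- sweep(offs, 2, ctr, "+")
      covered[p[tumor_mask[p], , drop = FALSE]] <- TRUE
      shots[[length(shots) + 1L]] <-
        data.frame(cx = ctr[1], cy = ctr[2], cz = ctr[3],
                   collimator_mm = diam, sigma_mm = fwhmToSigma(fwhm),
                   weight = 1)
    }
  }

  if (length(shots) == 0) { # target smaller than the smallest kernel
    diam <- min(spec@collimator_mm)
    ctr <- round(colMeans(tum_arr))
    shots[[1]] <- data.frame(cx = ctr[1], cy = ctr[2], cz = ctr[3],
                             collimator_mm = diam,
                             sigma_mm = fwhmToSigma(spec@kernel_fwhm_scale *
                                                    diam),
                             weight = 1)
  }
  shots <- do.call(rbind, shots)

  dose <- array(0, gs)
  for (i in seq_len(nrow(shots)))
    dose <- dose + gaussianShotDose(gs, sp,
                                    c(shots$cx[i], shots$cy[i],
                                      shots$cz[i]),
                                    shots$sigma_mm[i], shots$weight[i])
  q <- quantile(dose[tum_idx], probs = 1 - spec@coverage_target, type = 7,
                names = FALSE)
  if (q <= 0) q <- max(dose[tum_idx])
  scale <- rx_gy / q
  shots$weight <- shots$weight * scale
  list(dose = dose * scale, shots = shots)
}

#' Generate a seeded cohort of synthetic lesion cases
#'
#' Draws `spec@n_lesions` lesions with [sampleLesionGeometry()], composes
#' their doses with [composeShotDose()] and computes ground-truth metrics
#' with [planMetrics()]. Identical specs (including the seed) produce
#' bit-identical cohorts. A warning is raised if fewer than 90% of cases
#' reach 95% coverage, the envelope the generator is calibrated to emulate.
#'
#' @param spec a [PhantomSpec-class].
#' @return list of [LesionCase-class] objects (empty when `n_lesions` = 0).
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  if (spec@n_lesions == 0L) return(list())
  cases <- withLocalSeed(spec@seed, {
    lapply(seq_len(spec@n_lesions), function(i) {
      geo <- sampleLesionGeometry(spec)
      sd_ <- composeShotDose(geo$tumor_mask, spec, geo$rx_gy)
      m <- planMetrics(sd_$dose / geo$rx_gy, geo$tumor_mask,
                       voxelVolume(spec@spacing_mm))
      new("LesionCase", lesion_id = sprintf("case_%03d", i),
          rx_gy = geo$rx_gy, tumor_mask = geo$tumor_mask,
          skull_mask = geo$skull_mask,
          dose = doseGrid(sd_$dose, spec@spacing_mm),
          shots = sd_$shots, true_metrics = m)
    })
  })
  covs <- vapply(cases, function(cs) cs@true_metrics@coverage, numeric(1))
  if (mean(covs >= 0.95) < 0.9)
    warning(sprintf("only %.0f%% of cases reach 95%% coverage",
                    100 * mean(covs >= 0.95)))
  cases
}

#' Summary statistics of a cohort
#'
#' @param cases list of [LesionCase-class].
#' @return data.frame of ranges per metric plus the coverage >= 95% share.
#' @export
cohortSummary <- function(cases) {
  tab <- planMetricsTable(cases)
  data.frame(
    metric = c("tv_mm3", "coverage_pct", "selectivity", "gi", "ci50"),
    min = vapply(tab[c("tv_mm3", "coverage_pct", "selectivity", "gi",
                       "ci50")], min, numeric(1), na.rm = TRUE),
    max = vapply(tab[c("tv_mm3", "coverage_pct", "selectivity", "gi",
                       "ci50")], max, numeric(1), na.rm = TRUE),
    frac_cov_ge_95 = mean(tab$coverage_pct >= 95),
    row.names = NULL)
}
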