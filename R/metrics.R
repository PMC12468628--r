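#' Isodose volume at a given dose level
#'
#' Selects all voxels receiving at least `level` (inclusive threshold,
#' matching the clinical "receiving at least" convention) on the
#' fraction-of-Rx scale and converts the count to a volume.
#'
#' @param dose_norm non-negative 3D array, dose as fraction of Rx.
#' @param level threshold as fraction of Rx (> 0); 1.0 gives PIV, 0.5 gives
#'   PIV_0.5Rx.
#' @param voxel_volume_mm3 volume of one voxel in mm^3.
#' @return list with `volume_mm3` and the logical selection `mask`.
#' @export
isodoseVolume <- function(dose_norm, level, voxel_volume_mm3 = 0.5^3) {
  stopifnot(level > 0, all(dose_norm >= 0))
  mask <- dose_norm >= level
  list(volume_mm3 = sum(mask) * voxel_volume_mm3, mask = mask)
}

#' Plan-quality metrics of one lesion
#'
#' Computes the four standard Gamma Knife plan-quality ratios from a
#' normalized dose volume and a target mask, all by voxel counting:
#' \deqn{coverage = |TV \cap PIV| / |TV|}
#' \deqn{selectivity = |TV \cap PIV| / |PIV|}
#' \deqn{GI = |PIV_{0.5Rx}| / |PIV|}
#' \deqn{CI50 = |PIV_{0.5Rx}| / |TV|}
#' where PIV and PIV_0.5Rx are the (inclusive) 100% and 50% isodose
#' volumes. Ratios with an empty denominator are NA and recorded in the
#' `unavailable` slot. The identity `GI * coverage == CI50 * selectivity`
#' holds to float precision whenever all four are defined.
#'
#' @param dose_norm non-negative 3D array, dose as fraction of Rx.
#' @param tumor_mask logical (or 0/1) array of the same shape.
#' @param voxel_volume_mm3 volume of one voxel in mm^3.
#' @return A [PlanMetrics-class] object.
#' @export
planMetrics <- function(dose_norm, tumor_mask, voxel_volume_mm3 = 0.5^3) {
  tumor_mask <- tumor_mask != 0
  if (!identical(dim(dose_norm), dim(tumor_mask)))
    stop("dose and tumor mask shapes differ")
  n_tv <- sum(tumor_mask)
  if (n_tv == 0L) stop("empty tumor mask")
  piv <- dose_norm >= 1.0
  piv50 <- dose_norm >= 0.5
  n_piv <- sum(piv)
  n_piv50 <- sum(piv50)
  n_int <- sum(piv & tumor_mask)

  unavailable <- character(0)
  cov <- n_int / n_tv
  if (n_piv > 0) {
    sel <- n_int / n_piv
    gi <- n_piv50 / n_piv
  } else {
    sel <- NA_real_
    gi <- NA_real_
    unavailable <- c(unavailable, "selectivity", "gi")
  }
  ci <- n_piv50 / n_tv
  new("PlanMetrics", coverage = cov, selectivity = sel, gi = gi, ci50 = ci,
      tv_mm3 = n_tv * voxel_volume_mm3, piv_mm3 = n_piv * voxel_volume_mm3,
      piv50_mm3 = n_piv50 * voxel_volume_mm3, unavailable = unavailable)
}

#' Dice similarity of two isodose surfaces
#'
#' Hard-threshold Dice coefficient 2|A n B| / (|A| + |B|) between the
#' suprathreshold sets of two dose distributions at a common level. Two
#' empty sets are defined as perfectly similar (1.0).
#'
#' @param dose_a_norm,dose_b_norm arrays of identical shape, fraction of Rx.
#' @param level isodose level as fraction of Rx (1.0 or 0.5 for the plan
#'   quality surfaces).
#' @return Dice coefficient in [0, 1].
#' @export
isodoseDSC <- function(dose_a_norm, dose_b_norm, level) {
  if (!identical(dim(dose_a_norm), dim(dose_b_norm)))
    stop("shape mismatch between dose volumes")
  a <- dose_a_norm >= level
  b <- dose_b_norm >= level
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1.0)
  2 * sum(a & b) / denom
}

#' Collimator-derived volume-group boundaries
#'
#' The group boundaries are the volumes of spheres whose diameters equal
#' the available collimator sizes, rounded to 0.1 mm^3: 33.5, 268.1 and
#' 2144.7 mm^3 for 4, 8 and 16 mm.
#'
#' @param collimator_mm collimator diameters in mm.
#' @return Increasing numeric vector of boundaries in mm^3.
#' @export
volumeGroupBounds <- function(collimator_mm = c(4, 8, 16)) {
  round(4 / 3 * pi * (collimator_mm / 2)^3, 1)
}

#' Volume group of a lesion
#'
#' Assigns the 1-based group index using half-open, lower-inclusive
#' intervals: group 1 below the first boundary, group g in
#' [bounds[g-1], bounds[g]), last group at or above the top boundary.
#'
#' @param tv_mm3 target volume(s) in mm^3, positive.
#' @param bounds increasing boundaries, by default [volumeGroupBounds()].
#' @return Integer group index (vectorized).
#' @export
volumeGroup <- function(tv_mm3, bounds = volumeGroupBounds()) {
  if (any(tv_mm3 <= 0)) stop("target volume must be positive")
  findInterval(tv_mm3, bounds) + 1L
}

#' Metric table for a list of cases or tumor spaces
#'
#' @param x list of [LesionCase-class] or [TumorSpace-class] objects.
#' @return data.frame with lesion_id, tv_mm3, coverage_pct, selectivity,
#'   gi, ci50 and group.
#' @export
planMetricsTable <- function(x) {
  rows <- lapply(x, function(obj) {
    if (is(obj, "LesionCase")) {
      m <- obj@true_metrics
      id <- obj@lesion_id
    } else if (is(obj, "TumorSpace")) {
      m <- planMetrics(obj@dose_norm, obj@input_mask == 2L,
                       voxelVolume(obj@spacing_mm))
      id <- obj@lesion_id
    } else stop("unsupported object of class ", class(obj))
    data.frame(lesion_id = id, tv_mm3 = m@tv_mm3,
               coverage_pct = 100 * m@coverage, selectivity = m@selectivity,
               gi = m@gi, ci50 = m@ci50,
               group = volumeGroup(m@tv_mm3))
  })
  do.call(rbind, rows)
}
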