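#' @import methods
#' @importFrom stats quantile rnorm runif sd median setNames
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib GKDosePredict, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' DoseGrid: a 3D scalar dose volume with isotropic spacing
#'
#' Container for an absolute dose distribution in Gy on a regular, isotropic
#' voxel grid. World coordinates follow `origin_mm + (index - 1) * spacing_mm`
#' with 1-based voxel indices; the third array axis is the superior--inferior
#' axis (the axis the augmentation module rotates about).
#'
#' @slot voxels 3D numeric array of dose values (Gy), all non-negative.
#' @slot spacing_mm isotropic voxel edge length in mm.
#' @slot origin_mm world coordinate of voxel (1,1,1), length-3 numeric (mm).
#' @export
setClass("DoseGrid",
  representation(voxels = "array", spacing_mm = "numeric",
                 origin_mm = "numeric"),
  prototype(spacing_mm = 0.5, origin_mm = c(0, 0, 0)))

setValidity("DoseGrid", function(object) {
  if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
  if (length(object@spacing_mm) != 1L || object@spacing_mm <= 0)
    return("spacing_mm must be a single positive number")
  if (length(object@origin_mm) != 3L) return("origin_mm must have length 3")
  if (anyNA(object@voxels) || any(object@voxels < 0))
    return("dose voxels must be finite and non-negative")
  TRUE
})

#' Construct a DoseGrid
#'
#' @param voxels 3D numeric array of dose in Gy.
#' @param spacing_mm isotropic voxel spacing in mm (default 0.5).
#' @param origin_mm world position of the first voxel (mm).
#' @return A [DoseGrid-class] object.
#' @export
doseGrid <- function(voxels, spacing_mm = 0.5, origin_mm = c(0, 0, 0)) {
  new("DoseGrid", voxels = voxels, spacing_mm = spacing_mm,
      origin_mm = as.numeric(origin_mm))
}

#' PlanMetrics: Gamma Knife plan-quality metrics for one lesion
#'
#' Holds the four standard plan-quality ratios together with the constituent
#' volumes they are computed from. Metrics whose denominator is empty are NA
#' and listed in `unavailable` (mirroring how a clinical planning system
#' reports metrics it cannot attribute).
#'
#' @slot coverage fraction of the target receiving at least Rx (stored as a
#'   fraction in [0,1]; clinical display is percent).
#' @slot selectivity fraction of the prescription isodose volume inside the
#'   target.
#' @slot gi gradient index, PIV_0.5Rx / PIV.
#' @slot ci50 intermediate dose spillage, PIV_0.5Rx / TV.
#' @slot tv_mm3,piv_mm3,piv50_mm3 target volume and the 100% / 50% isodose
#'   volumes in mm^3.
#' @slot unavailable names of metrics that could not be computed.
#' @export
setClass("PlanMetrics",
  representation(coverage = "numeric", selectivity = "numeric",
                 gi = "numeric", ci50 = "numeric", tv_mm3 = "numeric",
                 piv_mm3 = "numeric", piv50_mm3 = "numeric",
                 unavailable = "character"))

setValidity("PlanMetrics", function(object) {
  ok <- function(x) length(x) == 1L
  if (!all(vapply(list(object@coverage, object@selectivity, object@gi,
                       object@ci50, object@tv_mm3, object@piv_mm3,
                       object@piv50_mm3), ok, logical(1))))
    return("all metric slots must be scalars")
  if (!is.na(object@coverage) &&
      (object@coverage < 0 || object@coverage > 1))
    return("coverage must lie in [0, 1]")
  if (!is.na(object@selectivity) &&
      (object@selectivity < 0 || object@selectivity > 1))
    return("selectivity must lie in [0, 1]")
  TRUE
})

#' LesionCase: one synthetic lesion with its dose and ground-truth metrics
#'
#' @slot lesion_id character identifier.
#' @slot rx_gy prescription dose in Gy.
#' @slot tumor_mask logical 3D array marking the target.
#' @slot skull_mask logical 3D array marking the skull shell.
#' @slot dose [DoseGrid-class] with the composed shot dose (Gy).
#' @slot shots data.frame of shots: center (voxel index, 3 columns),
#'   collimator_mm and weight (Gy at kernel peak).
#' @slot true_metrics [PlanMetrics-class] computed from `dose`.
#' @export
setClass("LesionCase",
  representation(lesion_id = "character", rx_gy = "numeric",
                 tumor_mask = "array", skull_mask = "array",
                 dose = "DoseGrid", shots = "data.frame",
                 true_metrics = "PlanMetrics"))

setValidity("LesionCase", function(object) {
  dm <- dim(object@dose@voxels)
  if (!identical(dim(object@tumor_mask), dm) ||
      !identical(dim(object@skull_mask), dm))
    return("dose grid and masks must share one shape")
  if (!any(object@tumor_mask)) return("tumor mask must be non-empty")
  TRUE
})

#' TumorSpace: a lesion-level training sample
#'
#' The paired (input mask, normalized dose) cube for one lesion: the
#' network's input and regression target. The dose channel is the clinical
#' dose divided by the prescription and zeroed outside the 30%-of-Rx isodose
#' region; the mask channel is truncated (not isodose-zeroed) from the
#' patient-level label volume so that it can be built for new cases whose
#' dose is unknown.
#'
#' @slot lesion_id character identifier.
#' @slot input_mask integer 3D array with codes 2 (tumor), 1 (skull),
#'   0 (elsewhere).
#' @slot dose_norm non-negative 3D array in units of fraction-of-Rx.
#' @slot rx_gy prescription dose in Gy.
#' @slot center_index_patient voxel index (1-based) of the crop centre in
#'   the patient grid.
#' @slot spacing_mm isotropic voxel spacing in mm.
#' @export
setClass("TumorSpace",
  representation(lesion_id = "character", input_mask = "array",
                 dose_norm = "array", rx_gy = "numeric",
                 center_index_patient = "integer", spacing_mm = "numeric"))

setValidity("TumorSpace", function(object) {
  dm <- dim(object@input_mask)
  if (length(dm) != 3L || length(unique(dm)) != 1L)
    return("input_mask must be a cubic 3D array")
  if (!identical(dim(object@dose_norm), dm))
    return("dose_norm must match input_mask shape")
  if (!all(object@input_mask %in% c(0L, 1L, 2L)))
    return("input_mask codes must be 0, 1 or 2")
  if (!any(object@input_mask == 2L)) return("tumor voxels (code 2) missing")
  if (any(object@dose_norm < 0)) return("dose_norm must be non-negative")
  TRUE
})

#' PhantomSpec: study conditions for the synthetic lesion generator
#'
#' All knobs of the shot-composed dose phantom. Defaults reproduce the
#' cohort envelope the generator is meant to emulate: lesion volumes from
#' 14.875 to 5995.875 mm^3, prescriptions from the clinical 12--21 Gy menu,
#' and the three Gamma Knife collimator sizes (4, 8, 16 mm).
#'
#' @slot seed integer RNG seed; identical specs yield bit-identical cohorts.
#' @slot n_lesions number of lesions to generate.
#' @slot volume_range_mm3 (low, high) lesion volume bounds, drawn
#'   log-uniformly.
#' @slot rx_menu_gy prescription dose menu in Gy.
#' @slot collimator_mm available collimator diameters in mm, ascending.
#' @slot kernel_fwhm_scale multiplier mapping collimator diameter to the
#'   Gaussian kernel FWHM (1 = FWHM equals the diameter).
#' @slot skull_inner_radius_mm inner radius of the spherical skull model.
#' @slot skull_thickness_mm skull shell thickness.
#' @slot coverage_target in-target dose quantile calibrated to Rx
#'   (0.99 means the 1st percentile of in-target dose equals Rx).
#' @slot grid_shape voxel grid of each generated case.
#' @slot spacing_mm isotropic voxel spacing in mm.
#' @slot depth_range_mm (min, max) lesion-centre depth below the inner skull
#'   surface; small depths put skull inside the case window.
#' @export
setClass("PhantomSpec",
  representation(seed = "integer", n_lesions = "integer",
                 volume_range_mm3 = "numeric", rx_menu_gy = "numeric",
                 collimator_mm = "numeric", kernel_fwhm_scale = "numeric",
                 skull_inner_radius_mm = "numeric",
                 skull_thickness_mm = "numeric", coverage_target = "numeric",
                 grid_shape = "integer", spacing_mm = "numeric",
                 depth_range_mm = "numeric"))

setValidity("PhantomSpec", function(object) {
  v <- object@volume_range_mm3
  if (length(v) != 2L || v[1] > v[2] || v[1] <= 0)
    return("volume_range_mm3 must be a positive (low, high) pair")
  if (v[1] < 14.875 - 1e-9 || v[2] > 5995.875 + 1e-9)
    return("volume_range_mm3 must lie within [14.875, 5995.875]")
  if (length(object@rx_menu_gy) == 0 ||
      any(object@rx_menu_gy < 12 | object@rx_menu_gy > 21))
    return("all prescriptions must lie within the 12-21 Gy menu")
  cl <- object@collimator_mm
  if (length(cl) == 0 || is.unsorted(cl, strictly = TRUE))
    return("collimator_mm must be non-empty and sorted ascending")
  if (object@coverage_target <= 0 || object@coverage_target > 1)
    return("coverage_target must lie in (0, 1]")
  if (length(object@grid_shape) != 3L || any(object@grid_shape < 8))
    return("grid_shape must be three values >= 8")
  if (object@kernel_fwhm_scale <= 0) return("kernel_fwhm_scale must be > 0")
  TRUE
})

#' LossConfig: parameters of the composite training objective
#'
#' @slot steepness sigmoid steepness k of the smoothed step function
#'   (default 1000 on the fraction-of-Rx scale).
#' @slot a_iso_levels isodose levels (fraction of Rx) at which the smoothed
#'   Dice losses act; default c(1.0, 0.5).
#' @slot omega_in weight of voxels at/above Rx in the ground truth
#'   (default 8).
#' @slot omega_out weight of all other tumor-space voxels (default 1).
#' @slot alpha weight of the Dice loss at the 100% isodose (default 100).
#' @slot beta weight of the Dice loss at the 50% isodose (default 10).
#' @slot epsilon denominator guard for empty-isodose degenerate fields.
#' @export
setClass("LossConfig",
  representation(steepness = "numeric", a_iso_levels = "numeric",
                 omega_in = "numeric", omega_out = "numeric",
                 alpha = "numeric", beta = "numeric", epsilon = "numeric"))

setValidity("LossConfig", function(object) {
  if (object@steepness <= 0) return("steepness must be > 0")
  if (object@alpha < 0 || object@beta < 0)
    return("alpha and beta must be >= 0")
  if (!(object@omega_in >= object@omega_out && object@omega_out > 0))
    return("need omega_in >= omega_out > 0")
  if (length(object@a_iso_levels) != 2L) return("a_iso_levels must be a pair")
  TRUE
})

#' NetConfig: architecture of the hierarchically dense 3D U-Net
#'
#' @slot growth_rate new features added by every dense convolution or dense
#'   down-sampling operation (default 16).
#' @slot upsample_features features returned by each U-Net up-sampling
#'   operation (default 64).
#' @slot n_levels number of resolution levels (default 5 for 128^3 input,
#'   giving an 8^3 bottleneck).
#' @slot input_shape cubic input edge in voxels (default 128).
#' @slot dropout_rate dropout after each dense convolution block
#'   (default 0.10).
#' @slot kernel_size convolution kernel edge; only 3 is supported.
#' @slot precision "float" (training default) or "double" (used by the
#'   finite-difference gradient tests).
#' @export
setClass("NetConfig",
  representation(growth_rate = "integer", upsample_features = "integer",
                 n_levels = "integer", input_shape = "integer",
                 dropout_rate = "numeric", kernel_size = "integer",
                 precision = "character"))

setValidity("NetConfig", function(object) {
  if (object@growth_rate < 1) return("growth_rate must be >= 1")
  if (object@dropout_rate < 0 || object@dropout_rate >= 1)
    return("dropout_rate must lie in [0, 1)")
  div <- 2L^(object@n_levels - 1L)
  if (object@input_shape %% div != 0L)
    return("input_shape must be divisible by 2^(n_levels - 1)")
  if (object@kernel_size != 3L)
    return("only kernel_size 3 is supported")
  if (!object@precision %in% c("float", "double"))
    return("precision must be 'float' or 'double'")
  TRUE
})

#' AugmentPolicy: joint augmentation of (mask, dose) pairs
#'
#' @slot p_augment probability that a sample is augmented at all
#'   (default 0.75).
#' @slot p_flip probability of a left-right flip after the transform
#'   (default 0.5).
#' @slot angles_deg the eight rotation angles about the superior--inferior
#'   axis permitted by the 8-fold sector symmetry of the delivery system.
#' @slot translation_max_voxels per-axis bound of integer translations.
#' @export
setClass("AugmentPolicy",
  representation(p_augment = "numeric", p_flip = "numeric",
                 angles_deg = "numeric", translation_max_voxels = "integer"))

setValidity("AugmentPolicy", function(object) {
  if (object@p_augment < 0 || object@p_augment > 1 ||
      object@p_flip < 0 || object@p_flip > 1)
    return("probabilities must lie in [0, 1]")
  if (!identical(sort(object@angles_deg), seq(0, 315, by = 45)))
    return("angles_deg must be the eight multiples of 45 degrees")
  if (object@translation_max_voxels < 0)
    return("translation_max_voxels must be >= 0")
  TRUE
})

#' TrainConfig: schedule of the cross-validated training loop
#'
#' Defaults follow the reference schedule: ten folds, 80 epochs of 200
#' batches of size 2, learning rate starting at 0.001 and decaying by a
#' factor of 0.93 every 200 batches.
#'
#' @slot n_folds number of cross-validation folds.
#' @slot epochs epochs per fold.
#' @slot batches_per_epoch batches per epoch; NA derives it from the
#'   training-set size so that data are seen approximately once per epoch.
#' @slot batch_size samples per batch.
#' @slot lr_initial initial learning rate.
#' @slot lr_decay_factor multiplicative decay factor.
#' @slot lr_decay_every decay period in batches.
#' @slot seed master seed; fold split, weight init and augmentation streams
#'   are all derived from it.
#' @export
setClass("TrainConfig",
  representation(n_folds = "integer", epochs = "integer",
                 batches_per_epoch = "integer", batch_size = "integer",
                 lr_initial = "numeric", lr_decay_factor = "numeric",
                 lr_decay_every = "integer", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@n_folds < 1 || object@epochs < 1 || object@batch_size < 1 ||
      object@lr_decay_every < 1)
    return("all counts must be positive")
  if (object@lr_decay_factor <= 0 || object@lr_decay_factor >= 1)
    return("lr_decay_factor must lie in (0, 1)")
  TRUE
})

#' HDUNet: handle to a constructed network
#'
#' Wraps the external pointer to the compiled network state together with
#' its configuration. Weights are accessed with [networkWeights()] and the
#' handle is rebuilt from a checkpoint with [loadCheckpoint()].
#'
#' @slot ptr external pointer to the compiled network.
#' @slot config the [NetConfig-class] used to build it.
#' @slot n_params total number of trainable parameters.
#' @export
setClass("HDUNet",
  representation(ptr = "externalptr", config = "NetConfig",
                 n_params = "numeric"))
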