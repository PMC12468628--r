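#' Construct a PhantomSpec
#'
#' See [PhantomSpec-class] for the meaning of every field. The defaults are
#' the full-scale study conditions; reduced-scale experiments (e.g. 32^3
#' grids) override `grid_shape`, `volume_range_mm3` and `collimator_mm`
#' coherently so that lesions and kernels fit the window.
#'
#' @param seed integer RNG seed.
#' @param n_lesions number of lesions.
#' @param volume_range_mm3 lesion volume bounds (mm^3), log-uniform draw.
#' @param rx_menu_gy prescription menu in Gy.
#' @param collimator_mm collimator diameters in mm, ascending.
#' @param kernel_fwhm_scale kernel FWHM = scale * collimator diameter.
#' @param skull_inner_radius_mm,skull_thickness_mm spherical skull model.
#' @param coverage_target in-target dose quantile calibrated to Rx.
#' @param grid_shape case grid (voxels); scalar is expanded to a cube.
#' @param spacing_mm isotropic spacing in mm.
#' @param depth_range_mm lesion depth range below the inner skull surface.
#' @return A validated [PhantomSpec-class].
#' @export
phantomSpec <- function(seed = 1L, n_lesions = 200L,
                        volume_range_mm3 = c(14.875, 5995.875),
                        rx_menu_gy = c(21, 20, 18, 17, 16, 15, 14, 12),
                        collimator_mm = c(4, 8, 16),
                        kernel_fwhm_scale = 1.0,
                        skull_inner_radius_mm = 70,
                        skull_thickness_mm = 5,
                        coverage_target = 0.99,
                        grid_shape = 128L,
                        spacing_mm = 0.5,
                        depth_range_mm = c(3, 25)) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  new("PhantomSpec", seed = as.integer(seed),
      n_lesions = as.integer(n_lesions),
      volume_range_mm3 = as.numeric(volume_range_mm3),
      rx_menu_gy = as.numeric(rx_menu_gy),
      collimator_mm = as.numeric(collimator_mm),
      kernel_fwhm_scale = as.numeric(kernel_fwhm_scale),
      skull_inner_radius_mm = as.numeric(skull_inner_radius_mm),
      skull_thickness_mm = as.numeric(skull_thickness_mm),
      coverage_target = as.numeric(coverage_target),
      grid_shape = as.integer(grid_shape),
      spacing_mm = as.numeric(spacing_mm),
      depth_range_mm = as.numeric(depth_range_mm))
}

#' Construct a LossConfig
#'
#' @param steepness sigmoid steepness of the smoothed step (default 1000).
#' @param a_iso_levels isodose levels of the two Dice terms.
#' @param omega_in,omega_out weighted-MSE voxel weights (inside/outside the
#'   ground-truth prescription isodose).
#' @param alpha,beta weights of the Dice losses at 100% and 50% of Rx.
#' @param epsilon denominator guard.
#' @return A validated [LossConfig-class].
#' @export
lossConfig <- function(steepness = 1000, a_iso_levels = c(1.0, 0.5),
                       omega_in = 8, omega_out = 1, alpha = 100, beta = 10,
                       epsilon = 1e-7) {
  new("LossConfig", steepness = steepness, a_iso_levels = a_iso_levels,
      omega_in = omega_in, omega_out = omega_out, alpha = alpha,
      beta = beta, epsilon = epsilon)
}

#' The plain-MSE baseline objective
#'
#' Convenience constructor for the comparator configuration: both Dice
#' weights zero and uniform MSE weights, reducing the composite objective to
#' a conventional mean-squared-error loss.
#'
#' @param ... passed through to [lossConfig()].
#' @return A [LossConfig-class] with `alpha = beta = 0`, `omega_in = 1`.
#' @export
mseBaselineConfig <- function(...) {
  lossConfig(alpha = 0, beta = 0, omega_in = 1, omega_out = 1, ...)
}

#' Construct a NetConfig
#'
#' @param growth_rate features added per dense operation.
#' @param upsample_features features returned by U-Net up-sampling.
#' @param n_levels resolution levels; the default 5 takes a 128^3 input
#'   down to an 8^3 bottleneck, 3 suits a 32^3 input.
#' @param input_shape cubic input edge (voxels).
#' @param dropout_rate dropout after each dense convolution block.
#' @param kernel_size convolution kernel edge (3).
#' @param precision "float" or "double".
#' @return A validated [NetConfig-class].
#' @export
netConfig <- function(growth_rate = 16L, upsample_features = 64L,
                      n_levels = 5L, input_shape = 128L,
                      dropout_rate = 0.10, kernel_size = 3L,
                      precision = "float") {
  new("NetConfig", growth_rate = as.integer(growth_rate),
      upsample_features = as.integer(upsample_features),
      n_levels = as.integer(n_levels),
      input_shape = as.integer(input_shape),
      dropout_rate = dropout_rate, kernel_size = as.integer(kernel_size),
      precision = precision)
}

#' Construct an AugmentPolicy
#'
#' @param p_augment probability of augmenting a sample (default 0.75).
#' @param p_flip probability of a subsequent left-right flip (default 0.5).
#' @param angles_deg the eight sector-symmetric rotation angles.
#' @param translation_max_voxels per-axis integer translation bound
#'   (default 10 voxels = 5 mm at 0.5 mm spacing).
#' @return A validated [AugmentPolicy-class].
#' @export
augmentPolicy <- function(p_augment = 0.75, p_flip = 0.5,
                          angles_deg = seq(0, 315, by = 45),
                          translation_max_voxels = 10L) {
  new("AugmentPolicy", p_augment = p_augment, p_flip = p_flip,
      angles_deg = as.numeric(angles_deg),
      translation_max_voxels = as.integer(translation_max_voxels))
}

#' Construct a TrainConfig
#'
#' @param n_folds cross-validation folds (default 10).
#' @param epochs epochs per fold (default 80).
#' @param batches_per_epoch batches per epoch (default 200; NA derives the
#'   value from the training-set size).
#' @param batch_size samples per batch (default 2).
#' @param lr_initial initial learning rate (default 0.001).
#' @param lr_decay_factor decay factor (default 0.93).
#' @param lr_decay_every decay period in batches (default 200).
#' @param seed master seed.
#' @return A validated [TrainConfig-class].
#' @export
trainConfig <- function(n_folds = 10L, epochs = 80L,
                        batches_per_epoch = 200L, batch_size = 2L,
                        lr_initial = 0.001, lr_decay_factor = 0.93,
                        lr_decay_every = 200L, seed = 1L) {
  new("TrainConfig", n_folds = as.integer(n_folds),
      epochs = as.integer(epochs),
      batches_per_epoch = as.integer(batches_per_epoch),
      batch_size = as.integer(batch_size), lr_initial = lr_initial,
      lr_decay_factor = lr_decay_factor,
      lr_decay_every = as.integer(lr_decay_every), seed = as.integer(seed))
}

#' Construct a TumorSpace
#'
#' Usually produced by [extractTumorSpace()]; exposed for tests and adapters.
#'
#' @param lesion_id identifier.
#' @param input_mask integer 3D array with codes 0/1/2.
#' @param dose_norm non-negative 3D array, fraction of Rx.
#' @param rx_gy prescription dose in Gy.
#' @param center_index_patient crop centre in the patient grid (1-based).
#' @param spacing_mm voxel spacing in mm.
#' @return A validated [TumorSpace-class].
#' @export
tumorSpace <- function(lesion_id, input_mask, dose_norm, rx_gy,
                       center_index_patient = c(0L, 0L, 0L),
                       spacing_mm = 0.5) {
  storage.mode(input_mask) <- "integer"
  new("TumorSpace", lesion_id = as.character(lesion_id),
      input_mask = input_mask, dose_norm = dose_norm, rx_gy = rx_gy,
      center_index_patient = as.integer(center_index_patient),
      spacing_mm = spacing_mm)
}

voxelVolume <- function(spacing_mm) spacing_mm^3

setMethod("show", "DoseGrid", function(object) {
  dm <- dim(object@voxels)
  cat(sprintf("DoseGrid %dx%dx%d @ %.3g mm, dose %.2f-%.2f Gy\n",
              dm[1], dm[2], dm[3], object@spacing_mm,
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "PlanMetrics", function(object) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
  cat(sprintf(paste0("PlanMetrics: coverage %s%%, selectivity %s, GI %s, ",
                     "CI50 %s (TV %.1f mm^3)\n"),
              ifelse(is.na(object@coverage), "NA",
                     sprintf("%.2f", 100 * object@coverage)),
              fmt(object@selectivity), fmt(object@gi), fmt(object@ci50),
              object@tv_mm3))
  if (length(object@unavailable))
    cat("  unavailable:", paste(object@unavailable, collapse = ", "), "\n")
})

setMethod("show", "TumorSpace", function(object) {
  dm <- dim(object@input_mask)
  cat(sprintf(paste0("TumorSpace '%s': %d^3 @ %.3g mm, Rx %.3g Gy, ",
                     "%d tumor voxels, peak dose %.2f Rx\n"),
              object@lesion_id, dm[1], object@spacing_mm, object@rx_gy,
              sum(object@input_mask == 2L), max(object@dose_norm)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %d lesions, volumes %.3f-%.3f mm^3, ",
                     "Rx {%s} Gy, collimators {%s} mm, grid %s @ %.3g mm, ",
                     "seed %d\n"),
              object@n_lesions, object@volume_range_mm3[1],
              object@volume_range_mm3[2],
              paste(object@rx_menu_gy, collapse = ","),
              paste(object@collimator_mm, collapse = ","),
              paste(object@grid_shape, collapse = "x"), object@spacing_mm,
              object@seed))
})

setMethod("show", "HDUNet", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("HDUNet: %d levels, growth %d, upsample %d, input ",
                     "%d^3, dropout %.2f, %s precision, %s parameters\n"),
              cfg@n_levels, cfg@growth_rate, cfg@upsample_features,
              cfg@input_shape, cfg@dropout_rate, cfg@precision,
              format(object@n_params, big.mark = ",")))
})

#' Metric accessors
#'
#' Read individual plan-quality values from a [PlanMetrics-class] object.
#' `coverage()` returns a fraction; multiply by 100 for the clinical
#' percent display.
#'
#' @param x a PlanMetrics object.
#' @return A single numeric value (NA if the metric was unavailable).
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))
#' @rdname coverage
#' @export
setGeneric("selectivity", function(x) standardGeneric("selectivity"))
#' @rdname coverage
#' @export
setGeneric("gradientIndex", function(x) standardGeneric("gradientIndex"))
#' @rdname coverage
#' @export
setGeneric("ci50", function(x) standardGeneric("ci50"))
#' @rdname coverage
#' @export
setGeneric("targetVolume", function(x) standardGeneric("targetVolume"))

#' @rdname coverage
setMethod("coverage", "PlanMetrics", function(x) x@coverage)
#' @rdname coverage
setMethod("selectivity", "PlanMetrics", function(x) x@selectivity)
#' @rdname coverage
setMethod("gradientIndex", "PlanMetrics", function(x) x@gi)
#' @rdname coverage
setMethod("ci50", "PlanMetrics", function(x) x@ci50)
#' @rdname coverage
setMethod("targetVolume", "PlanMetrics", function(x) x@tv_mm3)

#' @export
as.data.frame.PlanMetrics <- function(x, ...) {
  data.frame(coverage = x@coverage, selectivity = x@selectivity,
             gi = x@gi, ci50 = x@ci50, tv_mm3 = x@tv_mm3,
             piv_mm3 = x@piv_mm3, piv50_mm3 = x@piv50_mm3)
}
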