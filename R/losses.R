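#' Smoothed step function
#'
#' Steep logistic sigmoid `1 / (1 + exp(-k * x))` used as a differentiable
#' approximation of the unit step when comparing dose values against an
#' isodose threshold. The exponent is clamped at +/-60, which leaves the
#' saturated values unchanged at double precision while avoiding overflow.
#'
#' @param x numeric input (any shape).
#' @param k steepness (default 1000 on the fraction-of-Rx scale).
#' @return Values in (0, 1), same shape as `x`.
#' @export
smoothStep <- function(x, k = 1000) {
  e <- pmin(pmax(-k * x, -60), 60)
  1 / (1 + exp(e))
}

#' Smoothed-Dice loss at one isodose level
#'
#' A differentiable disagreement score between the predicted and ground
#' truth isodose surfaces at level `a_iso` (fraction of Rx):
#' \deqn{L = \frac{\sum_i (\sigma(p_i - a) - \sigma(t_i - a))^2}
#'            {\sum_i (\sigma(p_i - a)^2 + \sigma(t_i - a)^2)}}
#' with the smoothed step \eqn{\sigma}. For fields whose voxels all sit
#' well away from the threshold this equals 1 minus the hard-threshold Dice
#' coefficient; near the threshold it is smooth, which is what lets the
#' gradient pull the predicted isodose line onto the true one.
#'
#' @param d_pred_norm,d_true_norm arrays of identical shape on the
#'   fraction-of-Rx scale.
#' @param a_iso isodose level (1.0 or 0.5 for the clinical surfaces).
#' @param steepness sigmoid steepness k.
#' @param epsilon denominator guard; if the denominator falls below it
#'   (both fields entirely far below the level) the loss is defined as 0
#'   and a warning is raised.
#' @return Non-negative scalar.
#' @export
dscLoss <- function(d_pred_norm, d_true_norm, a_iso, steepness = 1000,
                    epsilon = 1e-7) {
  if (!identical(dim(d_pred_norm), dim(d_true_norm)))
    stop("shape mismatch")
  sp <- smoothStep(d_pred_norm - a_iso, steepness)
  st <- smoothStep(d_true_norm - a_iso, steepness)
  den <- sum(sp * sp) + sum(st * st)
  if (den < epsilon) {
    warning("both fields lie entirely below the ", a_iso,
            " isodose level; Dice loss defined as 0")
    return(0)
  }
  sum((sp - st)^2) / den
}

#' Weighted mean-squared-error loss
#'
#' Voxelwise squared error on the normalized dose, weighted `omega_in` for
#' voxels that receive at least the prescription dose in the ground truth
#' and `omega_out` elsewhere in the tumor space, averaged over all N voxels
#' of the sample (zero padding included). Doses are stored pre-normalized
#' by Rx, so the conventional 1/Rx^2 factor of the squared error is
#' already absorbed.
#'
#' @param d_pred_norm,d_true_norm arrays of identical shape.
#' @param omega_in weight where `d_true_norm >= 1` (default 8).
#' @param omega_out weight elsewhere (default 1).
#' @return Non-negative scalar.
#' @export
wmseLoss <- function(d_pred_norm, d_true_norm, omega_in = 8, omega_out = 1) {
  if (!identical(dim(d_pred_norm), dim(d_true_norm)))
    stop("shape mismatch")
  w <- ifelse(d_true_norm >= 1.0, omega_in, omega_out)
  mean(w * (d_pred_norm - d_true_norm)^2)
}

#' Composite training objective
#'
#' `wMSE + alpha * DiceLoss(a=1.0) + beta * DiceLoss(a=0.5)`: the weighted
#' MSE drives voxelwise agreement while the two smoothed-Dice terms enforce
#' agreement of the 100% and 50% isodose surfaces that the plan-quality
#' metrics are computed from. With `alpha = beta = 0` and uniform omega it
#' reduces to the conventional MSE baseline.
#'
#' @param d_pred_norm,d_true_norm arrays of identical shape.
#' @param config a [LossConfig-class].
#' @return Non-negative scalar.
#' @seealso [totalLossGradient()] for the analytic gradient.
#' @export
totalLoss <- function(d_pred_norm, d_true_norm, config = lossConfig()) {
  l <- wmseLoss(d_pred_norm, d_true_norm, config@omega_in, config@omega_out)
  if (config@alpha > 0)
    l <- l + config@alpha * dscLoss(d_pred_norm, d_true_norm,
                                    config@a_iso_levels[1],
                                    config@steepness, config@epsilon)
  if (config@beta > 0)
    l <- l + config@beta * dscLoss(d_pred_norm, d_true_norm,
                                   config@a_iso_levels[2],
                                   config@steepness, config@epsilon)
  l
}

dscLossGradient <- function(d_pred_norm, d_true_norm, a_iso, steepness,
                            epsilon) {
  sp <- smoothStep(d_pred_norm - a_iso, steepness)
  st <- smoothStep(d_true_norm - a_iso, steepness)
  num <- sum((sp - st)^2)
  den <- sum(sp * sp) + sum(st * st)
  if (den < epsilon) return(array(0, dim(d_pred_norm)))
  # dL/dsp = (2 (sp - st) den - num * 2 sp) / den^2 ; dsp/dp = k sp (1 - sp)
  dsp <- (2 * (sp - st) * den - 2 * num * sp) / den^2
  dsp * steepness * sp * (1 - sp)
}

#' Analytic gradient of the composite objective
#'
#' Gradient of [totalLoss()] with respect to the predicted dose, used by
#' the training loop to seed back-propagation. Verified against central
#' finite differences in the test suite.
#'
#' @inheritParams totalLoss
#' @return Array of the same shape as `d_pred_norm`.
#' @export
totalLossGradient <- function(d_pred_norm, d_true_norm,
                              config = lossConfig()) {
  w <- ifelse(d_true_norm >= 1.0, config@omega_in, config@omega_out)
  g <- 2 * w * (d_pred_norm - d_true_norm) / length(d_pred_norm)
  if (config@alpha > 0)
    g <- g + config@alpha *
      dscLossGradient(d_pred_norm, d_true_norm, config@a_iso_levels[1],
                      config@steepness, config@epsilon)
  if (config@beta > 0)
    g <- g + config@beta *
      dscLossGradient(d_pred_norm, d_true_norm, config@a_iso_levels[2],
                      config@steepness, config@epsilon)
  g
}
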