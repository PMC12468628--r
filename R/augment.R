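# Joint augmentation of (mask, dose) pairs. Rotations are restricted to
# the eight multiples of 45 degrees about the superior--inferior (third)
# axis, reflecting the 8-fold rotational symmetry of the radiation source
# sectors; translations are integer voxel shifts; the only reflection is a
# left-right flip. No elastic or affine deformation is ever applied, since
# deforming a dose distribution would invalidate its plan-quality metrics.

#' Flip a volume left-right
#'
#' Reverses the first (left-right) axis.
#' @param vol 3D array.
#' @return Flipped array.
#' @export
flipLR <- function(vol) vol[dim(vol)[1]:1, , , drop = FALSE]

#' Translate a volume by integer voxels
#'
#' @param vol 3D array.
#' @param shift integer length-3 shift; content moves toward higher indices
#'   for positive shifts, with zero fill.
#' @return Shifted array.
#' @export
translateVolume <- function(vol, shift) {
  gs <- dim(vol)
  out <- array(vector(typeof(vol), 1L), gs) # typed zero fill
  src_lo <- pmax(1L, 1L - shift)
  src_hi <- pmin(gs, gs - shift)
  if (any(src_lo > src_hi)) return(out)
  dst_lo <- src_lo + shift
  dst_hi <- src_hi + shift
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    vol[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}

# per-(edge, angle) cache of the inverse in-plane source coordinates
.rotationCache <- new.env(parent = emptyenv())
rotationMap <- function(n, angle_deg) {
  key <- paste(n, angle_deg)
  hit <- .rotationCache[[key]]
  if (!is.null(hit)) return(hit)
  th <- angle_deg * pi / 180
  ctr <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n) - ctr, y = seq_len(n) - ctr)
  map <- list(xs = cos(th) * g$x + sin(th) * g$y + ctr,
              ys = -sin(th) * g$x + cos(th) * g$y + ctr)
  .rotationCache[[key]] <- map
  map
}

#' Rotate a volume about the superior--inferior axis
#'
#' Angles that are multiples of 90 degrees are exact voxel permutations;
#' the 45-degree family is resampled about the geometric centre of the
#' volume with bilinear (dose) or nearest-neighbour (mask, to preserve
#' integer codes) interpolation, zero outside the grid.
#'
#' @param vol 3D array with square first two dimensions.
#' @param angle_deg one of 0, 45, ..., 315.
#' @param interpolation "trilinear" or "nearest".
#' @return Rotated array.
#' @export
rotateVolumeZ <- function(vol, angle_deg,
                          interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  angle_deg <- angle_deg %% 360
  gs <- dim(vol)
  if (gs[1] != gs[2]) stop("in-plane dimensions must be square")
  if (angle_deg == 0) return(vol)
  if (angle_deg == 90) return(aperm(vol, c(2, 1, 3))[gs[2]:1, , ,
                                                     drop = FALSE])
  if (angle_deg == 180) return(vol[gs[1]:1, gs[2]:1, , drop = FALSE])
  if (angle_deg == 270) return(aperm(vol, c(2, 1, 3))[, gs[1]:1, ,
                                                      drop = FALSE])
  n <- gs[1]
  map <- rotationMap(n, angle_deg)
  xs <- map$xs
  ys <- map$ys
  mat <- matrix(vol, n * n, gs[3]) # columns are z-slices
  out <- matrix(0, n * n, gs[3])
  if (interpolation == "nearest") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 1 & xi <= n & yi >= 1 & yi <= n
    out[ok, ] <- mat[xi[ok] + (yi[ok] - 1) * n, , drop = FALSE]
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    for (dx in 0:1) for (dy in 0:1) {
      xi <- x0 + dx; yi <- y0 + dy
      wgt <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy)
      ok <- xi >= 1 & xi <= n & yi >= 1 & yi <= n & wgt > 0
      out[ok, ] <- out[ok, , drop = FALSE] +
        wgt[ok] * mat[xi[ok] + (yi[ok] - 1) * n, , drop = FALSE]
    }
  }
  array(out, gs)
}

#' Jointly augment a (mask, dose) pair
#'
#' With probability `1 - p_augment` the pair is returned untouched.
#' Otherwise exactly one of an integer translation or a sector-symmetric
#' rotation is applied (equal chances, each rotation angle equiprobable),
#' followed by a left-right flip with probability `p_flip`. The same
#' transform is applied to both volumes; masks use nearest-neighbour and
#' doses trilinear resampling. A translation that would push tumor voxels
#' off the grid is resampled (up to 20 attempts, then an error).
#'
#' Uses the caller's RNG state; seed externally for reproducibility.
#'
#' @param mask integer 3D label array (tumor code 2).
#' @param dose 3D dose array, same shape.
#' @param policy an [AugmentPolicy-class].
#' @return list with `mask`, `dose` and a `transform` record.
#' @export
augmentPair <- function(mask, dose, policy = augmentPolicy()) {
  stopifnot(identical(dim(mask), dim(dose)))
  if (runif(1) >= policy@p_augment)
    return(list(mask = mask, dose = dose,
                transform = list(kind = "none", flip = FALSE)))
  kind <- if (runif(1) < 0.5) "translate" else "rotate"
  if (kind == "translate") {
    tmax <- policy@translation_max_voxels
    n_tum <- sum(mask == 2L)
    for (attempt in seq_len(20)) {
      shift <- as.integer(round(runif(3, -tmax - 0.5 + 1e-9,
                                      tmax + 0.5 - 1e-9)))
      m2 <- translateVolume(mask, shift)
      if (sum(m2 == 2L) == n_tum) {
        mask <- m2
        dose <- translateVolume(dose, shift)
        rec <- list(kind = "translate", shift = shift)
        break
      }
      if (attempt == 20) stop("translation keeps clipping the tumor")
    }
  } else {
    angle <- sample(policy@angles_deg, 1)
    mask <- rotateVolumeZ(mask, angle, "nearest")
    storage.mode(mask) <- "integer"
    dose <- rotateVolumeZ(dose, angle, "trilinear")
    rec <- list(kind = "rotate", angle = angle)
  }
  rec$flip <- runif(1) < policy@p_flip
  if (rec$flip) {
    mask <- flipLR(mask)
    dose <- flipLR(dose)
  }
  list(mask = mask, dose = dose, transform = rec)
}
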