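# Build lesion-level training samples (tumor spaces) from patient-level
# masks and dose grids, and apply the cohort exclusion filters.

# centroid rounded to the nearest voxel, ties toward the lower index
roundCentroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  as.integer(ceiling(colMeans(idx) - 0.5))
}

# 1-based index windows of a cube of edge `window` centred on `center`
cropWindow <- function(center, window) {
  start <- center - window %/% 2L + 1L
  list(start = start, end = start + window - 1L)
}

# crop an array over a window, zero-padding where the window leaves the grid
cropPad <- function(arr, win, fill = 0) {
  window <- win$end - win$start + 1L
  out <- array(fill, window)
  gs <- dim(arr)
  src_lo <- pmax(win$start, 1L)
  src_hi <- pmin(win$end, gs)
  if (any(src_lo > src_hi)) return(out)
  dst_lo <- src_lo - win$start + 1L
  dst_hi <- src_hi - win$start + 1L
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    arr[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}

#' Build the network input mask for a crop window
#'
#' Label codes: 2 for the target, 1 for the skull, 0 everywhere else
#' (including in-body soft tissue, so the skull stays distinguishable, and
#' voxels past the patient grid). The mask is truncated from the
#' patient-level volumes, never zeroed by any isodose region, so it can be
#' built for new cases whose dose is unknown. Overlapping tumor and skull
#' labels resolve to tumor.
#'
#' @param tumor_mask,skull_mask logical patient-grid arrays.
#' @param body_mask optional logical array; currently informational only
#'   since non-body voxels already code 0.
#' @param window list with `start` and `end` index vectors (from an
#'   extraction) or an integer edge length, in which case the window is
#'   centred on the tumor centroid.
#' @return Integer array with codes 0/1/2.
#' @export
buildInputMask <- function(tumor_mask, skull_mask, body_mask = NULL,
                           window = 128L) {
  if (is.numeric(window))
    window <- cropWindow(roundCentroid(tumor_mask), as.integer(window))
  tw <- cropPad(tumor_mask, window) != 0
  sw <- cropPad(skull_mask, window) != 0
  out <- array(0L, dim(tw))
  out[sw] <- 1L
  out[tw] <- 2L
  out
}

#' Extract the tumor space of one lesion
#'
#' Crops a cube of `window`^3 voxels centred on the tumor centroid
#' (rounded to the nearest voxel, ties toward the lower index). The dose
#' channel keeps only voxels receiving at least 30% of the prescription
#' (inclusive), zeroes the rest, zero-pads where the window leaves the
#' patient grid, and divides by the prescription. The mask channel is
#' truncated from the patient-level labels via [buildInputMask()]. If the
#' 30% isodose region extends beyond the window it is clipped and a
#' warning reports the clipped voxel count.
#'
#' @param dose a [DoseGrid-class] or 3D array of dose in Gy.
#' @param tumor_mask,skull_mask logical patient-grid arrays.
#' @param body_mask optional logical array, see [buildInputMask()].
#' @param rx_gy prescription dose in Gy.
#' @param window cubic window edge in voxels (default 128).
#' @param spacing_mm voxel spacing, taken from `dose` when it is a
#'   [DoseGrid-class].
#' @param lesion_id identifier for the resulting sample.
#' @param iso_fraction tumor-space isodose threshold (default 0.3).
#' @return A [TumorSpace-class].
#' @export
extractTumorSpace <- function(dose, tumor_mask, skull_mask,
                              body_mask = NULL, rx_gy, window = 128L,
                              spacing_mm = 0.5, lesion_id = "lesion",
                              iso_fraction = 0.3) {
  if (is(dose, "DoseGrid")) {
    spacing_mm <- dose@spacing_mm
    dose <- dose@voxels
  }
  if (!any(tumor_mask)) stop("empty tumor mask")
  if (!identical(dim(dose), dim(tumor_mask)))
    stop("dose and mask grids are not aligned")
  center <- roundCentroid(tumor_mask)
  win <- cropWindow(center, as.integer(window))

  thr <- iso_fraction * rx_gy
  in_space <- dose >= thr
  n_space <- sum(in_space)
  dw <- cropPad(dose, win)
  dw[dw < thr] <- 0
  n_kept <- sum(dw >= thr)
  if (n_kept < n_space)
    warning(sprintf("tumor space clipped by the window: %d voxels lost",
                    n_space - n_kept))
  if (n_kept == 0L)
    warning("entire dose lies below the tumor-space threshold")

  mask <- buildInputMask(tumor_mask, skull_mask, body_mask, win)
  tumorSpace(lesion_id, mask, dw / rx_gy, rx_gy, center, spacing_mm)
}

#' Organ-at-risk tolerance table
#'
#' Editable dose-tolerance configuration used by [filterNearOAR()]. The
#' shipped table carries the optical pathway entry (8 Gy to 2 cc, the
#' lowest cranial tolerance) plus commonly used placeholder values which
#' users should replace with institutional limits.
#'
#' @param path optional path to a custom CSV (columns organ_name,
#'   tolerance_gy, endpoint_kind).
#' @return data.frame of exclusion rules.
#' @export
oarToleranceTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "oar_tolerances.csv",
                        package = "GKDosePredict")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("organ_name", "tolerance_gy", "endpoint_kind") %in%
                names(tab)), all(tab$tolerance_gy > 0))
  tab
}

#' Exclusion filter for lesions near critical organs
#'
#' A lesion is excluded iff, for any organ, (a) the organ lies fully or
#' partially inside the lesion's tumor space AND (b) the organ's clinical
#' dose endpoint exceeds 50% of its tolerance. Brainstem lesions whose
#' prescription was already reduced to the brainstem tolerance are retained
#' when `brainstem_exception` is set. An organ listed in the rules but
#' missing from `oar_doses` is excluded conservatively.
#'
#' @param oar_in_space named logical vector: does each organ intersect the
#'   tumor space?
#' @param oar_doses named numeric vector of clinical endpoint doses (Gy).
#' @param rules data.frame of tolerances, see [oarToleranceTable()].
#' @param brainstem_exception retain brainstem cases planned to tolerance.
#' @return list with `keep` (logical) and `reason` (character).
#' @export
filterNearOAR <- function(oar_in_space, oar_doses,
                          rules = oarToleranceTable(),
                          brainstem_exception = FALSE) {
  for (i in seq_len(nrow(rules))) {
    organ <- rules$organ_name[i]
    if (!isTRUE(oar_in_space[organ])) next # condition (a) fails
    if (organ == "brainstem" && brainstem_exception)
      next # prescription already reduced to tolerance; no extra shaping
    if (!organ %in% names(oar_doses)) {
      message("no endpoint recorded for ", organ, "; excluding conservatively")
      return(list(keep = FALSE,
                  reason = paste0(organ, ": endpoint unknown")))
    }
    if (oar_doses[[organ]] > 0.5 * rules$tolerance_gy[i])
      return(list(keep = FALSE,
                  reason = sprintf("%s endpoint %.2f Gy > 50%% of %.2f Gy",
                                   organ, oar_doses[[organ]],
                                   rules$tolerance_gy[i])))
  }
  list(keep = TRUE, reason = "clear of critical organs")
}

#' Adjacency filter for lesion pairs
#'
#' Flags two lesions as adjacent when their dose distributions overlap such
#' that prescription-isodose (or half-prescription, for the gradient index)
#' attribution becomes ambiguous: some voxel receives at least Rx (resp.
#' 0.5 Rx) from both lesions' dose fields.
#'
#' @param dose_a,dose_b dose arrays on a common grid (Gy).
#' @param rx_a,rx_b the two prescriptions (Gy).
#' @return list with `adjacent`, `piv_overlap` and `piv50_overlap` flags.
#' @export
filterAdjacent <- function(dose_a, dose_b, rx_a, rx_b) {
  if (!identical(dim(dose_a), dim(dose_b)))
    stop("doses must share a grid")
  piv <- any(dose_a >= rx_a & dose_b >= rx_b)
  piv50 <- any(dose_a >= 0.5 * rx_a & dose_b >= 0.5 * rx_b)
  list(adjacent = piv || piv50, piv_overlap = piv, piv50_overlap = piv50)
}

#' Tumor spaces for a whole phantom cohort
#'
#' @param cases list of [LesionCase-class].
#' @param window cubic window edge (defaults to each case's own grid).
#' @return list of [TumorSpace-class].
#' @export
extractCohortSpaces <- function(cases, window = NULL) {
  lapply(cases, function(cs) {
    w <- if (is.null(window)) dim(cs@dose@voxels)[1] else window
    suppressWarnings(
      extractTumorSpace(cs@dose, cs@tumor_mask, cs@skull_mask,
                        rx_gy = cs@rx_gy, window = w,
                        lesion_id = cs@lesion_id))
  })
}
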