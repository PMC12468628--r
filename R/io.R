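# File formats: NIfTI volumes (RNifti), a focused DICOM RT-Dose reader,
# directory-based cohort / tumor-space containers with JSON manifests,
# and the run-configuration reader.

#' Write a dose volume to NIfTI
#'
#' @param dose a [DoseGrid-class] or 3D array.
#' @param path output path (.nii or .nii.gz).
#' @param spacing_mm voxel spacing when `dose` is a bare array.
#' @return The path, invisibly.
#' @export
writeDoseVolume <- function(dose, path, spacing_mm = 0.5) {
  if (is(dose, "DoseGrid")) {
    spacing_mm <- dose@spacing_mm
    dose <- dose@voxels
  }
  img <- RNifti::asNifti(dose)
  RNifti::pixdim(img) <- rep(spacing_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

isDicomFile <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 132)
  length(hdr) == 132 && rawToChar(hdr[129:132]) == "DICM"
}

#' Read a dose volume
#'
#' Dispatches on file content: DICOM RT-Dose objects go through
#' [readDicomRTDose()], anything else is read as a NIfTI scalar volume.
#'
#' @param path input file.
#' @return A [DoseGrid-class] with dose in Gy.
#' @export
readDoseVolume <- function(path) {
  if (isDicomFile(path)) return(readDicomRTDose(path))
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  doseGrid(array(as.numeric(img), dim(img)), spacing_mm = pd[1],
           origin_mm = c(0, 0, 0))
}

# --- minimal DICOM reader -------------------------------------------------
# Explicit/implicit VR little endian, enough to extract an RT-Dose grid:
# geometry tags, DoseGridScaling and the integer pixel data.

dcmUint <- function(raw, signed = FALSE) {
  sum(as.numeric(raw) * 256^(seq_along(raw) - 1)) -
    if (signed && as.integer(raw[length(raw)]) >= 128) 256^length(raw) else 0
}

readDicomElements <- function(bytes) {
  pos <- 133L # past the 128-byte preamble and "DICM"
  n <- length(bytes)
  elements <- list()
  explicit <- TRUE
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    group <- dcmUint(bytes[pos:(pos + 1L)])
    elem <- dcmUint(bytes[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    if (group != 0x0002 && !explicit) {
      len <- dcmUint(bytes[pos:(pos + 3L)])
      pos <- pos + 4L
      vr <- ""
    } else {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      if (grepl("^[A-Z]{2}$", vr)) {
        if (vr %in% long_vrs) {
          len <- dcmUint(bytes[(pos + 4L):(pos + 7L)])
          pos <- pos + 8L
        } else {
          len <- dcmUint(bytes[(pos + 2L):(pos + 3L)])
          pos <- pos + 4L
        }
      } else { # implicit VR after all (no valid VR bytes)
        len <- dcmUint(bytes[pos:(pos + 3L)])
        pos <- pos + 4L
        vr <- ""
      }
    }
    if (len == 0xFFFFFFFF)
      stop("undefined-length DICOM elements are not supported")
    if (pos + len - 1L > n) stop("truncated DICOM element")
    key <- sprintf("%04X,%04X", group, elem)
    elements[[key]] <- list(vr = vr,
                            value = bytes[seq.int(pos, length.out = len)])
    if (key == "0002,0010") {
      uid <- trimws(rawToStr(elements[[key]]$value))
      if (uid == "1.2.840.10008.1.2") explicit <- FALSE
      else if (uid != "1.2.840.10008.1.2.1")
        stop("unsupported DICOM transfer syntax: ", uid)
    }
    pos <- pos + len
  }
  elements
}

rawToStr <- function(r) rawToChar(r[r != as.raw(0)]) # strip NUL padding
dcmString <- function(el) trimws(rawToStr(el$value))
dcmNumbers <- function(el) as.numeric(strsplit(dcmString(el), "\\\\")[[1]])

#' Read a DICOM RT-Dose file
#'
#' Focused reader for axial RT-Dose grids in (explicit or implicit VR)
#' little-endian transfer syntax: applies DoseGridScaling to the stored
#' integers and populates grid spacing and origin from PixelSpacing,
#' GridFrameOffsetVector and ImagePositionPatient. The first array axis is
#' the DICOM column (x) direction, the second the row (y) direction, the
#' third the frame (z) direction. Any missing required tag raises an error
#' naming it.
#'
#' @param path DICOM file path.
#' @return A [DoseGrid-class] with dose in Gy.
#' @export
readDicomRTDose <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic)")
  el <- readDicomElements(bytes)
  need <- function(key, name) {
    if (is.null(el[[key]]))
      stop("required DICOM tag missing: ", name, " (", key, ")")
    el[[key]]
  }
  modality <- dcmString(need("0008,0060", "Modality"))
  if (modality != "RTDOSE")
    stop("not an RT-Dose object (Modality = ", modality, ")")
  rows <- dcmUint(need("0028,0010", "Rows")$value)
  cols <- dcmUint(need("0028,0011", "Columns")$value)
  frames <- as.integer(dcmString(need("0028,0008", "NumberOfFrames")))
  spacing <- dcmNumbers(need("0028,0030", "PixelSpacing"))
  offsets <- dcmNumbers(need("3004,000C", "GridFrameOffsetVector"))
  scaling <- dcmNumbers(need("3004,000E", "DoseGridScaling"))
  origin <- dcmNumbers(need("0020,0032", "ImagePositionPatient"))
  bits <- dcmUint(need("0028,0100", "BitsAllocated")$value)
  signed <- dcmUint(need("0028,0103", "PixelRepresentation")$value) == 1
  pix <- need("7FE0,0010", "PixelData")$value
  if (!bits %in% c(16, 32)) stop("unsupported BitsAllocated: ", bits)
  ints <- readBin(pix, "integer", n = rows * cols * frames,
                  size = bits / 8, signed = if (bits == 16) signed else TRUE,
                  endian = "little")
  if (bits == 32 && !signed) ints[ints < 0] <- ints[ints < 0] + 2^32
  dz <- if (length(offsets) > 1) diff(offsets[1:2]) else spacing[1]
  sp <- c(spacing[2], spacing[1], dz) # column, row, frame spacing
  if (max(sp) - min(sp) > 1e-6)
    warning("anisotropic RT-Dose grid; spacing_mm records the column pitch")
  # pixel data is row-major per frame: x (column) varies fastest
  arr <- array(as.numeric(ints) * scaling, dim = c(cols, rows, frames))
  doseGrid(arr, spacing_mm = sp[1], origin_mm = origin)
}

# --- directory containers -------------------------------------------------

writeJSON <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

# atomic directory write: assemble under a temporary sibling, then rename
withStagingDir <- function(dir, body) {
  stage <- paste0(dir, ".tmp", Sys.getpid())
  dir.create(stage, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  tryCatch({
    body(stage)
    if (dir.exists(dir)) unlink(dir, recursive = TRUE)
    ok <- file.rename(stage, dir)
  }, finally = if (!ok && dir.exists(stage)) unlink(stage, recursive = TRUE))
  invisible(dir)
}

#' Write / read a phantom cohort container
#'
#' One directory per cohort: a `manifest.json` with per-case attributes
#' (rx_gy, spacing, shots, ground-truth metrics) plus one NIfTI dose
#' volume and one label volume (codes 2 tumor / 1 skull / 0 background)
#' per case.
#'
#' @param cases list of [LesionCase-class].
#' @param dir container directory.
#' @return `readCohort()` returns the list of cases.
#' @export
writeCohort <- function(cases, dir) {
  withStagingDir(dir, function(stage) {
    manifest <- list(kind = "gk_phantom_cohort", n_cases = length(cases),
                     cases = lapply(cases, function(cs) {
      m <- cs@true_metrics
      list(lesion_id = cs@lesion_id, rx_gy = cs@rx_gy,
           spacing_mm = cs@dose@spacing_mm,
           origin_mm = cs@dose@origin_mm,
           shots = cs@shots,
           metrics = list(coverage = m@coverage,
                          selectivity = m@selectivity, gi = m@gi,
                          ci50 = m@ci50, tv_mm3 = m@tv_mm3,
                          piv_mm3 = m@piv_mm3, piv50_mm3 = m@piv50_mm3,
                          unavailable = I(m@unavailable)))
    }))
    for (cs in cases) {
      writeDoseVolume(cs@dose, file.path(stage,
                                         paste0(cs@lesion_id, "_dose.nii.gz")))
      lab <- array(0L, dim(cs@tumor_mask))
      lab[cs@skull_mask] <- 1L
      lab[cs@tumor_mask] <- 2L
      img <- RNifti::asNifti(lab)
      RNifti::pixdim(img) <- rep(cs@dose@spacing_mm, 3)
      RNifti::writeNifti(img, file.path(stage,
                                        paste0(cs@lesion_id, "_labels.nii.gz")))
    }
    writeJSON(manifest, file.path(stage, "manifest.json"))
  })
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  if (!identical(manifest$kind, "gk_phantom_cohort"))
    stop("not a cohort container")
  num <- function(x) as.numeric(unlist(x))
  lapply(manifest$cases, function(meta) {
    id <- meta$lesion_id
    dose <- readDoseVolume(file.path(dir, paste0(id, "_dose.nii.gz")))
    dose@origin_mm <- num(meta$origin_mm)
    lab <- RNifti::readNifti(file.path(dir, paste0(id, "_labels.nii.gz")))
    lab <- array(as.integer(lab), dim(lab))
    mm <- meta$metrics
    asn <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    pm <- new("PlanMetrics", coverage = asn(mm$coverage),
              selectivity = asn(mm$selectivity), gi = asn(mm$gi),
              ci50 = asn(mm$ci50), tv_mm3 = asn(mm$tv_mm3),
              piv_mm3 = asn(mm$piv_mm3), piv50_mm3 = asn(mm$piv50_mm3),
              unavailable = as.character(unlist(mm$unavailable)))
    shots <- do.call(rbind, lapply(meta$shots, function(s)
      as.data.frame(s, stringsAsFactors = FALSE)))
    new("LesionCase", lesion_id = id, rx_gy = num(meta$rx_gy),
        tumor_mask = lab == 2L, skull_mask = lab == 1L, dose = dose,
        shots = shots, true_metrics = pm)
  })
}

#' Write / read a tumor-space container
#'
#' One directory per dataset: `manifest.json` with ids, prescriptions and
#' spacings, plus per-lesion NIfTI volumes for the label mask and the
#' normalized dose. The round trip is lossless up to float storage of the
#' dose channel.
#'
#' @param spaces list of [TumorSpace-class].
#' @param dir container directory.
#' @return `readSpaces()` returns the list of spaces.
#' @export
writeSpaces <- function(spaces, dir) {
  withStagingDir(dir, function(stage) {
    manifest <- list(kind = "gk_tumor_spaces", n_spaces = length(spaces),
                     spaces = lapply(spaces, function(sp)
                       list(lesion_id = sp@lesion_id, rx_gy = sp@rx_gy,
                            spacing_mm = sp@spacing_mm,
                            center_index_patient = sp@center_index_patient)))
    for (sp in spaces) {
      img <- RNifti::asNifti(sp@input_mask)
      RNifti::pixdim(img) <- rep(sp@spacing_mm, 3)
      RNifti::writeNifti(img, file.path(stage,
                                        paste0(sp@lesion_id, "_mask.nii.gz")))
      img <- RNifti::asNifti(sp@dose_norm)
      RNifti::pixdim(img) <- rep(sp@spacing_mm, 3)
      RNifti::writeNifti(img, file.path(stage,
                                        paste0(sp@lesion_id, "_dose.nii.gz")))
    }
    writeJSON(manifest, file.path(stage, "manifest.json"))
  })
}

#' @rdname writeSpaces
#' @export
readSpaces <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  if (!identical(manifest$kind, "gk_tumor_spaces"))
    stop("not a tumor-space container; missing or foreign manifest")
  lapply(manifest$spaces, function(meta) {
    if (is.null(meta$rx_gy)) stop("manifest entry missing rx_gy")
    id <- meta$lesion_id
    mask <- RNifti::readNifti(file.path(dir, paste0(id, "_mask.nii.gz")))
    dose <- RNifti::readNifti(file.path(dir, paste0(id, "_dose.nii.gz")))
    tumorSpace(id, array(as.integer(mask), dim(mask)),
               array(as.numeric(dose), dim(dose)), as.numeric(meta$rx_gy),
               as.integer(unlist(meta$center_index_patient)),
               as.numeric(meta$spacing_mm))
  })
}

# --- run configuration ----------------------------------------------------

runConfigBlocks <- list(
  phantom = phantomSpec, prep = NULL, loss = lossConfig, net = netConfig,
  augment = augmentPolicy, train = trainConfig)

#' Default run configuration
#'
#' Nested named list with one block per pipeline stage; every default
#' equals the corresponding constructor default.
#'
#' @return Named list of blocks.
#' @export
defaultRunConfig <- function() {
  evalf <- function(f)
    lapply(as.list(formals(f)), function(x)
      if (is.language(x)) eval(x, envir = getNamespace("GKDosePredict"))
      else x)
  list(phantom = evalf(phantomSpec),
       prep = list(window = 128L, iso_fraction = 0.3),
       loss = evalf(lossConfig), net = evalf(netConfig),
       augment = evalf(augmentPolicy), train = evalf(trainConfig))
}

#' Read and validate a run configuration file
#'
#' YAML file with nested blocks {phantom, prep, loss, net, augment,
#' train}. Unknown blocks or keys are rejected; values are merged over the
#' constructor defaults and validated by constructing the corresponding
#' configuration objects.
#'
#' @param path YAML file.
#' @return list of validated configuration objects / lists.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(defaultRunConfig())
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown configuration blocks: ", paste(extra, collapse = ", "))
  out <- list()
  for (block in names(raw)) {
    ctor <- runConfigBlocks[[block]]
    if (is.null(ctor)) { # prep block: plain keys
      bad <- setdiff(names(raw[[block]]),
                     names(defaultRunConfig()[[block]]))
      if (length(bad))
        stop("unknown keys in block '", block, "': ",
             paste(bad, collapse = ", "))
      out[[block]] <- utils::modifyList(defaultRunConfig()[[block]],
                                        raw[[block]])
      next
    }
    bad <- setdiff(names(raw[[block]]), names(formals(ctor)))
    if (length(bad))
      stop("unknown keys in block '", block, "': ",
           paste(bad, collapse = ", "))
    out[[block]] <- do.call(ctor, raw[[block]])
  }
  out
}

#' Provenance record for a run
#'
#' Configuration hash, seed and version stamp sufficient to reproduce the
#' deterministic stages bit for bit.
#'
#' @param config any serializable configuration object or list.
#' @param seed the seed in force.
#' @return Named list.
#' @export
provenanceRecord <- function(config, seed) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  list(config_hash = unname(tools::md5sum(tmp)), seed = seed,
       package = "GKDosePredict",
       package_version = as.character(utils::packageVersion("GKDosePredict")),
       r_version = R.version.string, timestamp = format(Sys.time(),
                                                        tz = "UTC"))
}
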