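# Construct a tiny RT-Dose file with pydicom (independent writer) and a
# helper python that is part of the runtime image.
writeRTDoseFixture <- function(path, scaling = 0.0025, frames = 4,
                               rows = 5, cols = 6, modality = "RTDOSE") {
  script <- sprintf('
import numpy as np, pydicom
from pydicom.dataset import Dataset, FileDataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian
meta = FileMetaDataset()
meta.MediaStorageSOPClassUID = pydicom.uid.RTDoseStorage
meta.MediaStorageSOPInstanceUID = pydicom.uid.generate_uid()
meta.TransferSyntaxUID = ExplicitVRLittleEndian
ds = FileDataset(r"%s", {}, file_meta=meta, preamble=b"\\x00"*128)
ds.Modality = "%s"
ds.Rows, ds.Columns, ds.NumberOfFrames = %d, %d, "%d"
ds.PixelSpacing = ["0.5", "0.5"]
ds.ImagePositionPatient = ["-10", "-20", "-30"]
ds.GridFrameOffsetVector = [i * 0.5 for i in range(%d)]
ds.DoseGridScaling = "%g"
ds.BitsAllocated = 16
ds.BitsStored = 16
ds.HighBit = 15
ds.PixelRepresentation = 0
ds.SamplesPerPixel = 1
ds.PhotometricInterpretation = "MONOCHROME2"
arr = np.arange(%d, dtype=np.uint16).reshape(%d, %d, %d)
ds.PixelData = arr.tobytes()
ds.save_as(r"%s", enforce_file_format=True)
', path, modality, rows, cols, frames, frames, scaling,
    frames * rows * cols, frames, rows, cols, path)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = TRUE, stderr = TRUE)
  file.exists(path)
}

test_that("NIfTI dose volumes round-trip bit-identically", {
  d <- array(runif(8^3, 0, 20), rep(8L, 3))
  dg <- doseGrid(d, spacing_mm = 0.5)
  p <- tempfile(fileext = ".nii.gz")
  writeDoseVolume(dg, p)
  back <- readDoseVolume(p)
  expect_equal(back@voxels, d, tolerance = 0)
  expect_equal(back@spacing_mm, 0.5)
})

test_that("RT-Dose grid scaling and geometry are applied", {
  p <- tempfile(fileext = ".dcm")
  if (!writeRTDoseFixture(p, scaling = 0.0025))
    fail("could not construct the RT-Dose fixture")
  dg <- readDicomRTDose(p)
  # stored integers 0..(n-1) times the scaling, x fastest within a frame
  expect_identical(dim(dg@voxels), c(6L, 5L, 4L))
  expect_equal(dg@voxels[1, 1, 1], 0)
  expect_equal(dg@voxels[2, 1, 1], 0.0025)
  expect_equal(dg@voxels[1, 2, 1], 6 * 0.0025)
  expect_equal(dg@voxels[1, 1, 2], 30 * 0.0025)
  expect_equal(max(dg@voxels), (4 * 5 * 6 - 1) * 0.0025)
  expect_equal(dg@spacing_mm, 0.5)
  expect_equal(dg@origin_mm, c(-10, -20, -30))
  # content sniffing dispatches DICOM vs NIfTI automatically
  dg2 <- readDoseVolume(p)
  expect_equal(dg2@voxels, dg@voxels)
})

test_that("non-dose DICOM and missing tags raise typed errors", {
  p <- tempfile(fileext = ".dcm")
  if (!writeRTDoseFixture(p, modality = "MR"))
    fail("could not construct the DICOM fixture")
  expect_error(readDicomRTDose(p), "not an RT-Dose object")
  expect_error(readDoseVolume(tempfile(fileext = ".nii")), ".")
})

test_that("cohort containers round-trip all volumes and attributes", {
  cases <- generateCohort(smallPhantomSpec(seed = 13, n = 3))
  dir <- file.path(tempdir(), "cohort_rt")
  writeCohort(cases, dir)
  back <- readCohort(dir)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]@lesion_id, cases[[i]]@lesion_id)
    expect_equal(back[[i]]@rx_gy, cases[[i]]@rx_gy)
    expect_equal(back[[i]]@dose@voxels, cases[[i]]@dose@voxels,
                 tolerance = 0)
    expect_identical(back[[i]]@tumor_mask, cases[[i]]@tumor_mask)
    expect_identical(back[[i]]@skull_mask, cases[[i]]@skull_mask)
    expect_equal(back[[i]]@true_metrics@gi, cases[[i]]@true_metrics@gi)
    expect_equal(back[[i]]@shots$weight, cases[[i]]@shots$weight)
  }
  unlink(dir, recursive = TRUE)
})

test_that("tumor-space containers round-trip and validate their layout", {
  spaces <- extractCohortSpaces(generateCohort(smallPhantomSpec(seed = 14,
                                                                n = 3)))
  dir <- file.path(tempdir(), "spaces_rt")
  writeSpaces(spaces, dir)
  back <- readSpaces(dir)
  for (i in 1:3) {
    expect_identical(back[[i]]@input_mask, spaces[[i]]@input_mask)
    expect_equal(back[[i]]@dose_norm, spaces[[i]]@dose_norm, tolerance = 0)
    expect_equal(back[[i]]@rx_gy, spaces[[i]]@rx_gy)
  }
  # a manifest entry without rx_gy is rejected
  mf <- file.path(dir, "manifest.json")
  m <- jsonlite::read_json(mf)
  m$spaces[[1]]$rx_gy <- NULL
  jsonlite::write_json(m, mf, auto_unbox = TRUE)
  expect_error(readSpaces(dir), "rx_gy")
  unlink(dir, recursive = TRUE)
  expect_error(readSpaces(tempdir()), ".")
})

test_that("run configuration files reject unknown keys and round-trip", {
  cfgfile <- tempfile(fileext = ".yaml")
  writeLines(c("loss:", "  alpha: 50", "  beta: 5", "train:",
               "  epochs: 12", "  seed: 3"), cfgfile)
  cfg <- readRunConfig(cfgfile)
  expect_s4_class(cfg$loss, "LossConfig")
  expect_equal(cfg$loss@alpha, 50)
  expect_equal(cfg$loss@omega_in, 8) # untouched defaults remain
  expect_equal(cfg$train@epochs, 12L)
  writeLines(c("loss:", "  alpha: 50", "  gamma: 1"), cfgfile)
  expect_error(readRunConfig(cfgfile), "unknown keys")
  writeLines(c("nonsense:", "  a: 1"), cfgfile)
  expect_error(readRunConfig(cfgfile), "unknown configuration blocks")
})

test_that("provenance records are reproducible for identical configs", {
  p1 <- provenanceRecord(lossConfig(), seed = 5)
  p2 <- provenanceRecord(lossConfig(), seed = 5)
  expect_identical(p1$config_hash, p2$config_hash)
  p3 <- provenanceRecord(lossConfig(alpha = 1), seed = 5)
  expect_false(identical(p1$config_hash, p3$config_hash))
})

test_that("the command-line pipeline is deterministic end to end", {
  cli <- system.file("cli", "gkdose.R", package = "GKDosePredict")
  expect_true(nzchar(cli))
  run <- function(...) {
    out <- system2("Rscript", c(cli, ...), stdout = TRUE, stderr = TRUE,
                   env = paste0("R_LIBS=",
                                paste(.libPaths(), collapse = .Platform$path.sep)))
    if (is.null(attr(out, "status"))) attr(out, "status") <- 0L
    out
  }
  td <- tempdir()
  c1 <- file.path(td, "cli_cohort1"); c2 <- file.path(td, "cli_cohort2")
  m1 <- file.path(td, "m1.csv"); m2 <- file.path(td, "m2.csv")
  o <- run("simulate", "--n", "3", "--seed", "1", "--out", c1,
           "--grid", "32")
  expect_equal(attr(o, "status"), 0L)
  expect_length(readCohort(c1), 3)
  run("simulate", "--n", "3", "--seed", "1", "--out", c2, "--grid", "32")
  s1 <- file.path(td, "cli_spaces1")
  o <- run("prepare", "--in", c1, "--out", s1)
  expect_equal(attr(o, "status"), 0L)
  o <- run("metrics", "--in", c1, "--out", m1)
  expect_equal(attr(o, "status"), 0L)
  run("metrics", "--in", c2, "--out", m2)
  expect_identical(readLines(m1), readLines(m2))
  tab <- read.csv(m1)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("lesion_id", "coverage_pct", "gi", "group") %in%
                    names(tab)))
  # unknown flags and subcommands exit non-zero
  expect_equal(attr(run("simulate", "--bogus", "1"), "status"), 1L)
  expect_equal(attr(run("frobnicate"), "status"), 1L)
  unlink(c(c1, c2, s1, m1, m2), recursive = TRUE)
})
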