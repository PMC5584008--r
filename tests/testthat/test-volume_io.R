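test_that("NIfTI round trip preserves data, spacing and labels", {
  d <- c(8L, 8L, 8L)
  ramp <- array(seq_len(prod(d)) - 500, d)
  vol <- HUVolume(ramp, spacing = c(1.0, 0.66, 0.66))
  f <- tempfile(fileext = ".nii.gz")
  saveVolume(vol, f)
  back <- loadVolume(f)
  expect_identical(voxelData(back), voxelData(vol))
  expect_equal(spacing(back), c(1.0, 0.66, 0.66), tolerance = 1e-6)

  lab <- LabelMap(array(sample.int(5L, prod(d), replace = TRUE) - 1L, d))
  f2 <- tempfile(fileext = ".nii.gz")
  saveVolume(lab, f2, spacing = c(1, 1, 1))
  back2 <- loadLabelMap(f2)
  expect_identical(voxelData(back2), voxelData(lab))
})

test_that("a constant single-slice volume survives the round trip", {
  vol <- HUVolume(array(-1000, c(1L, 6L, 6L)))
  f <- tempfile(fileext = ".nii")
  saveVolume(vol, f)
  back <- loadVolume(f)
  expect_true(all(voxelData(back) == -1000))
  expect_identical(dim(voxelData(back)), c(1L, 6L, 6L))
})

test_that("loading a missing file or an invalid volume errors", {
  expect_error(loadVolume(tempfile(fileext = ".nii")), "not found")
  expect_error(HUVolume(array(c(1, NA), c(1, 1, 2))), "finite")
  expect_error(HUVolume(array(0, c(2, 2, 2)), downAxis = 1L), "in-slice")
})

# --- DICOM series through the pydicom bridge -----------------------------

writeSyntheticDicom <- function(dir, positions = c(0, 1, 2), slope = 1,
                                intercept = -1024, stored = 24) {
  script <- sprintf('
import pydicom, numpy as np, os, sys
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
outdir = sys.argv[1]
positions = [%s]
series = generate_uid()
for i, zp in enumerate(positions):
    ds = Dataset()
    ds.SOPClassUID = "1.2.840.10008.5.1.4.1.1.2"
    ds.SOPInstanceUID = generate_uid()
    ds.SeriesInstanceUID = series
    ds.Modality = "CT"
    ds.InstanceNumber = i + 1
    ds.Rows = 4; ds.Columns = 4
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 0
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.RescaleSlope = %f; ds.RescaleIntercept = %f
    ds.PixelSpacing = [0.66, 0.66]
    ds.SliceThickness = 1.0
    ds.ImageOrientationPatient = [1,0,0,0,1,0]
    ds.ImagePositionPatient = [0, 0, zp]
    ds.PixelData = (np.ones((4,4), dtype=np.uint16) * %d).tobytes()
    meta = FileMetaDataset()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    meta.MediaStorageSOPClassUID = ds.SOPClassUID
    meta.MediaStorageSOPInstanceUID = ds.SOPInstanceUID
    ds.file_meta = meta
    ds.save_as(os.path.join(outdir, "slice%%03d.dcm" %% i),
               write_like_original=False)
', paste(positions, collapse = ","), slope, intercept, stored)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, shQuote(dir)), stdout = TRUE,
                    stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0)
    stop("fixture generation failed: ", paste(status, collapse = "\n"))
  invisible(dir)
}

test_that("a DICOM series is rescaled to HU and ordered by position", {
  dir <- tempfile(); dir.create(dir)
  writeSyntheticDicom(dir, positions = c(2, 0, 1))
  vol <- loadVolume(dir, format = "dicom_dir")
  expect_identical(dim(voxelData(vol)), c(3L, 4L, 4L))
  expect_true(all(voxelData(vol) == 24 - 1024))   # slope 1, intercept -1024
  expect_equal(spacing(vol), c(1.0, 0.66, 0.66), tolerance = 1e-6)
})

test_that("duplicate slice positions are rejected as an ordering error", {
  dir <- tempfile(); dir.create(dir)
  writeSyntheticDicom(dir, positions = c(0, 0, 1))
  expect_error(loadVolume(dir, format = "dicom_dir"), "non-monotone")
})
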