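# Volume I/O: NIfTI-1 through RNifti; DICOM series through the
# pre-installed python + pydicom stack (inst/python/dicom_to_raw.py).
# Everything downstream consumes the canonical (slice, down, right) axis
# order established here.

#' Read a CT volume
#'
#' Loads a 3-D CT volume in Hounsfield units from a NIfTI-1 file or a
#' DICOM series directory. DICOM stored values are calibrated with the
#' rescale slope/intercept; slices are ordered along the normal of the
#' shared image orientation. The array is returned in the canonical
#' (slice, down, right) axis order with the down axis defaulting to the
#' second (in-slice row) axis, i.e. the scanner table at the image bottom.
#'
#' @param path a `.nii`/`.nii.gz` file or a DICOM directory.
#' @param format "auto" (by path type), "nifti" or "dicom_dir".
#' @param downAxis in-slice axis pointing toward the table (2 or 3);
#'   override when the acquisition deviates from the usual row-down
#'   orientation.
#' @return an \linkS4class{HUVolume}.
#' @export
loadVolume <- function(path, format = c("auto", "nifti", "dicom_dir"),
                       downAxis = 2L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  if (format == "nifti") {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    dat <- array(as.numeric(img), dim(img))
    if (length(dim(dat)) != 3L) stop("expected a 3-D volume: ", path)
    sp <- RNifti::pixdim(img)
    v <- HUVolume(dat, spacing = sp[seq_len(3)], downAxis = downAxis)
  } else {
    v <- .loadDicomDir(path, downAxis)
  }
  validObject(v)
  v
}

.pythonBin <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found for DICOM reading")
  py
}

.loadDicomDir <- function(path, downAxis) {
  if (!dir.exists(path)) stop("DICOM directory not found: ", path)
  script <- system.file("python", "dicom_to_raw.py", package = "ecleanse")
  stopifnot(nzchar(script))
  raw <- tempfile(fileext = ".raw")
  hdr <- tempfile(fileext = ".json")
  on.exit(unlink(c(raw, hdr)), add = TRUE)
  status <- suppressWarnings(
    system2(.pythonBin(), c(script, shQuote(path), shQuote(raw),
                            shQuote(hdr)),
            stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0)
    stop("DICOM reading failed: ", paste(status, collapse = " "))
  meta <- jsonlite::read_json(hdr, simplifyVector = TRUE)
  n <- prod(meta$shape)
  dat <- readBin(raw, what = "numeric", n = n, size = 8, endian = "little")
  dat <- array(dat, dim = meta$shape)   # written in column-major order
  HUVolume(dat, spacing = meta$spacing, downAxis = downAxis)
}

#' Write a volume or label map
#'
#' Saves an \linkS4class{HUVolume} (floating point) or
#' \linkS4class{LabelMap} (32-bit integer) as NIfTI-1. A saved file read
#' back with [loadVolume()] reproduces the grid, spacing and values
#' exactly.
#'
#' @param vol an \linkS4class{HUVolume} or \linkS4class{LabelMap}.
#' @param path output `.nii` or `.nii.gz` path.
#' @param spacing spacing to record for a LabelMap (mm).
#' @return `path`, invisibly.
#' @export
setGeneric("saveVolume", function(vol, path, ...) standardGeneric("saveVolume"))

#' @rdname saveVolume
#' @export
setMethod("saveVolume", "HUVolume", function(vol, path, ...) {
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@spacing
  tryCatch(RNifti::writeNifti(img, path, datatype = "double"),
           error = function(e) stop("cannot write volume: ",
                                    conditionMessage(e)))
  invisible(path)
})

#' @rdname saveVolume
#' @export
setMethod("saveVolume", "LabelMap", function(vol, path, spacing = c(1, 1, 1), ...) {
  img <- RNifti::asNifti(array(as.integer(vol@data), dim(vol@data)))
  RNifti::pixdim(img) <- spacing
  tryCatch(RNifti::writeNifti(img, path, datatype = "int32"),
           error = function(e) stop("cannot write label map: ",
                                    conditionMessage(e)))
  invisible(path)
})

#' Read a label map
#'
#' @param path NIfTI file written by [saveVolume()].
#' @param legend optional named character vector of label names.
#' @return a \linkS4class{LabelMap}.
#' @export
loadLabelMap <- function(path, legend = character()) {
  img <- RNifti::readNifti(path)
  LabelMap(array(as.integer(img), dim(img)), legend = legend)
}
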