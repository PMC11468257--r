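# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O in base R.
#
# Only what a PET SUV pipeline needs: axis-aligned 3-D grids, voxel spacing
# from pixdim, origin from the sform (or qoffset) translation. No support for
# oblique orientations, .hdr/.img pairs or extensions. The writer emits
# float32 for SUV and uint8 for masks with sform_code = 1 and an identity
# rotation, which every mainstream reader (nibabel, SimpleITK, FSL) accepts.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352

nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

nifti_read <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rb")   # transparently handles plain and gzipped files
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", NIFTI_HDR_SIZE)
  if (length(raw_hdr) < NIFTI_HDR_SIZE) {
    stop("not a NIfTI-1 file (truncated header): ", path, call. = FALSE)
  }
  endian <- "little"
  sizeof_hdr <- readBin(raw_hdr[1:4], "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != NIFTI_HDR_SIZE) {
    endian <- "big"
    sizeof_hdr <- readBin(raw_hdr[1:4], "integer", 1L, size = 4L, endian = endian)
    if (sizeof_hdr != NIFTI_HDR_SIZE) {
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
    }
  }
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("not a NIfTI-1 file (bad magic): ", path, call. = FALSE)
  }
  rd_i16 <- function(off, n) readBin(raw_hdr[(off + 1):(off + 2L * n)],
                                     "integer", n, size = 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(raw_hdr[(off + 1):(off + 4L * n)],
                                     "double", n, size = 4L, endian = endian)
  dim8 <- rd_i16(40L, 8L)
  ndim <- dim8[1]
  if (ndim < 3L) stop("image is not 3-D: ", path, call. = FALSE)
  shape <- dim8[2:(ndim + 1L)]
  if (ndim > 3L) {
    if (any(shape[4:ndim] > 1L)) stop("image is not 3-D: ", path, call. = FALSE)
    shape <- shape[1:3]
  }
  datatype <- rd_i16(70L, 1L)
  spec <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE)
  pixdim <- rd_f32(76L, 8L)
  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("non-positive voxel spacing in NIfTI header: ", path, call. = FALSE)
  }
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  qform_code <- rd_i16(252L, 1L)
  sform_code <- rd_i16(254L, 1L)
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    srow <- matrix(rd_f32(280L, 12L), nrow = 3L, byrow = TRUE)
    offdiag <- srow[, 1:3]; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-4 * max(spacing))) {
      stop("oblique (non axis-aligned) NIfTI orientations are not supported",
           call. = FALSE)
    }
    origin <- srow[, 4]
  } else if (qform_code > 0L) {
    origin <- rd_f32(268L, 3L)
  }
  skip <- max(0, round(vox_offset) - NIFTI_HDR_SIZE)
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, spec$what, n, size = spec$size, signed = spec$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data section: ", path, call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(values = array(as.double(vals), dim = shape),
       spacing = spacing, origin = origin)
}

nifti_write <- function(values, spacing, origin, path, datatype = 16L) {
  dir <- dirname(path)
  if (!nzchar(dir) || !dir.exists(dir)) {
    stop("cannot write NIfTI file, directory does not exist: ", path, call. = FALSE)
  }
  shape <- dim(values)
  hdr <- raw(NIFTI_HDR_SIZE)
  put <- function(hdr, off, x, what, size) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0L, NIFTI_HDR_SIZE, "integer", 4L)
  hdr <- put(hdr, 40L, as.integer(c(3L, shape, 1L, 1L, 1L, 1L)), "integer", 2L)
  bitpix <- switch(as.character(datatype), `2` = 8L, `16` = 32L, `64` = 64L,
                   stop("unsupported write datatype ", datatype, call. = FALSE))
  hdr <- put(hdr, 70L, as.integer(datatype), "integer", 2L)
  hdr <- put(hdr, 72L, bitpix, "integer", 2L)
  hdr <- put(hdr, 76L, c(1, spacing, 0, 0, 0, 0), "double", 4L)
  hdr <- put(hdr, 108L, NIFTI_VOX_OFFSET, "double", 4L)
  hdr <- put(hdr, 112L, 1, "double", 4L)   # scl_slope
  hdr <- put(hdr, 116L, 0, "double", 4L)   # scl_inter
  hdr <- put(hdr, 252L, 0L, "integer", 2L) # qform_code
  hdr <- put(hdr, 254L, 1L, "integer", 2L) # sform_code
  srow <- rbind(c(spacing[1], 0, 0, origin[1]),
                c(0, spacing[2], 0, origin[2]),
                c(0, 0, spacing[3], origin[3]))
  hdr <- put(hdr, 280L, as.double(t(srow)), "double", 4L)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)  # pad to vox_offset = 352
  if (datatype == 2L) {
    writeBin(as.integer(values), con, size = 1L, endian = "little")
  } else {
    writeBin(as.double(values), con, size = bitpix %/% 8L, endian = "little")
  }
  invisible(path)
}

#' Read an SUV volume from a NIfTI-1 file
#'
#' Voxel spacing is taken from the header `pixdim`, the origin from the sform
#' (or qform) translation; SUV values are returned unmodified (float32
#' round-off aside, the writer/reader pair is an identity). Axis order is
#' `(i,j,k)` matching world `(x,y,z)`.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3-D image.
#' @return An [suv_volume()].
#' @export
load_suv_volume <- function(path) {
  nf <- nifti_read(path)
  suv_volume(nf$values, spacing = nf$spacing, origin = nf$origin)
}

#' Write an SUV volume to a NIfTI-1 file (float64)
#'
#' Voxel data are stored as float64 so values round-trip bit-exactly; the
#' header geometry (pixdim, sform) is float32 by the NIfTI-1 format, so
#' spacing/origin round-trip to single precision (~1e-7 relative).
#'
#' @param vol an [suv_volume()].
#' @param path destination `.nii` (or `.nii.gz`) path.
#' @return `path`, invisibly.
#' @export
save_suv_volume <- function(vol, path) {
  stopifnot(inherits(vol, "suv_volume"))
  nifti_write(vol$values, vol$spacing, vol$origin, path, datatype = 64L)
}

#' Read a binary mask from a NIfTI-1 file
#' @param path path to a `.nii` / `.nii.gz` file with values in \{0, 1\}.
#' @param reference optional [suv_volume()] the mask must align with (shape
#'   check; geometry copied from the file itself).
#' @return A [tumor_mask()].
#' @export
load_mask <- function(path, reference = NULL) {
  nf <- nifti_read(path)
  if (!all(nf$values %in% c(0, 1))) {
    stop("mask file contains values other than 0/1: ", path, call. = FALSE)
  }
  m <- tumor_mask(nf$values != 0, spacing = nf$spacing, origin = nf$origin)
  if (!is.null(reference) && !identical(dim(m$values), dim(reference$values))) {
    stop("mask shape does not match the reference volume", call. = FALSE)
  }
  m
}

#' Write a binary mask to a NIfTI-1 file (uint8, values 0/1)
#' @param mask a [tumor_mask()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tumor_mask"))
  nifti_write(mask$values, mask$spacing, mask$origin, path, datatype = 2L)
}
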