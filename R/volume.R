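#' SUV volume container
#'
#' A 3-D grid of standardized uptake values (SUV, unitless, body-weight
#' normalized) together with the voxel spacing and the world position of the
#' centre of voxel (1,1,1). All physical quantities are in millimetres; the
#' voxel-centre convention is used throughout, so the world position of voxel
#' `(i,j,k)` (1-based) is `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @param values numeric 3-D array of SUV; must be finite and non-negative.
#' @param spacing numeric length-3, voxel edge lengths `(dx, dy, dz)` in mm;
#'   all strictly positive. Anisotropic grids (e.g. the clinical
#'   4.07 x 4.07 x 2.5 mm PET grid) are the normal case.
#' @param origin numeric length-3, world coordinates (mm) of the centre of
#'   voxel (1,1,1).
#' @return An object of class `suv_volume`.
#' @seealso [tumor_mask()], [voxel_to_world()], [load_suv_volume()]
#' @export
suv_volume <- function(values, spacing = c(4.07, 4.07, 2.5), origin = c(0, 0, 0)) {
  values <- as_array3d(values, "values")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three finite, strictly positive values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("origin must be three finite values (mm)", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("SUV values must all be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("SUV values must be non-negative", call. = FALSE)
  }
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "suv_volume")
}

#' Binary tumour mask aligned to an SUV volume
#'
#' @param values logical (or 0/1 numeric) 3-D array.
#' @param spacing,origin geometry, identical to the parent [suv_volume()].
#' @param reference optional `suv_volume` or `tumor_mask` whose geometry is
#'   copied and whose shape the mask must match.
#' @return An object of class `tumor_mask`.
#' @export
tumor_mask <- function(values, spacing = c(4.07, 4.07, 2.5), origin = c(0, 0, 0),
                       reference = NULL) {
  values <- as_array3d(values, "values")
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1))) {
      stop("mask values must be logical or 0/1", call. = FALSE)
    }
    values <- array(values != 0, dim = dim(values))
  }
  if (!is.null(reference)) {
    if (!identical(dim(values), dim(reference$values))) {
      stop("mask shape does not match its reference volume", call. = FALSE)
    }
    spacing <- reference$spacing
    origin <- reference$origin
  }
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "tumor_mask")
}

as_array3d <- function(x, what) {
  if (is.null(dim(x)) || length(dim(x)) != 3L) {
    stop(sprintf("%s must be a 3-D array", what), call. = FALSE)
  }
  x
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<suv_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  SUV range [%.3g, %.3g], origin (%.3g, %.3g, %.3g) mm\n",
              min(x$values), max(x$values), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
print.tumor_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<tumor_mask> %d x %d x %d voxels, %d set, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], sum(x$values),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Map voxel indices to world coordinates
#'
#' Voxel-centre convention: world = origin + (idx - 1) * spacing, componentwise.
#' Distances between returned points are therefore Euclidean distances in mm on
#' the scanner grid.
#'
#' @param vol a `suv_volume` or `tumor_mask` supplying the geometry.
#' @param idx integer matrix with 3 columns (one row per voxel) or a length-3
#'   vector; 1-based indices.
#' @return numeric matrix with columns `(x, y, z)` in mm (a single row for a
#'   single index).
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- rbind_idx(idx)
  d <- dim(vol$values)
  if (any(idx < 1L) || any(idx[, 1] > d[1]) || any(idx[, 2] > d[2]) ||
      any(idx[, 3] > d[3])) {
    stop("voxel index out of bounds", call. = FALSE)
  }
  sweep(sweep(idx - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

rbind_idx <- function(idx) {
  if (is.null(dim(idx))) {
    if (length(idx) != 3L) stop("voxel index must have 3 components", call. = FALSE)
    idx <- matrix(idx, nrow = 1L)
  }
  if (ncol(idx) != 3L) stop("voxel index matrix must have 3 columns", call. = FALSE)
  storage.mode(idx) <- "double"
  dimnames(idx) <- NULL
  idx
}

# World coordinates (n x 3) of all TRUE voxels of a mask.
mask_world_coords <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE)
  voxel_to_world(mask, idx)
}

#' Volume of one voxel in cubic millimetres
#' @param vol a `suv_volume` or `tumor_mask`.
#' @return scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$spacing)
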