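#' Conventional PET features: SUVmax, SUVpeak, MTV, TLG
#'
#' SUVpeak follows the usual ~1 cm^3 sphere convention: candidate sphere
#' centres are the mask voxel centres; for each candidate the mean SUV is
#' taken over all voxels whose centres lie within a sphere of volume
#' `peak_sphere_volume_cm3`, including non-mask voxels; positions outside the
#' grid contribute 0 with the full-sphere denominator (zero padding), so
#' placements truncated by the grid edge are never favoured. The maximum of
#' these means is SUVpeak and the maximizing centre is `peak_center`; ties
#' break toward the lexicographically smallest centre index. Lesions smaller
#' than the sphere are rejected, mirroring the usual < 1 cm^3 exclusion rule.
#'
#' @param vol an [suv_volume()].
#' @param mask segmented lesion, a [tumor_mask()] aligned with `vol`.
#' @param peak_sphere_volume_cm3 volume of the SUVpeak sphere (default 1.0).
#' @return A list of class `conventional_features` with `suv_max`,
#'   `suv_max_voxel` (1-based i,j,k), `suv_peak`, `peak_center` (world mm),
#'   `mtv_cm3` and `tlg`.
#' @export
conventional_features <- function(vol, mask, peak_sphere_volume_cm3 = 1.0) {
  stopifnot(inherits(vol, "suv_volume"), inherits(mask, "tumor_mask"))
  if (!identical(dim(vol$values), dim(mask$values))) {
    stop("mask shape does not match the volume", call. = FALSE)
  }
  if (!any(mask$values)) stop("mask is empty", call. = FALSE)
  mtv_cm3 <- sum(mask$values) * voxel_volume_mm3(vol) / 1000
  if (mtv_cm3 < peak_sphere_volume_cm3) {
    stop(sprintf(
      "lesion too small for SUVpeak: MTV %.3g cm^3 < sphere volume %.3g cm^3",
      mtv_cm3, peak_sphere_volume_cm3), call. = FALSE)
  }
  mx <- suvmax_voxel(vol, mask$values)
  tlg <- mean(vol$values[mask$values]) * mtv_cm3

  r_mm <- (3 * peak_sphere_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  sp <- vol$spacing
  ranges <- lapply(1:3, function(a) -floor(r_mm / sp[a]):floor(r_mm / sp[a]))
  offs <- as.matrix(expand.grid(ranges[[1]], ranges[[2]], ranges[[3]]))
  keep <- (offs[, 1] * sp[1])^2 + (offs[, 2] * sp[2])^2 + (offs[, 3] * sp[3])^2 <=
    r_mm^2
  offs <- offs[keep, , drop = FALSE]

  d <- dim(vol$values)
  centers <- which(mask$values, arr.ind = TRUE)
  # deterministic tie-break: scan candidates in lexicographic (i,j,k) order
  centers <- centers[order(centers[, 1], centers[, 2], centers[, 3]), , drop = FALSE]
  no <- nrow(offs)
  best <- -Inf; best_row <- 1L
  chunk_rows <- max(1L, floor(4e6 / no))
  for (start in seq(1L, nrow(centers), by = chunk_rows)) {
    end <- min(nrow(centers), start + chunk_rows - 1L)
    cc <- centers[start:end, , drop = FALSE]
    nc <- nrow(cc)
    pi_ <- rep(cc[, 1], each = no) + rep(offs[, 1], times = nc)
    pj <- rep(cc[, 2], each = no) + rep(offs[, 2], times = nc)
    pk <- rep(cc[, 3], each = no) + rep(offs[, 3], times = nc)
    inb <- pi_ >= 1L & pi_ <= d[1] & pj >= 1L & pj <= d[2] & pk >= 1L & pk <= d[3]
    lin <- pi_ + (pj - 1L) * d[1] + (pk - 1L) * (d[1] * d[2])
    if (all(inb)) {
      means <- colMeans(matrix(vol$values[lin], nrow = no))
    } else {
      vals <- numeric(length(lin))          # zero padding outside the grid
      vals[inb] <- vol$values[lin[inb]]
      means <- colMeans(matrix(vals, nrow = no))
    }
    w <- which(means > best)
    if (length(w) > 0L) {
      best_local <- w[which.max(means[w])]
      # strict '>' keeps the first (lexicographically smallest) maximizer
      if (means[best_local] > best) {
        best <- means[best_local]
        best_row <- start + best_local - 1L
      }
    }
  }
  peak_center <- drop(voxel_to_world(vol, centers[best_row, , drop = FALSE]))

  structure(list(suv_max = mx$suv,
                 suv_max_voxel = mx$idx,
                 suv_peak = best,
                 peak_center = peak_center,
                 mtv_cm3 = mtv_cm3,
                 tlg = tlg),
            class = "conventional_features")
}

#' Radius of the sphere with the lesion's volume
#' @param mtv_cm3 metabolic tumour volume in cm^3 (> 0).
#' @return Radius in mm: `(3 V / 4 pi)^(1/3)` with V in mm^3.
#' @export
equivalent_sphere_radius <- function(mtv_cm3) {
  if (!is.finite(mtv_cm3) || mtv_cm3 <= 0) {
    stop("mtv_cm3 must be positive", call. = FALSE)
  }
  (3 * mtv_cm3 * 1000 / (4 * pi))^(1 / 3)
}

#' Geometric centroid of a mask
#'
#' Unweighted mean of the world centres of the mask voxels. An SUV-weighted
#' variant is available for sensitivity analyses.
#'
#' @param mask a nonempty [tumor_mask()].
#' @param vol optional [suv_volume()]; required when `weighted = TRUE`.
#' @param weighted if `TRUE`, weight voxel centres by SUV.
#' @return World point `(x, y, z)` in mm.
#' @export
mask_centroid <- function(mask, vol = NULL, weighted = FALSE) {
  stopifnot(inherits(mask, "tumor_mask"))
  if (!any(mask$values)) stop("mask is empty", call. = FALSE)
  coords <- mask_world_coords(mask)
  if (weighted) {
    if (is.null(vol)) stop("weighted centroid needs the SUV volume", call. = FALSE)
    w <- vol$values[mask$values]
    colSums(coords * w) / sum(w)
  } else {
    colMeans(coords)
  }
}

#' Minimum distance from a point to the mask perimeter
#'
#' The perimeter is the set of mask voxels with at least one face-adjacent
#' non-mask neighbour (the array border counting as outside); the distance is
#' the minimum Euclidean distance in mm from `p` to their voxel centres.
#'
#' @param p world point `(x, y, z)` in mm.
#' @param mask a nonempty [tumor_mask()].
#' @return scalar distance in mm.
#' @export
min_surface_distance <- function(p, mask) {
  stopifnot(inherits(mask, "tumor_mask"))
  if (!any(mask$values)) stop("mask is empty", call. = FALSE)
  bnd <- which(boundary_voxels(mask$values), arr.ind = TRUE)
  coords <- voxel_to_world(mask, bnd)
  min_dist_to_points(matrix(as.numeric(p), nrow = 1L), coords)
}

#' Normalized hotspot-to-centroid and hotspot-to-perimeter distances
#'
#' Computes the four geometry parameters: distances from the SUVmax voxel and
#' from the SUVpeak sphere centre to the (geometric) tumour centroid and to
#' the tumour perimeter, each divided by the radius R of the sphere having the
#' lesion's volume. NHOC/NHOP are dimensionless and deliberately *not*
#' clamped to `[0, 1]` — elongated lesions can exceed 1.
#'
#' @param vol an [suv_volume()].
#' @param mask the segmented lesion.
#' @param conv [conventional_features()] computed from the same `vol`/`mask`;
#'   computed on the fly when `NULL`.
#' @param weighted_centroid use the SUV-weighted centroid instead of the
#'   geometric one (default `FALSE`).
#' @return A list of class `hotspot_geometry`: `centroid`, `equiv_radius_mm`,
#'   `nhoc_max`, `nhoc_peak`, `nhop_max`, `nhop_peak`.
#' @export
hotspot_geometry <- function(vol, mask, conv = NULL, weighted_centroid = FALSE) {
  if (is.null(conv)) conv <- conventional_features(vol, mask)
  ctr <- mask_centroid(mask, vol = vol, weighted = weighted_centroid)
  R <- equivalent_sphere_radius(conv$mtv_cm3)
  pmax_w <- drop(voxel_to_world(vol, matrix(conv$suv_max_voxel, nrow = 1L)))
  ppeak_w <- conv$peak_center
  structure(list(
    centroid = ctr,
    equiv_radius_mm = R,
    nhoc_max = sqrt(sum((pmax_w - ctr)^2)) / R,
    nhoc_peak = sqrt(sum((ppeak_w - ctr)^2)) / R,
    nhop_max = min_surface_distance(pmax_w, mask) / R,
    nhop_peak = min_surface_distance(ppeak_w, mask) / R),
    class = "hotspot_geometry")
}

#' One CSV-ready feature row for a patient
#'
#' Runs segmentation and both feature families and returns a single-row
#' data frame with the columns the cohort statistics expect.
#'
#' @param id patient identifier.
#' @param vol an [suv_volume()].
#' @param voi initial VOI mask.
#' @param background optional background mask (default shell otherwise).
#' @param cfg a [seg_config()].
#' @param weighted_centroid see [hotspot_geometry()].
#' @return data.frame with columns `id, suv_max, suv_peak, mtv_cm3, tlg,
#'   nhoc_max, nhoc_peak, nhop_max, nhop_peak, threshold_suv`.
#' @export
extract_features <- function(id, vol, voi, background = NULL,
                             cfg = seg_config(), weighted_centroid = FALSE) {
  seg <- segment_tumor(vol, voi, background, cfg)
  conv <- conventional_features(vol, seg$mask)
  geo <- hotspot_geometry(vol, seg$mask, conv,
                          weighted_centroid = weighted_centroid)
  data.frame(id = id,
             suv_max = conv$suv_max,
             suv_peak = conv$suv_peak,
             mtv_cm3 = conv$mtv_cm3,
             tlg = conv$tlg,
             nhoc_max = geo$nhoc_max,
             nhoc_peak = geo$nhoc_peak,
             nhop_max = geo$nhop_max,
             nhop_peak = geo$nhop_peak,
             threshold_suv = seg$threshold_suv,
             stringsAsFactors = FALSE)
}
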