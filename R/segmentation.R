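#' Segmentation configuration
#'
#' Parameters of the adaptive-threshold (Nestle) delineation. The threshold is
#' `threshold_slope * mean(SUV of VOI voxels with SUV > high_uptake_fraction *
#' SUVmax) + mean(background SUV)`; defaults are the published constants 0.30
#' and 0.70.
#'
#' @param high_uptake_fraction fraction of SUVmax defining the hot core;
#'   strict inequality is used (default 0.70).
#' @param threshold_slope multiplier on the hot-core mean SUV (default 0.30).
#' @param background_shell_mm inner/outer distances (mm) of the default
#'   background shell around the initial VOI (default `c(8, 16)`).
#' @param connectivity neighbourhood for the lesion component: 6, 18 or 26
#'   (default 26, the permissive standard for blob-like lesions).
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(high_uptake_fraction = 0.70, threshold_slope = 0.30,
                       background_shell_mm = c(8, 16), connectivity = 26L) {
  if (!(high_uptake_fraction > 0 && high_uptake_fraction < 1)) {
    stop("high_uptake_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (threshold_slope <= 0) stop("threshold_slope must be positive", call. = FALSE)
  background_shell_mm <- as.numeric(background_shell_mm)
  if (length(background_shell_mm) != 2L ||
      background_shell_mm[1] >= background_shell_mm[2] ||
      background_shell_mm[1] < 0) {
    stop("background_shell_mm must be (inner, outer) with 0 <= inner < outer",
         call. = FALSE)
  }
  connectivity <- as.integer(connectivity)
  connectivity_offsets(connectivity)  # validates
  structure(list(high_uptake_fraction = high_uptake_fraction,
                 threshold_slope = threshold_slope,
                 background_shell_mm = background_shell_mm,
                 connectivity = connectivity),
            class = "seg_config")
}

#' Default background shell around an initial VOI
#'
#' The published threshold formula needs a "mean SUV of background" but leaves
#' the background region undefined; the default here is the shell of voxels
#' whose Euclidean distance (voxel centre to nearest VOI voxel centre) lies in
#' `[inner, outer)` mm, excluding the VOI itself — a stand-in for adjacent
#' normal breast tissue. Supply your own mask to [nestle_threshold()] to
#' override it.
#'
#' @param voi initial lesion VOI, a [tumor_mask()] (nonempty).
#' @param cfg a [seg_config()].
#' @return A [tumor_mask()] marking the shell.
#' @export
default_background_shell <- function(voi, cfg = seg_config()) {
  stopifnot(inherits(voi, "tumor_mask"))
  if (!any(voi$values)) stop("VOI is empty", call. = FALSE)
  inner <- cfg$background_shell_mm[1]; outer <- cfg$background_shell_mm[2]
  # exact voxel-centre-to-VOI distances via the separable distance transform
  dist <- distance_to_mask_mm(voi$values, voi$spacing)
  shell <- !voi$values & dist >= inner & dist < outer
  if (!any(shell)) {
    stop(paste0("background shell is empty (lesion touches the image border?); ",
                "supply a background mask explicitly"), call. = FALSE)
  }
  tumor_mask(shell, spacing = voi$spacing, origin = voi$origin)
}

# Lexicographically smallest row of an (n x 3) index matrix: deterministic
# reference voxel when SUVmax is tied.
lex_min_idx <- function(idx) {
  idx[order(idx[, 1], idx[, 2], idx[, 3])[1L], ]
}

# Index (i,j,k) of the SUVmax voxel within a logical region.
suvmax_voxel <- function(vol, region) {
  vals <- vol$values[region]
  mx <- max(vals)
  hit <- which(region & vol$values == mx, arr.ind = TRUE)
  list(idx = as.integer(lex_min_idx(hit)), suv = mx)
}

#' Adaptive (Nestle) SUV threshold
#'
#' Computes `threshold = slope * mean(hot core) + mean(background)` where the
#' hot core is the set of VOI voxels with SUV strictly above
#' `high_uptake_fraction * SUVmax(VOI)`.
#'
#' @param vol an [suv_volume()].
#' @param voi initial VOI mask (nonempty).
#' @param background background mask; `NULL` uses [default_background_shell()].
#' @param cfg a [seg_config()].
#' @return A list with `threshold_suv`, `suv_max_in_voi`, `hot_core_mean`,
#'   `background_mean` and the `background` mask used.
#' @export
nestle_threshold <- function(vol, voi, background = NULL, cfg = seg_config()) {
  stopifnot(inherits(vol, "suv_volume"), inherits(voi, "tumor_mask"))
  if (!identical(dim(vol$values), dim(voi$values))) {
    stop("VOI shape does not match the volume", call. = FALSE)
  }
  if (!any(voi$values)) stop("VOI is empty", call. = FALSE)
  if (is.null(background)) background <- default_background_shell(voi, cfg)
  if (!any(background$values)) stop("background mask is empty", call. = FALSE)
  if (any(voi$values & background$values)) {
    stop("VOI and background masks overlap", call. = FALSE)
  }
  mx <- suvmax_voxel(vol, voi$values)
  if (mx$suv <= 0) stop("no uptake inside the VOI (SUVmax <= 0)", call. = FALSE)
  hot <- voi$values & vol$values > cfg$high_uptake_fraction * mx$suv
  hot_mean <- mean(vol$values[hot])
  bg_mean <- mean(vol$values[background$values])
  list(threshold_suv = cfg$threshold_slope * hot_mean + bg_mean,
       suv_max_in_voi = mx$suv,
       hot_core_mean = hot_mean,
       background_mean = bg_mean,
       background = background)
}

#' Delineate the lesion at a given SUV threshold
#'
#' Keeps the VOI voxels with SUV strictly above the threshold and returns the
#' connected component (per `cfg$connectivity`) containing the SUVmax voxel.
#'
#' @param vol an [suv_volume()].
#' @param voi initial VOI mask.
#' @param threshold_suv SUV cutoff (>= 0).
#' @param cfg a [seg_config()].
#' @return A [tumor_mask()] of the delineated lesion (always nonempty).
#' @export
segment_lesion <- function(vol, voi, threshold_suv, cfg = seg_config()) {
  stopifnot(inherits(vol, "suv_volume"), inherits(voi, "tumor_mask"))
  if (!is.finite(threshold_suv) || threshold_suv < 0) {
    stop("threshold_suv must be a non-negative number", call. = FALSE)
  }
  if (!any(voi$values)) stop("VOI is empty", call. = FALSE)
  mx <- suvmax_voxel(vol, voi$values)
  if (threshold_suv >= mx$suv) {
    stop(sprintf("lesion not delineable: threshold %.3g >= SUVmax %.3g",
                 threshold_suv, mx$suv), call. = FALSE)
  }
  above <- voi$values & vol$values > threshold_suv
  comp <- connected_component(above, mx$idx, cfg$connectivity)
  tumor_mask(comp, spacing = vol$spacing, origin = vol$origin)
}

#' Full adaptive-threshold segmentation
#'
#' Convenience wrapper: threshold via [nestle_threshold()], delineation via
#' [segment_lesion()].
#'
#' @inheritParams nestle_threshold
#' @return A list of class `segmentation_result`: `mask`, `threshold_suv`,
#'   `suv_max_in_voi`, `hot_core_mean`, `background_mean`.
#' @export
segment_tumor <- function(vol, voi, background = NULL, cfg = seg_config()) {
  th <- nestle_threshold(vol, voi, background, cfg)
  mask <- segment_lesion(vol, voi, th$threshold_suv, cfg)
  structure(list(mask = mask,
                 threshold_suv = th$threshold_suv,
                 suv_max_in_voi = th$suv_max_in_voi,
                 hot_core_mean = th$hot_core_mean,
                 background_mean = th$background_mean),
            class = "segmentation_result")
}
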