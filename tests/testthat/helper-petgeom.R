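# Fixture builders and independent oracles. The oracles deliberately use the
# dumbest possible algorithm (nested loops, exhaustive enumeration) so they
# share no code path with the implementation they check.

# Digitized sphere mask on an isotropic grid: voxel centres within radius_mm
# of the grid centre. Returns the mask plus the centre (world mm).
make_sphere_mask <- function(radius_mm, spacing = 1, pad = 3L) {
  n <- 2L * (ceiling(radius_mm / spacing) + pad) + 1L
  ctr <- (n - 1) / 2 * spacing
  ax <- (seq_len(n) - 1) * spacing - ctr
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  mask <- tumor_mask(d2 <= radius_mm^2, spacing = rep(spacing, 3),
                     origin = c(0, 0, 0))
  list(mask = mask, center = rep(ctr, 3), n = n)
}

# Toy volume for the adaptive threshold: a line of six VOI voxels with SUVs
# {10, 8, 7.5, 6, 4, 2} and a separate constant background region.
make_nestle_toy <- function(bg_value = 0.5) {
  vals <- array(0, dim = c(8L, 5L, 5L))
  suvs <- c(10, 8, 7.5, 6, 4, 2)
  voi <- array(FALSE, dim = dim(vals))
  for (i in seq_along(suvs)) {
    vals[i + 1L, 3L, 3L] <- suvs[i]
    voi[i + 1L, 3L, 3L] <- TRUE
  }
  bg <- array(FALSE, dim = dim(vals))
  bg[, , 1L] <- TRUE
  vals[, , 1L] <- bg_value
  list(vol = suv_volume(vals, spacing = c(1, 1, 1)),
       voi = tumor_mask(voi, spacing = c(1, 1, 1)),
       bg = tumor_mask(bg, spacing = c(1, 1, 1)))
}

# Random connected-ish blob mask: union of a few digitized balls.
random_blob_mask <- function(dim3, spacing = c(1, 1, 1), n_balls = 3L) {
  m <- array(FALSE, dim = dim3)
  ax <- lapply(1:3, function(a) (seq_len(dim3[a]) - 1) * spacing[a])
  for (b in seq_len(n_balls)) {
    c_idx <- sapply(dim3, function(n) sample.int(n, 1L))
    r <- runif(1, 1.5, max(3, min(dim3 * spacing) / 3))
    cw <- (c_idx - 1) * spacing
    d2 <- outer(outer((ax[[1]] - cw[1])^2, (ax[[2]] - cw[2])^2, `+`),
                (ax[[3]] - cw[3])^2, `+`)
    m <- m | (d2 <= r^2)
  }
  tumor_mask(m, spacing = spacing, origin = c(0, 0, 0))
}

# Oracle: minimum distance from world point p to the face-boundary voxel
# centres of the mask, by explicit loops.
oracle_surface_distance <- function(p, mask) {
  d <- dim(mask$values)
  best <- Inf
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask$values[i, j, k]) next
    on_boundary <- FALSE
    for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1))) {
      q <- c(i, j, k) + step
      if (any(q < 1L) || any(q > d) || !mask$values[q[1], q[2], q[3]]) {
        on_boundary <- TRUE
        break
      }
    }
    if (on_boundary) {
      w <- mask$origin + (c(i, j, k) - 1) * mask$spacing
      best <- min(best, sqrt(sum((p - w)^2)))
    }
  }
  best
}

# Oracle: AUC by exhaustive positive-negative pair counting, ties 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (x in pos) for (y in neg) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

# Run the segmentation + geometry chain on a phantom and return the features.
extract_phantom_geometry <- function(ph, cfg = seg_config()) {
  seg <- segment_tumor(ph$volume, ph$voi, cfg = cfg)
  conv <- conventional_features(ph$volume, seg$mask)
  geo <- hotspot_geometry(ph$volume, seg$mask, conv)
  list(seg = seg, conv = conv, geo = geo)
}

# seg_config with a tight background shell for small 1 mm test grids (the
# default 8-16 mm shell would fall outside them).
fine_grid_cfg <- function() seg_config(background_shell_mm = c(2, 6))
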