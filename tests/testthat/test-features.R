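# Conventional SUV features and the hotspot-distance geometry.

test_that("equivalent sphere radius has the closed form", {
  expect_equal(equivalent_sphere_radius(4 / 3 * pi), 10.0)
  expect_equal(equivalent_sphere_radius(1), 6.2035, tolerance = 1e-4)
  expect_equal(equivalent_sphere_radius(8 * 2.5), 2 * equivalent_sphere_radius(2.5))
  expect_error(equivalent_sphere_radius(0), "positive")
})

test_that("centroid is the unweighted mean of voxel centres", {
  arr <- array(FALSE, c(5, 5, 5)); arr[3, 2, 4] <- TRUE
  m1 <- tumor_mask(arr, spacing = c(4.07, 4.07, 2.5), origin = c(0, 0, 0))
  expect_equal(mask_centroid(m1), c(2 * 4.07, 1 * 4.07, 3 * 2.5))

  arr2 <- array(FALSE, c(5, 5, 5)); arr2[1, 1, 1] <- TRUE; arr2[3, 1, 1] <- TRUE
  m2 <- tumor_mask(arr2, spacing = c(4.07, 4.07, 2.5))
  expect_equal(mask_centroid(m2), c(4.07, 0, 0))   # x = (0 + 8.14) / 2

  sph <- make_sphere_mask(8, spacing = 1)
  expect_true(all(abs(mask_centroid(sph$mask) - sph$center) < 0.5))

  # SUV-weighted variant shifts toward the bright side
  vals <- array(1, dim(arr2)); vals[3, 1, 1] <- 9
  vol <- suv_volume(vals, spacing = c(4.07, 4.07, 2.5))
  expect_gt(mask_centroid(m2, vol, weighted = TRUE)[1], 4.07)
})

test_that("surface distance matches the exhaustive boundary oracle", {
  sph <- make_sphere_mask(10, spacing = 1)
  d_ctr <- min_surface_distance(sph$center, sph$mask)
  expect_equal(d_ctr, oracle_surface_distance(sph$center, sph$mask))
  expect_true(abs(d_ctr - 10) <= 1)
  # at a boundary voxel centre the distance is zero
  bvox <- which(petgeom:::boundary_voxels(sph$mask$values), arr.ind = TRUE)[1, ]
  expect_equal(min_surface_distance(drop(voxel_to_world(sph$mask, bvox)), sph$mask), 0)
  # moving radially outward shrinks the distance monotonically
  ds <- sapply(c(0, 3, 6, 9), function(r)
    min_surface_distance(sph$center + c(r, 0, 0), sph$mask))
  expect_true(all(diff(ds) < 0))
})

test_that("surface distance equals the oracle on random masks", {
  set.seed(31)
  for (r in 1:10) {
    m <- random_blob_mask(sample(6:12, 3, replace = TRUE),
                          spacing = runif(3, 0.8, 4))
    if (!any(m$values)) next
    p <- runif(3, -2, 10)
    expect_equal(min_surface_distance(p, m), oracle_surface_distance(p, m),
                 tolerance = 1e-12)
  }
})

test_that("uniform lesions give SUVmax = SUVpeak and TLG = mean * MTV", {
  n <- 20L
  vals <- array(0, c(n, n, n))
  mask_arr <- array(FALSE, c(n, n, n)); mask_arr[4:17, 4:17, 4:17] <- TRUE
  vals[mask_arr] <- 3.5
  vol <- suv_volume(vals, spacing = c(1, 1, 1))
  mask <- tumor_mask(mask_arr, spacing = c(1, 1, 1))
  cf <- conventional_features(vol, mask)
  expect_equal(cf$suv_max, 3.5)
  expect_equal(cf$suv_peak, 3.5)       # a fully interior sphere sees only 3.5
  expect_equal(cf$mtv_cm3, 14^3 / 1000)
  expect_equal(cf$tlg, 3.5 * cf$mtv_cm3)
})

test_that("SUVpeak averages down a single hot voxel", {
  n <- 20L
  vals <- array(1, c(n, n, n))
  vals[10, 10, 10] <- 11
  vol <- suv_volume(vals, spacing = c(1, 1, 1))
  mask <- tumor_mask(array(TRUE, c(n, n, n)), spacing = c(1, 1, 1))
  cf <- conventional_features(vol, mask)
  # oracle: sphere voxel count at 1 mm for a 1 cm^3 sphere
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  offs <- expand.grid(-7:7, -7:7, -7:7)
  n_sph <- sum(rowSums(offs^2) <= r^2)
  expect_equal(cf$suv_peak, 1 + 10 / n_sph)
  # every tied maximizer contains the hot voxel; the reported centre must too
  expect_lte(sqrt(sum((cf$peak_center - c(9, 9, 9))^2)), r)
  expect_true(cf$suv_peak < cf$suv_max && cf$suv_peak > 1)
})

test_that("lesions below the sphere volume are rejected", {
  vals <- array(2, c(6, 6, 6))
  mask_arr <- array(FALSE, c(6, 6, 6)); mask_arr[3:4, 3:4, 3:4] <- TRUE
  expect_error(
    conventional_features(suv_volume(vals, spacing = c(2, 2, 2)),
                          tumor_mask(mask_arr, spacing = c(2, 2, 2))),
    "too small")
})

test_that("hotspot geometry recovers the spherical construction", {
  # digitized sphere, radius 10 mm, hotspot at fractional radius f
  sph <- make_sphere_mask(10, spacing = 1)
  base <- array(0, dim(sph$mask$values))
  base[sph$mask$values] <- 1
  for (f in c(0, 0.5)) {
    vals <- base
    hot_idx <- round(sph$center / 1) + 1 + c(round(f * 10), 0, 0)
    vals[hot_idx[1], hot_idx[2], hot_idx[3]] <- 5
    vol <- suv_volume(vals, spacing = c(1, 1, 1))
    geo <- hotspot_geometry(vol, sph$mask)
    expect_true(abs(geo$nhoc_max - f) <= 0.1)
    expect_true(abs(geo$nhop_max - (1 - f)) <= 0.1)
    expect_true(abs(geo$nhoc_max + geo$nhop_max - 1) <= 0.1)
  }
})

test_that("geometry is invariant to SUV scale and equivariant to spacing", {
  set.seed(32)
  m <- random_blob_mask(c(14, 14, 14), spacing = c(1, 1, 1), n_balls = 2L)
  m$values[2:13, 2:13, 2:13] <- m$values[2:13, 2:13, 2:13] |
    (array(runif(12^3), c(12, 12, 12)) < 0.9)   # ensure > 1 cm^3
  vals <- array(runif(14^3, 1, 10), c(14, 14, 14))
  vol <- suv_volume(vals, spacing = c(1, 1, 1))
  g1 <- hotspot_geometry(vol, m)
  # SUV scale invariance
  g2 <- hotspot_geometry(suv_volume(vals * 7.3, spacing = c(1, 1, 1)), m)
  for (p in c("nhoc_max", "nhoc_peak", "nhop_max", "nhop_peak")) {
    expect_equal(g2[[p]], g1[[p]])
  }
  # isotropic spacing scale: all raw distances and R scale together, the
  # normalized parameters do not move (peak sphere scaled to keep the same
  # voxel support)
  s <- 2
  vol_s <- suv_volume(vals, spacing = rep(s, 3))
  m_s <- tumor_mask(m$values, spacing = rep(s, 3))
  conv1 <- conventional_features(vol, m, peak_sphere_volume_cm3 = 1)
  conv_s <- conventional_features(vol_s, m_s, peak_sphere_volume_cm3 = s^3)
  g1b <- hotspot_geometry(vol, m, conv1)
  g2b <- hotspot_geometry(vol_s, m_s, conv_s)
  expect_equal(g2b$equiv_radius_mm, s * g1b$equiv_radius_mm)
  for (p in c("nhoc_max", "nhoc_peak", "nhop_max", "nhop_peak")) {
    expect_equal(g2b[[p]], g1b[[p]], tolerance = 1e-10)
  }
})

test_that("SUVmax and SUVpeak ties resolve deterministically", {
  vals <- array(4, c(20, 20, 20))
  mask <- tumor_mask(array(TRUE, c(20, 20, 20)), spacing = c(1, 1, 1))
  cf <- conventional_features(suv_volume(vals, spacing = c(1, 1, 1)), mask)
  expect_equal(cf$suv_max_voxel, c(1L, 1L, 1L))
  # zero padding penalizes truncated placements, so the tied maximizers are
  # the fully interior centres; the lexicographically smallest is (7,7,7)
  expect_equal(cf$peak_center, c(6, 6, 6))
  cf2 <- conventional_features(suv_volume(vals, spacing = c(1, 1, 1)), mask)
  expect_identical(cf2$peak_center, cf$peak_center)
})
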