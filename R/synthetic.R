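# Synthetic phantoms and cohorts with known ground truth.
#
# The generator states a world and sticks to it: lesion geometry on the
# clinical 4.07 x 4.07 x 2.5 mm PET grid, a hotspot whose eccentricity
# (fraction of the centroid-to-surface ray) is the single true geometric
# driver, and outcomes wired to that TRUE geometry through a logistic link
# (response) and a proportional-hazards link (progression), so that feature
# extraction error attenuates effects the way it would in a real cohort.

#' Marginals of the reference clinical cohort
#'
#' Cohort-level counts and proportions used as defaults by [cohort_spec()]:
#' 135 patients, 32 complete responders (23.7%), 34 progression events
#' (25.2%), 92.6% node-positive, the molecular-subtype mix, and the
#' follow-up window. These are aggregate targets only; no patient-level
#' fidelity is claimed.
#'
#' @return A named list of counts, rates (percent) and category proportions.
#' @export
study_cohort_profile <- function() {
  list(
    n = 135L,
    pcr_n = 32L, pcr_rate_pct = 23.7,
    event_n = 34L, event_rate_pct = 25.2,
    median_age = 47, age_range = c(27, 79),
    premenopausal_prop = 0.556,
    idc_prop = 0.963,
    grade_props = c(`Grade 1` = 0.089, `Grade 2` = 0.556, `Grade 3` = 0.333,
                    `Not specified` = 0.022),
    subtype_props = c(`Luminal A` = 0.200, `Luminal B` = 0.526,
                      `HER2-enriched` = 0.141, `Triple negative` = 0.133),
    t34_prop = 0.400,
    n13_prop = 0.926,
    median_ki67_pct = 30,
    followup_months = c(min = 5.6, median = 60.0, max = 137.3)
  )
}

#' Phantom specification
#'
#' An ellipsoidal lesion of constant base uptake carrying a Gaussian hotspot
#' at eccentricity `eccentricity` along a fixed ray from the lesion centre
#' toward the surface (0 = central hotspot, -> 1 = rim hotspot), on a low
#' noisy background.
#'
#' @param shape grid dimensions (voxels).
#' @param spacing voxel spacing in mm; default is the clinical PET grid
#'   `c(4.07, 4.07, 2.5)`; use `c(1, 1, 1)` for fine-grid convergence tests.
#' @param semi_axes_mm ellipsoid semi-axes (mm); a sphere when all equal.
#' @param center_mm lesion centre in world mm (`NULL` = grid centre).
#' @param eccentricity hotspot position as a fraction of the
#'   centre-to-surface ray, in `[0, 1)`.
#' @param ray unit-free direction of that ray (normalized internally).
#' @param lesion_suv base SUV inside the lesion.
#' @param hotspot_peak_suv amplitude added at the hotspot centre.
#' @param hotspot_width_mm Gaussian sd of the hotspot bump (mm).
#' @param background_suv mean background SUV.
#' @param noise_sd sd of additive Gaussian noise (applied last, everywhere).
#' @param psf_fwhm_mm optional isotropic Gaussian blur FWHM applied before
#'   noise; 0 disables.
#' @param seed RNG seed for the noise (`NULL` = leave RNG state alone).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 24), spacing = c(4.07, 4.07, 2.5),
                         semi_axes_mm = c(12, 12, 12), center_mm = NULL,
                         eccentricity = 0.5, ray = c(1, 0, 0),
                         lesion_suv = 4, hotspot_peak_suv = 6,
                         hotspot_width_mm = 4, background_suv = 0.5,
                         noise_sd = 0.1, psf_fwhm_mm = 0, seed = NULL) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  if (any(shape < 4L)) stop("grid too small", call. = FALSE)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (any(semi_axes_mm <= 0)) stop("semi-axes must be positive", call. = FALSE)
  if (!(eccentricity >= 0 && eccentricity < 1)) {
    stop("eccentricity must lie in [0, 1)", call. = FALSE)
  }
  if (lesion_suv < 0 || background_suv < 0 || hotspot_peak_suv < 0 ||
      noise_sd < 0) {
    stop("SUV levels and noise sd must be non-negative", call. = FALSE)
  }
  if (sqrt(sum(ray^2)) == 0) stop("ray must be a nonzero direction", call. = FALSE)
  if (is.null(center_mm)) center_mm <- (shape - 1) / 2 * spacing
  extent <- shape * spacing
  if (any(center_mm - semi_axes_mm < -spacing / 2) ||
      any(center_mm + semi_axes_mm > extent - spacing / 2)) {
    stop("lesion does not fit inside the grid", call. = FALSE)
  }
  structure(list(shape = shape, spacing = spacing,
                 semi_axes_mm = as.numeric(semi_axes_mm),
                 center_mm = as.numeric(center_mm),
                 eccentricity = eccentricity,
                 ray = ray / sqrt(sum(ray^2)),
                 lesion_suv = lesion_suv, hotspot_peak_suv = hotspot_peak_suv,
                 hotspot_width_mm = hotspot_width_mm,
                 background_suv = background_suv, noise_sd = noise_sd,
                 psf_fwhm_mm = psf_fwhm_mm, seed = seed),
            class = "phantom_spec")
}

#' Named phantom presets
#'
#' `"central"` and `"rim"` are calibrated so the extracted NHOCmax lands near
#' 0.27 and 0.78 respectively — the two clinical regimes used throughout the
#' documentation (a central-hotspot responder-like lesion versus a
#' rim-hotspot non-responder-like lesion).
#'
#' @param name `"central"` or `"rim"`.
#' @param ... overrides passed on to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(name = c("central", "rim"), ...) {
  name <- match.arg(name)
  eps <- switch(name, central = 0.27, rim = 0.78)
  phantom_spec(eccentricity = eps, seed = 1L, ...)
}

# Separable Gaussian blur; sigma in voxel units per axis. Edge handling:
# kernel renormalized over the in-grid support.
gaussian_blur3d <- function(x, sigma_vox) {
  d <- dim(x)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    num <- array(0, dim = d); den <- array(0, dim = d)
    for (t in -r:r) {
      w <- k[t + r + 1L]
      idx_to <- lapply(d, seq_len); idx_from <- idx_to
      n <- d[ax]
      if (t > 0) { idx_to[[ax]] <- (t + 1L):n; idx_from[[ax]] <- 1L:(n - t) }
      if (t < 0) { idx_to[[ax]] <- 1L:(n + t); idx_from[[ax]] <- (1L - t):n }
      num[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
        num[idx_to[[1]], idx_to[[2]], idx_to[[3]]] +
        w * x[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
      den[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
        den[idx_to[[1]], idx_to[[2]], idx_to[[3]]] + w
    }
    x <- num / den
  }
  x
}

#' Generate a digital lesion phantom
#'
#' Builds the SUV volume described by a [phantom_spec()], the initial VOI
#' (lesion bounding box dilated by 2 voxels) and the ground truth. Uptake is
#' `lesion_suv + hotspot_peak_suv * exp(-d^2 / (2 w^2))` inside the lesion
#' (d = distance to the true hotspot position) and `background_suv` outside;
#' optional PSF blur is applied before the additive Gaussian noise; negative
#' values are clipped at 0. Deterministic for a fixed `seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([suv_volume()]), `voi` ([tumor_mask()]) and
#'   `truth` (true eccentricity, hotspot position, centre, analytic lesion
#'   volume in cm^3, ray).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  d <- spec$shape; sp <- spec$spacing
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  cx <- spec$center_mm; ax <- spec$semi_axes_mm
  ex <- ((xs - cx[1]) / ax[1])^2
  ey <- ((ys - cx[2]) / ax[2])^2
  ez <- ((zs - cx[3]) / ax[3])^2
  q <- outer(outer(ex, ey, `+`), ez, `+`)
  inside <- q <= 1

  # hotspot centre: eccentric fraction of the centre-to-surface ray
  u <- spec$ray
  t_surface <- 1 / sqrt(sum((u / ax)^2))
  hot <- cx + spec$eccentricity * t_surface * u
  dx2 <- outer(outer((xs - hot[1])^2, (ys - hot[2])^2, `+`), (zs - hot[3])^2, `+`)
  vals <- array(spec$background_suv, dim = d)
  bump <- spec$hotspot_peak_suv * exp(-dx2 / (2 * spec$hotspot_width_mm^2))
  vals[inside] <- spec$lesion_suv + bump[inside]
  if (spec$psf_fwhm_mm > 0) {
    vals <- gaussian_blur3d(vals, spec$psf_fwhm_mm / 2.35482 / sp)
  }
  if (spec$noise_sd > 0) {
    vals <- vals + array(stats::rnorm(prod(d), sd = spec$noise_sd), dim = d)
  }
  vals[vals < 0] <- 0
  vol <- suv_volume(vals, spacing = sp, origin = c(0, 0, 0))

  li <- which(inside, arr.ind = TRUE)
  lo <- pmax(1L, apply(li, 2, min) - 2L)
  hi <- pmin(d, apply(li, 2, max) + 2L)
  voi_arr <- array(FALSE, dim = d)
  voi_arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  voi <- tumor_mask(voi_arr, spacing = sp, origin = c(0, 0, 0))

  truth <- list(eccentricity = spec$eccentricity,
                hotspot_mm = hot, center_mm = cx,
                semi_axes_mm = ax,
                volume_cm3 = 4 / 3 * pi * prod(ax) / 1000,
                ray = u, t_surface_mm = t_surface)
  list(volume = vol, voi = voi, truth = truth)
}

#' Cohort specification
#'
#' States the simulated world for a patient cohort: the distribution of true
#' hotspot eccentricity, lesion sizes and uptake levels, covariate marginals
#' (defaults from [study_cohort_profile()]), and the outcome links. Response
#' follows `logit P(pCR) = beta0 + beta_nhoc * eps (+ covariate terms)`;
#' progression follows an exponential proportional-hazards model with linear
#' predictor `gamma_nhoc_peak * true_nhoc_peak + gamma_mtv * volume_cm3` and
#' uniform censoring on `(0, censoring_window_months)`. Intercept and
#' baseline hazard are calibrated (deterministically, given the drawn
#' geometry) to the target pCR and event rates unless given explicitly.
#'
#' @param n number of patients (>= 2).
#' @param eps_dist eccentricity distribution: `list(type = "beta", shape1,
#'   shape2, max)` (default Beta(2,2) scaled to `[0, 0.95]`),
#'   `list(type = "uniform", min, max)`, or `list(type = "two_group", means,
#'   sd, prob)` mixing a central-hotspot and a rim-hotspot group.
#' @param volume_meanlog,volume_sdlog log-normal lesion volume (cm^3).
#' @param min_volume_cm3 truncation floor, default 1.2 (keeps lesions above
#'   the 1 cm^3 SUVpeak exclusion).
#' @param suvmax_meanlog,suvmax_sdlog log-normal SUVmax.
#' @param peak_offset_ratio true NHOCpeak as a fraction of true NHOCmax
#'   (the peak sphere centre sits slightly inward of the max voxel).
#' @param feature_noise_sd sd of the measurement noise added to the true
#'   geometry when emitting extracted-like feature columns.
#' @param beta0 logistic intercept (`NULL` = calibrate to `target_pcr_rate`).
#' @param beta_nhoc logistic slope on true eccentricity (default -3: higher
#'   eccentricity, lower response odds).
#' @param beta_cov named numeric of optional covariate effects on the logit:
#'   `age` (per year), `t34`, `n13`, `tn` (triple negative); default all 0.
#' @param target_pcr_rate mean response probability for calibration.
#' @param gamma_nhoc_peak log-hazard per 1.00 of true NHOCpeak (default 1.5).
#' @param gamma_mtv log-hazard per cm^3 (default `log(1.012)`).
#' @param baseline_hazard events/month (`NULL` = calibrate to
#'   `target_event_rate`).
#' @param target_event_rate mean probability of an observed event.
#' @param censoring_window_months uniform censoring window (> 0).
#' @param phantom_shape,phantom_spacing,phantom_noise_sd geometry of emitted
#'   phantoms (only used when phantoms are written).
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 135L,
                        eps_dist = list(type = "beta", shape1 = 2, shape2 = 2,
                                        max = 0.95),
                        volume_meanlog = log(5), volume_sdlog = 0.6,
                        min_volume_cm3 = 1.2,
                        suvmax_meanlog = log(8), suvmax_sdlog = 0.4,
                        peak_offset_ratio = 0.8,
                        feature_noise_sd = 0.03,
                        beta0 = NULL, beta_nhoc = -3,
                        beta_cov = c(age = 0, t34 = 0, n13 = 0, tn = 0),
                        target_pcr_rate = 0.237,
                        gamma_nhoc_peak = 1.5, gamma_mtv = log(1.012),
                        baseline_hazard = NULL, target_event_rate = 0.252,
                        censoring_window_months = 137.3,
                        phantom_shape = c(32, 32, 24),
                        phantom_spacing = c(4.07, 4.07, 2.5),
                        phantom_noise_sd = 0.1,
                        seed = 1L) {
  if (n < 2L) stop("need n >= 2 patients", call. = FALSE)
  if (censoring_window_months <= 0) {
    stop("censoring window must be positive", call. = FALSE)
  }
  if (target_pcr_rate <= 0 || target_pcr_rate >= 1 ||
      target_event_rate <= 0 || target_event_rate >= 1) {
    stop("target rates must lie in (0, 1)", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_spec")
}

draw_eps <- function(dist, n) {
  switch(dist$type,
         beta = dist$max * stats::rbeta(n, dist$shape1, dist$shape2),
         uniform = stats::runif(n, dist$min, dist$max),
         two_group = {
           g <- stats::rbinom(n, 1L, if (is.null(dist$prob)) 0.5 else dist$prob)
           pmin(0.95, pmax(0, stats::rnorm(n, mean = dist$means[g + 1L],
                                           sd = dist$sd)))
         },
         stop("unknown eps_dist type: ", dist$type, call. = FALSE))
}

# P(T <= C) for T ~ Exp(lambda), C ~ U(0, W), averaged over patients.
expected_event_rate <- function(log_h0, lp, W) {
  lam <- exp(log_h0 + lp)
  mean(1 - (1 - exp(-lam * W)) / (lam * W))
}

#' Generate a synthetic cohort
#'
#' Draws per-patient geometry and covariates from a [cohort_spec()], wires
#' the outcomes to the TRUE geometry, and emits a cohort table whose feature
#' columns are the true values plus measurement noise (extracted-like).
#' Optionally writes one phantom (volume + VOI NIfTI pair) per patient so the
#' full imaging pipeline can be exercised on the same cohort.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir if non-`NULL`, write `cohort.csv`, `truth.csv`, a
#'   `manifest.txt` and (when `write_phantoms`) the per-patient NIfTI files
#'   there.
#' @param write_phantoms also synthesize and write per-patient phantoms
#'   (spherical lesions with the drawn volume and eccentricity, random ray).
#' @return list with `cohort` (data.frame), `truth` (data.frame) and `spec`.
#' @export
generate_cohort <- function(spec, out_dir = NULL, write_phantoms = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  prof <- study_cohort_profile()

  eps <- draw_eps(spec$eps_dist, n)
  volume <- exp(stats::rnorm(n, spec$volume_meanlog, spec$volume_sdlog))
  if (all(volume < 1)) {
    stop("infeasible cohort spec: all lesions below 1 cm^3 (SUVpeak exclusion)",
         call. = FALSE)
  }
  volume <- pmax(volume, spec$min_volume_cm3)
  suv_max_true <- exp(stats::rnorm(n, spec$suvmax_meanlog, spec$suvmax_sdlog))
  peak_eps <- spec$peak_offset_ratio * eps

  age <- round(pmin(79, pmax(27, stats::rnorm(n, prof$median_age, 11))))
  menopausal <- ifelse(stats::runif(n) < prof$premenopausal_prop,
                       "Premenopausal", "Postmenopausal")
  histology <- ifelse(stats::runif(n) < prof$idc_prop,
                      "Invasive ductal carcinoma", "Others")
  grade <- sample(names(prof$grade_props), n, replace = TRUE,
                  prob = prof$grade_props)
  subtype <- sample(names(prof$subtype_props), n, replace = TRUE,
                    prob = prof$subtype_props)
  clinical_t <- ifelse(stats::runif(n) < prof$t34_prop, "T3-T4", "T1-T2")
  clinical_n <- ifelse(stats::runif(n) < prof$n13_prop, "N1-N3", "N0")
  ki67 <- round(pmin(99, pmax(1, 100 * stats::rbeta(n, 1.3, 2.6))))

  bc <- spec$beta_cov
  cov_lp <- bc[["age"]] * (age - prof$median_age) +
    bc[["t34"]] * (clinical_t == "T3-T4") +
    bc[["n13"]] * (clinical_n == "N1-N3") +
    bc[["tn"]] * (subtype == "Triple negative")
  slope_lp <- spec$beta_nhoc * eps + cov_lp
  beta0 <- spec$beta0
  if (is.null(beta0)) {
    beta0 <- stats::uniroot(
      function(b0) mean(stats::plogis(b0 + slope_lp)) - spec$target_pcr_rate,
      interval = c(-30, 30))$root
  }
  p_pcr <- stats::plogis(beta0 + slope_lp)
  pcr <- stats::runif(n) < p_pcr

  # residual cellularity (non-responders only), positively tied to eccentricity
  resid_cell <- rep(NA_real_, n)
  nr <- !pcr
  resid_cell[nr] <- pmin(100, pmax(5, 5 + 60 * eps[nr] +
                                     stats::rnorm(sum(nr), 0, 25)))

  hazard_lp <- spec$gamma_nhoc_peak * peak_eps + spec$gamma_mtv * volume
  h0 <- spec$baseline_hazard
  W <- spec$censoring_window_months
  if (is.null(h0)) {
    h0 <- exp(stats::uniroot(
      function(lh) expected_event_rate(lh, hazard_lp, W) - spec$target_event_rate,
      interval = c(-25, 5))$root)
  }
  t_event <- stats::rexp(n, rate = h0 * exp(hazard_lp))
  t_cens <- stats::runif(n, 0, W)
  event <- t_event <= t_cens
  pfs <- pmin(t_event, t_cens)

  fnoise <- function(x) pmax(0, x + stats::rnorm(n, 0, spec$feature_noise_sd))
  mtv <- volume * exp(stats::rnorm(n, 0, 0.05))
  suv_peak <- 0.8 * suv_max_true * exp(stats::rnorm(n, 0, 0.03))
  cohort <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    age = age, menopausal_status = menopausal, histology = histology,
    histologic_grade = grade, molecular_subtype = subtype,
    ki67_pct = ki67, clinical_t = clinical_t, clinical_n = clinical_n,
    pcr = pcr, residual_cellularity_pct = resid_cell,
    pfs_months = pfs, event = event,
    suv_max = suv_max_true,
    suv_peak = suv_peak,
    mtv_cm3 = mtv,
    tlg = 0.55 * suv_max_true * mtv,
    nhoc_max = fnoise(eps),
    nhoc_peak = fnoise(peak_eps),
    nhop_max = fnoise(0.45 * (1 - eps)),
    nhop_peak = fnoise(0.55 * (1 - eps)),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    id = cohort$id, eccentricity = eps, nhoc_peak_true = peak_eps,
    volume_cm3 = volume, logit_lp = beta0 + slope_lp, p_pcr = p_pcr,
    hazard_lp = hazard_lp, event_time = t_event, censor_time = t_cens,
    stringsAsFactors = FALSE)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (write_phantoms) {
      for (i in seq_len(n)) {
        r_mm <- (3 * volume[i] * 1000 / (4 * pi))^(1 / 3)
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        ph <- generate_phantom(phantom_spec(
          shape = spec$phantom_shape, spacing = spec$phantom_spacing,
          semi_axes_mm = rep(r_mm, 3), eccentricity = eps[i], ray = u,
          lesion_suv = 0.4 * suv_max_true[i],
          hotspot_peak_suv = 0.7 * suv_max_true[i],
          noise_sd = spec$phantom_noise_sd, seed = NULL))
        save_suv_volume(ph$volume, file.path(out_dir, paste0(cohort$id[i], "_suv.nii")))
        save_mask(ph$voi, file.path(out_dir, paste0(cohort$id[i], "_voi.nii")))
      }
    }
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    writeLines(c(sprintf("seed = %s", spec$seed),
                 sprintf("n = %d", n),
                 sprintf("generated = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                 sprintf("write_phantoms = %s", write_phantoms)),
               file.path(out_dir, "manifest.txt"))
  }
  list(cohort = cohort, truth = truth, spec = spec)
}
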