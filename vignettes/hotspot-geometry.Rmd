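---
title: "Hotspot geometry on FDG PET: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hotspot geometry on FDG PET: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petgeom)
```

## The model

Tumour progression pushes the most proliferative, metabolically active cell
populations toward the lesion edge, while the centre becomes dense and
necrotic. On FDG PET this displaces the uptake hotspot outward. `petgeom`
quantifies the displacement with two normalized distances computed from a
segmented lesion:

* **NHOC** — Euclidean distance from the hotspot to the lesion's geometric
  centroid, divided by the equivalent-sphere radius
  $R = (3\,\mathrm{MTV}/4\pi)^{1/3}$;
* **NHOP** — minimum Euclidean distance from the hotspot to the lesion
  perimeter, divided by the same $R$.

Two hotspot definitions are used: the SUVmax voxel centre (`max` variants)
and the centre of the 1 cm³ sphere that maximizes mean uptake (`peak`
variants). For a perfectly spherical lesion with the hotspot on a radial
ray, NHOC + NHOP ≈ 1 and NHOC equals the fractional radial position of the
hotspot; for ellipsoids no such identity holds, and for elongated lesions
NHOC may exceed 1 (normalization is by the equivalent sphere, not the
lesion's own extent — values are deliberately not clamped).

Downstream, the four geometry parameters and the four conventional ones
(SUVmax, SUVpeak, MTV, TLG) enter the standard clinical battery: rank tests
across clinico-pathological groups, Spearman correlations with Ki-67 and
residual tumour cellularity, ROC with Youden cutoffs for pathological
complete response (pCR, ypT0N0), logistic regression (odds ratios per 1.00
increase), Cox proportional hazards and Kaplan–Meier/log-rank for
progression-free survival. The multivariate design adds age, T stage
(T1–T2 vs T3–T4), N stage (N0 vs N1–N3) and molecular subtype (Luminal A
reference) to **one PET parameter at a time** — never several PET
parameters jointly, since they are strongly collinear.

## Segmentation

The lesion is delineated with the adaptive (Nestle) threshold:

$$\mathrm{SUV}_{thr} = 0.3 \cdot \overline{\mathrm{SUV}}_{hot} +
\overline{\mathrm{SUV}}_{bg},$$

where the hot core is the set of VOI voxels with SUV *strictly* above 70% of
SUVmax. Choices a user should know about:

* **Single pass.** The formula is applied once, not iterated. Iterative
  variants exist in some software; the printed formula is adopted as is.
* **Background region.** "Mean SUV of background" leaves the region
  undefined; the default is the shell of voxels 8–16 mm outside the initial
  VOI (a stand-in for adjacent normal tissue), computed with an exact
  anisotropic Euclidean distance transform. Any user-supplied mask can
  replace it; it must be disjoint from the VOI.
* **Strict inequalities** throughout (`> 0.7·SUVmax`, `> threshold`), so a
  uniform lesion is kept in full and thresholds sitting exactly on a voxel
  value exclude it.
* **Component selection.** The delineated mask is the 26-connected component
  (configurable to 6/18) of supra-threshold VOI voxels containing the SUVmax
  voxel. SUVmax ties resolve to the lexicographically smallest `(i,j,k)`
  index, making runs deterministic.

## Feature conventions

* **Grid.** Voxel-centre convention, 1-based indices, world position
  `origin + (idx − 1) · spacing`, distances in mm, volumes in cm³
  (mm³/1000). The clinical default grid is 4.07 × 4.07 × 2.5 mm; the
  pipeline accepts any positive anisotropic spacing.
* **SUVpeak.** Sphere of exactly 1 cm³ (radius 6.2035 mm); candidate centres
  are mask voxel centres; the mean runs over *all* voxels whose centres fall
  in the sphere, including non-mask voxels. Positions outside the grid
  contribute 0 against the full-sphere denominator (zero padding), so
  placements truncated by the image edge are never favoured. Ties break to
  the lexicographically smallest centre. Lesions with MTV < 1 cm³ are
  rejected — the same exclusion rule the clinical workflow applies.
* **Centroid.** Unweighted geometric centroid of the mask. Whether the
  reference construction is geometric or uptake-weighted is not settled; the
  SUV-weighted variant is available behind `weighted_centroid = TRUE`, with
  geometric as the default (the normalization by a geometric sphere radius
  argues for a geometric reference point).
* **Perimeter.** Mask voxels with at least one face-adjacent non-mask
  neighbour (the array border counts as outside); NHOP is the minimum
  distance to their centres. A sub-voxel surface mesh would change values by
  well under half a voxel and is not attempted. Whether the reference method
  measures the minimum distance or a distance along the centroid–hotspot ray
  is also unstated; the minimum is adopted, and the test suite pins this
  definition against an exhaustive brute-force oracle.
* `nhoc_peak ≤ nhoc_max` is *not* an invariant (the two hotspots are
  different points); only non-negativity and finiteness are guaranteed.

## Statistics

* **Rank tests.** Mann–Whitney is exact when there are no ties and both
  groups have < 50 observations, otherwise the normal approximation with tie
  correction and no continuity correction (so a mean-valued U gives exactly
  p = 1). Kruskal–Wallis beyond two groups. Two-sided everywhere, α = 0.05,
  no multiplicity correction (matching the clinical reporting style).
* **ROC.** AUC by the Mann–Whitney identity with ties counted ½; 95% CI by
  the DeLong variance; paired AUC comparison by the paired DeLong test (each
  marker oriented so AUC ≥ 0.5 first). DeLong is an assumption — the
  clinical software lineage does not name its method — and is cross-checked
  against a subject-resampling bootstrap in the tests.
* **Youden cutoff.** Maximizes sensitivity + specificity − 1 over midpoints
  between adjacent distinct scores; the smallest cutoff attaining the
  maximum is reported. Reapplying the reported cutoff and direction as a
  classifier reproduces the reported sensitivity/specificity exactly
  (self-consistency, tested).
* **Models.** Logistic via maximum likelihood with Wald CIs; separation and
  non-convergence are flagged (`converged = FALSE`), never silently
  reported. Cox with Efron handling of ties. Effects are per 1.00 increase
  of the parameter. The Kaplan–Meier grouping reuses the ROC cutoff for pCR
  of the same run — the report chains them exactly as the clinical analysis
  does.

## The simulated world

`generate_phantom()` builds an ellipsoidal lesion of constant base uptake
with a Gaussian hotspot bump placed at eccentricity ε along a
centre-to-surface ray (ε = 0 central, ε → 1 rim), on a noisy background,
with optional PSF blur applied before noise. `generate_cohort()` draws per
patient: ε, a log-normal lesion volume (median 5 cm³, floored at 1.2 cm³ to
stay above the SUVpeak exclusion), log-normal SUVmax, and covariates
matching the reference cohort's marginals (23.7% pCR target rate, 25.2%
event rate, 92.6% node-positive, 40% T3–T4, subtype mix 20/52.6/14.1/13.3%).
Outcomes are wired to the **true** geometry:

* response: `logit P(pCR) = β₀ + β_nhoc · ε` (+ optional covariate terms),
  default β_nhoc = −3 (direction and magnitude consistent with odds ratios
  ≪ 1 per 1.00 NHOC reported clinically), β₀ calibrated so the mean response
  probability hits the target rate;
* progression: exponential proportional hazards with linear predictor
  `γ_peak · NHOCpeak_true + γ_mtv · MTV_true`, defaults γ_peak = 1.5,
  γ_mtv = log(1.012) per cm³, uniform censoring on (0, 137.3) months and the
  baseline hazard calibrated (closed form under uniform censoring) to the
  target event rate.

Feature columns in the emitted cohort are the true values plus small
Gaussian measurement noise (sd 0.03 on the normalized distances — about
half the voxelization error bound observed on a 1 mm grid), so effect
estimates are attenuated the way extracted features would attenuate them.
The true NHOCpeak is 0.8 · ε: the peak sphere centre sits slightly inward
of the max voxel, consistent with the clinical medians (NHOCpeak below
NHOCmax). The default ε distribution is Beta(2,2) scaled to [0, 0.95],
matching the interquartile spread reported for NHOCmax; two named phantom
presets, `central` (ε = 0.27) and `rim` (ε = 0.78), reproduce the two
published example regimes and are verified to land there after the full
segmentation + extraction chain.

**Recovery experiment design.** The acceptance tests that recover β_nhoc and
γ_peak use the `two_group` ε distribution (a 50/50 mixture at 0.27 and
0.78, sd 0.1 — the two clinical regimes) and, for the logistic arm, a
balanced outcome rate. Both choices maximize the information about the
slope within the clinically observed range and were fixed before the tests
were run; the default cohort preset is unchanged.

**What the simulator does not emulate:** scanner physics (scatter, randoms,
reconstruction artifacts), breast anatomy and heterogeneous background
tissue, multifocal disease, partial-volume effects beyond simple Gaussian
blur, correlated covariates, or patient-level fidelity to any real cohort.
A green test therefore establishes that the *computational chain* is
correct and well calibrated — not that the clinical effect sizes would
reproduce on other patients.

## Numerical choices and degenerate inputs

* Distance transform: exact separable lower-envelope algorithm (squared
  distances are exact integer-weighted sums, so results match brute force to
  machine precision, verified on random masks).
* Empty masks, one-class outcomes, eventless survival data, constant
  parameters, and thresholds at or above SUVmax all raise errors rather than
  returning values; an all-censored Kaplan–Meier comparison reports p = 1
  with a `degenerate` flag.
* NIfTI-1 stores header geometry as float32 by format definition; SUV
  payloads are written as float64 so values round-trip bit-exactly while
  spacing/origin round-trip to single precision (~1e-7 relative). Oblique
  orientations, `.hdr/.img` pairs and DICOM are out of scope.
* All randomness in the simulators flows through a single seed recorded in
  the run manifest; pipelines are bit-for-bit reproducible given config and
  inputs.

## Limitations

Single-lesion analysis only (no lymph-node or multifocal aggregation); no
IBSI texture features; no resampling/interpolation policy (volumes are
consumed on the grid they arrive on — regridding is the producer's job);
the background-shell default is a pragmatic stand-in where the published
formula is silent; and the statistical battery intentionally mirrors a
clinical reporting pipeline rather than a modern penalized/multiple-testing
workflow.
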