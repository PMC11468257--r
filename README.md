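# petgeom

Hotspot geometry radiomics and outcome modelling for FDG PET.

## The problem

As a malignant tumour progresses, its most metabolically active region tends
to migrate from the centre toward the edge of the lesion. On FDG PET this
shows up as the uptake hotspot (the SUVmax voxel, or the centre of the
SUVpeak sphere) sitting closer to the tumour perimeter than to its centroid.
Two normalized distances capture this geometry:

- **NHOC** (normalized hotspot-to-centroid distance):
  `NHOC = ‖x_hot − x_centroid‖ / R`
- **NHOP** (normalized hotspot-to-perimeter distance):
  `NHOP = min_{b ∈ perimeter} ‖x_hot − b‖ / R`

where `R = (3·MTV / 4π)^{1/3}` is the radius of the sphere with the lesion's
metabolic tumour volume. Using the SUVmax voxel or the SUVpeak sphere centre
as the hotspot gives four parameters: NHOCmax, NHOCpeak, NHOPmax, NHOPpeak.
In breast cancer treated with neoadjuvant chemotherapy, higher NHOC (a
rim-seated hotspot) is associated with lower odds of pathological complete
response (pCR) and worse progression-free survival (PFS).

`petgeom` implements the full analysis chain for anyone who wants to compute
or stress-test these parameters:

1. **imaging I/O** — NIfTI-1 SUV volumes and masks, voxel-centre world
   coordinates (`load_suv_volume`, `save_mask`, `voxel_to_world`);
2. **segmentation** — Nestle's adaptive threshold,
   `SUV_thr = 0.3 · mean{SUV > 0.7·SUVmax} + mean(background)`,
   with a configurable background shell and connected-component selection
   (`segment_tumor`);
3. **features** — SUVmax, SUVpeak (1 cm³ sphere), MTV, TLG, and the four
   hotspot-distance parameters (`conventional_features`,
   `hotspot_geometry`);
4. **cohort statistics** — Mann–Whitney/Kruskal–Wallis, Spearman, ROC with
   Youden cutoffs and DeLong AUC comparisons, logistic regression for pCR,
   Cox and Kaplan–Meier with log-rank for PFS (`roc_youden`, `logistic_or`,
   `cox_hr`, `km_logrank`);
5. **simulation** — digital phantoms with a controllable hotspot
   eccentricity and cohorts whose outcomes are wired to the true geometry
   (`generate_phantom`, `generate_cohort`), enabling parameter-recovery and
   calibration tests without any clinical data;
6. **pipeline/CLI** — one-command runs producing the report tables
   (`run_study`, `run_cli`).

## Worked example

A rim-hotspot phantom (eccentricity 0.78, the non-responder-like preset),
segmented and measured:

```r
library(petgeom)
ph  <- generate_phantom(phantom_preset("rim"))
seg <- segment_tumor(ph$volume, ph$voi)
conv <- conventional_features(ph$volume, seg$mask)
geo  <- hotspot_geometry(ph$volume, seg$mask, conv)
cat(sprintf("threshold = %.3f SUV\n", seg$threshold_suv),
    sprintf("SUVmax = %.2f  SUVpeak = %.2f  MTV = %.2f cm^3  TLG = %.2f\n",
            conv$suv_max, conv$suv_peak, conv$mtv_cm3, conv$tlg),
    sprintf("NHOCmax = %.2f  NHOCpeak = %.2f  NHOPmax = %.2f  NHOPpeak = %.2f\n",
            geo$nhoc_max, geo$nhoc_peak, geo$nhop_max, geo$nhop_peak), sep = "")
```

prints:

```
threshold = 2.762 SUV
SUVmax = 9.06  SUVpeak = 6.38  MTV = 7.29 cm^3  TLG = 32.91
NHOCmax = 0.87  NHOCpeak = 0.55  NHOPmax = 0.00  NHOPpeak = 0.34
```

The adaptive threshold (2.762 SUV) sits well below the lesion's base uptake,
so the whole lesion is delineated; the hotspot lies at the rim — NHOCmax is
high and NHOPmax is ~0, the geometry of an aggressive lesion.

A small end-to-end simulated study (40 patients, phantoms written to disk,
features re-extracted from the images, then the statistics battery):

```r
out <- file.path(tempdir(), "demo")
generate_cohort(cohort_spec(n = 40, seed = 7, phantom_shape = c(24, 24, 18)),
                out_dir = out, write_phantoms = TRUE)
run_study(run_config(input_dir = out,
                     clinical_csv = file.path(out, "cohort.csv")))
```

```
<study_report>
  40 patients analysed, 0 excluded
  ROC (response prediction):
    suv_max    AUC 0.568 (0.368-0.769)  cutoff <7.35  sens 58.3%  spec 71.4%
    suv_peak   AUC 0.530 (0.327-0.732)  cutoff <5.39  sens 58.3%  spec 64.3%
    mtv_cm3    AUC 0.506 (0.284-0.728)  cutoff >8.43  sens 33.3%  spec 89.3%
    tlg        AUC 0.500 (0.276-0.724)  cutoff >49.4  sens 25.0%  spec 96.4%
    nhoc_max   AUC 0.676 (0.509-0.842)  cutoff <0.695  sens 100.0%  spec 42.9%
    nhoc_peak  AUC 0.635 (0.442-0.829)  cutoff <0.508  sens 91.7%  spec 46.4%
    nhop_max   AUC 0.650 (0.475-0.826)  cutoff >0.222  sens 91.7%  spec 50.0%
    nhop_peak  AUC 0.598 (0.409-0.787)  cutoff >0.371  sens 83.3%  spec 42.9%
  KM at response cutoff 0.508: log-rank p = 0.9449
```

Response in this simulated world is wired only to the true hotspot
eccentricity, and the geometry features duly outrank the conventional ones
on AUC (`<` in the cutoff column means *lower* values predict response).
At n = 40 nothing reaches significance — by design the generator produces
honest, noisy cohorts; the acceptance tests use the sizes at which effects
are recoverable.

The same run from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "petgeom.R", package = "petgeom"))')
Rscript "$CLI" simulate cohort --out demo --n 40 --seed 7 --phantoms
Rscript "$CLI" run-all --input demo --clinical demo/cohort.csv --out demo/report
```

## Documentation

The methods vignette (`vignettes/hotspot-geometry.Rmd`) describes the model
and its assumptions, every tunable parameter with units and defaults, the
numerical conventions (tie-breaks, boundary definitions, edge handling),
what the simulator does and does not emulate, and known limitations.
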