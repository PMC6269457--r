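# mammotex

Breast-anatomy-driven parenchymal texture analysis of mammograms.

## What it does, and for whom

Mammographic parenchymal texture carries breast-cancer-risk information beyond
percent density, but conventional pipelines sample the breast with a regular
square lattice that ignores anatomy. `mammotex` is for imaging researchers who
want texture sampled and summarized the way the breast is built:

1. **Anatomical parameterization** of an MLO-view mammogram: air-breast
   boundary (Otsu), pectoralis muscle (orientation-gated Hough line), dense
   tissue (fuzzy c-means density clusters), orientation standardization
   (pectoral line vertical, chest wall left), nipple localization, and the
   CBA/UOA quadrants defined by the nipple-pectoralis distance `r_P` and the
   fraction `f`.
2. **Anatomy-aligned texture**: a nipple-centered polar grid with radius unit
   `D` (denser sampling in the retro-areolar region); in each region 34
   descriptors (13 gray-level histogram, 7 co-occurrence, 11 run-length, 3
   structural), with co-occurrence and run-length axes aligned to the local
   radial direction.
3. **Anatomical weighting**: each region's weight is
   `W = c·S + (1−c)·T`, where `S` encodes proximity to the CBA/UOA centroids
   (tuned by `a`) and `T` the dense-vs-fatty composition (tuned by `b`).
   Weighted maps are summarized into a 68-element per-breast signature
   (per-feature mean and standard deviation over regions).
4. **Case-control modeling**: bilateral averaging, IQR/correlation-0.90
   feature filtering, elastic-net logistic regression under nested
   (10 outer × 5 inner, stratified) cross-validation, pooled out-of-fold AUC
   with bootstrap CI, DeLong tests, category-free NRI, baseline
   (density/BMI/age) augmentation, and grid optimization over
   `(D, f, a, b, c)`. Defaults sit at the method's optimized operating point
   (`D = 6.3` mm, `a = 0.8`, `b = 1`, `c = 0.4`).
5. **Lattice comparator and phantoms**: a regular-lattice texture baseline
   sharing the identical feature code path, and a seed-controlled synthetic
   MLO phantom generator with ground-truth masks and a localizable
   case-control texture effect, so the full pipeline runs and is testable
   with no patient data.

Input images are 2D "for processing" PNG/TIFF grayscale mammograms with known
pixel spacing (DICOM is not supported in this build — convert to 16-bit
PNG/TIFF first). The package convention is higher intensity = denser tissue;
`read_image(..., invert = TRUE)` flips vendors with the opposite polarity.

## Worked example

Simulate a 125-woman phantom cohort (25 cases at 1:4 matching) with a texture
effect injected in the dense tissue of the central breast area, run the
anatomy-weighted and lattice pipelines, and compare the models:

```r
library(mammotex)

cfg  <- run_config(seed = 11)   # D = 6.3 mm, f = 0.75, a = 0.8, b = 1, c = 0.4
co   <- generate_cohort(25, 100,
                        phantom_spec(effect = "cba_dense", effect_size = 2),
                        seed = 11)
pipe <- run_cohort_pipeline(co, cfg, include_lattice = TRUE)

pw_a <- aggregate_signatures(pipe$anatomy, pipe$subject_ids)  # 125 x 68
m_a  <- fit_elastic_net_cv(correlation_filter(pw_a), pipe$labels, seed = 11)
pw_l <- aggregate_signatures(pipe$lattice, pipe$subject_ids)
m_l  <- fit_elastic_net_cv(correlation_filter(pw_l), pipe$labels, seed = 11)

m_a
#> <model_result> cross-validated AUC 0.934 (95% CI 0.880-0.977), 31 features selected
m_l
#> <model_result> cross-validated AUC 0.853 (95% CI 0.727-0.957), 16 features selected
delong_test(m_a$oof, m_l$oof, pipe$labels)[c("delta_auc", "p")]
#> $delta_auc
#> [1] 0.0812
#>
#> $p
#> [1] 0.1492841
```

The anatomy-weighted signature discriminates the injected effect better than
the unweighted lattice (higher cross-validated AUC; at this desk-scale n a
single-seed DeLong comparison is not expected to reach significance — the
ordering is the reproducible claim, see `tests/testthat/test-acceptance.R`).
Per-breast diagnostics against the generator's ground truth are collected in
`pipe$diagnostics` (breast-mask Dice, nipple error in mm, pectoral angle
error in degrees).

A thin command-line front end over the same functions is installed at
`inst/cli/mammotex.R` (subcommands `simulate`, `features`, `cohort-model`,
`compare`).

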