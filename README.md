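# iacdens

Quantification and determinant modelling of intracranial arterial
calcification (IAC) density on non-contrast CT.

## The problem

Calcification of the intracranial arteries is the imaging hallmark of
intracranial arteriosclerosis and a risk factor for stroke and dementia.
Beyond the *volume* of calcification, its *density* (mean attenuation in
Hounsfield units) is thought to carry independent information: denser
calcification reflects more mature, stable plaque. This package implements
the measurement and inference chain needed to study IAC density in a
population cohort, for imaging epidemiologists and methods researchers:

* **Voxel-level quantification.** Within a per-artery region of interest,
  calcification is every voxel with HU >= 130 (the non-contrast detection
  floor). Volume is the supra-floor voxel count times the voxel volume;
  mean density is `sum(HU) / count`. Both are re-measured across a ladder
  of thresholds (200, 300, 400, 600, 800, 1000 HU) to isolate components of
  increasing density, and the maximum HU is binned into seven ordinal
  categories (130-200, 200-300, 300-400, 400-600, 600-800, 800-1000,
  >1000).
* **Aggregation.** Per-artery measurements roll up to the intracranial
  carotid (ICAC), vertebrobasilar (VBAC) and overall (IAC) beds; bed
  density is the unweighted mean of per-artery densities over affected
  arteries.
* **Subtypes.** Kockelkoren scores (0-19) classify carotid calcification
  as intimal (< 5), ambiguous (5-8) or medial (> 8); densities are
  compared across subtypes with two-sided rank-sum tests.
* **Inference.** Spearman correlation (Pearson on mid-ranks) with a
  percentile-bootstrap CI; a self-contained Newton-Raphson
  proportional-odds fit, `P(Y <= k | x) = logistic(alpha_k - x'beta)`,
  reporting common odds ratios `exp(beta)` with Wald CIs; OLS on the
  standardized log outcome ("per SD increase"); and the
  primary-prevention sensitivity restriction.
* **Synthetic test beds.** A CT phantom generator with exact ground truth
  validates the measurement core bit-for-bit, and a cohort simulator
  (published covariate marginals, proportional-odds outcomes, Gaussian
  copula density-volume pairs) validates the estimators by parameter
  recovery.

See `vignettes/iac-density-methods.Rmd` for the full methods account.

## Worked example

Quantify a synthetic phantom with known inserts, then fit the determinants
model on a simulated cohort:

```r
library(iacdens)

ins <- list(
  calc_insert("ICA_left", center_mm = c(10, 10, 12), radii_mm = 4,
              hu_profile = hu_graded(900, 180)),
  calc_insert("basilar", center_mm = c(20, 20, 36), radii_mm = 2.5,
              hu_profile = hu_uniform(250)))
ph <- generate_phantom(phantom_spec(ins, seed = 7))
quantify_phantom(ph)$ICA_left
#> <artery_measurement> ICA_left  max HU: 629  category: 600-800
#>   threshold voxel_count volume_mm3  mean_hu
#> 1       130         242     261.36 369.1240
#> 2       200         226     244.08 382.1416
#> 3       300         150     162.00 448.4267
#> 4       400          94     101.52 505.0213
#> 5       600          12      12.96 610.8333
#> 6       800           0       0.00       NA
#> 7      1000           0       0.00       NA
```

The graded carotid insert (core 900, rim 180 HU) loses voxels as the
threshold rises -- 242 voxels (261.4 mm^3) at the floor, 12 above 600 HU --
and its mean density climbs from 369 to 611 HU; the 3-mm slices mean the
realized maximum (629 HU) stays below the analytic core value, the expected
partial-volume behaviour. `aggregate_participant()` then gives this
participant an IAC volume of 336.96 mm^3, mean density 309.56 HU, and
maximum-density category 600-800.

```r
co <- simulate_cohort(n = 2040, seed = 1)   # truths: published odds ratios
eff <- attr(co, "generator")
fit_proportional_odds(as.data.frame(co)[names(eff$beta)], co$density_category)
#> Proportional-odds fit: n = 2040, K = 7, logLik = -3764.377 (converged, 5 iter)
#>                    beta     se     OR ci_low ci_high      p
#> age              0.0585 0.0062 1.0602 1.0475  1.0731 0.0000
#> female          -0.4345 0.0789 0.6476 0.5548  0.7560 0.0000
#> hypertension     0.3753 0.0895 1.4554 1.2213  1.7343 0.0000
#> chd_history      0.9912 0.1366 2.6946 2.0616  3.5219 0.0000
#> ...
```

One replicate's odds ratios scatter around their generating values (age
1.07, female 0.65, hypertension 1.59, CHD 2.59, ...); averaged over 50
seeded replicates they recover each truth to within a few percent
(`recover_ordinal_ors()`). Correlation of the simulated log volume and log
density:

```r
sp <- spearman_with_ci(co$ln_volume_plus1, co$ln_density, seed = 1)
#> Spearman rho 0.654 (95% CI 0.627-0.678)
```

`run_pipeline(list(out_dir = "out", seed = 1))` chains phantom ->
quantify -> cohort -> subtype -> fit end to end and writes a manifest with
an MD5 hash of every output; reruns under the same seed are hash-identical.

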