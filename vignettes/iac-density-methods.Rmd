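---
title: "Quantifying intracranial arterial calcification density: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracranial arterial calcification density: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iacdens)
```

# The measurement model

Intracranial artery calcification (IAC) on non-contrast CT is quantified
inside per-artery regions of interest drawn around the five cerebropetal
arteries: the paired intracranial carotids (the ICAC bed) and the paired
vertebrals plus basilar (the VBAC bed). The primitive operations are
deliberately simple and fully deterministic:

* **Detection.** A voxel is calcified when its attenuation is at least
  130 HU, the conventional calcification floor on non-contrast CT. The
  comparison is inclusive: a voxel at exactly 130 HU counts.
* **Volume.** Supra-floor voxel count times the physical voxel volume
  (`dx * dy * dz` in mm^3). No connected-component filtering and no minimum
  lesion size are applied -- any supra-threshold in-mask voxel counts. This
  is the standard calcium-scoring volume convention.
* **Mean density.** The plain arithmetic mean of the supra-floor HU values:
  their sum divided by their count. When no voxel reaches the floor the
  density is *absent* (`NA`), never zero; volume in that case is zero. An
  absent density therefore can never pollute an average over arteries.
* **The threshold ladder.** Volume and density are re-measured with the
  threshold raised to 200, 300, 400, 600, 800 and 1000 HU, isolating
  components of increasing density (increasingly mature calcification).
  Counts and volumes are non-increasing along the ladder and the mean
  density is non-decreasing; both facts are enforced as stage contracts and
  tested as properties.
* **Maximum-density category.** The maximum in-mask HU is binned into seven
  ordinal categories: 130-200, 200-300, 300-400, 400-600, 600-800,
  800-1000, >1000. Interior bin edges are left-closed/right-open (200 HU
  falls in 200-300), while the top of the ladder follows the printed
  labels: ">1000" is strictly exclusive, so 1000 HU itself belongs to
  800-1000. Only the interior-edge convention required a choice; the
  labels fix everything else.

**Participant aggregation.** Bed-level average density is the *unweighted
mean of per-artery mean densities* over affected arteries -- each artery
contributes equally regardless of its size. This differs from pooling all
voxels whenever artery sizes differ, and a regression test pins the
per-artery convention. Bed volume is the sum of per-artery volumes at the
floor; the bed category is the maximum of per-artery categories; IAC
aggregates apply the same rules across all five arteries.

# The synthetic phantom generator

Real scans cannot ship with the package, so the measurement core is
validated against synthetic phantoms with exact ground truth
(`generate_phantom()`, `truth_table()`).

A phantom is a background of soft-tissue noise, N(40, 10) HU rounded to
integers (CT stores integer HU), clipped below the 130-HU floor so that the
background can never register as calcification, into which calcific inserts
are written: spheres, ellipsoids or shells, with either a uniform HU value
or a radial gradient from a dense core to a less dense rim (core >= rim).
Voxel membership is decided by **voxel-center inclusion** -- the simplest
deterministic rule. It reproduces the partial-volume behaviour of
thick-slice CT: at the default 0.6 x 0.6 x 3 mm spacing, boundary voxels
flip in or out of an insert as the grid shifts, so the realized volume of a
small insert deviates from the analytic ellipsoid volume, and converges
toward it as slices get thinner (a tested property).

Each artery's mask covers its inserts plus a 2 mm soft-tissue margin,
emulating a region of interest delineated around the vessel. Mask geometry
is synthetic and declared as such: the visual delineation protocol used on
real scans is an image-reading procedure outside this package's scope.

`truth_table()` recomputes what each insert actually deposited -- voxel
count at the floor, realized volume, realized mean HU, realized category --
by *plain voxel-by-voxel loops*, written independently of the vectorized
measurement code. The two implementations must agree bit-for-bit on every
phantom; the validation suite checks 50 seeded phantoms. Because supra-floor
HU values are integers and their sums stay far below 2^53, both code paths
produce identical floating-point sums regardless of summation order, so
exact equality is a meaningful requirement rather than a tolerance in
disguise.

What the phantoms do **not** emulate: realistic vascular anatomy, beam
hardening and streak artefacts, scanner-specific reconstruction, or
contrast enhancement. Passing the phantom suite shows the counting and
averaging are correct, not that the pipeline is robust to acquisition
artefacts.

# Subtype classification and comparison

The Kockelkoren visual score (0-19) for intracranial carotid calcification
is mapped to morphological subtypes: **< 5 intimal, 5-8 ambiguous, > 8
medial**, partitioning the twenty scores into 5 + 4 + 11. Artery-level mean
densities are then summarized per stratum (n, median, IQR). Arteries that
carry a score but no measurable density are excluded from the summaries and
counted separately, mirroring how such arteries must be handled in real
data.

Pairwise comparisons across strata use the two-sided Mann-Whitney/Wilcoxon
rank-sum test: the exact null distribution when the smaller sample has at
most 8 observations and the pooled data are tie-free, and otherwise the
normal approximation with tie and continuity corrections. The n = 8 switch
keeps exact enumeration trivially cheap where it matters; beyond it, the
approximation error is far below any decision threshold (checked against a
10^4-permutation oracle). Raw p-values are the primary output for the three
display comparisons; a Bonferroni column is available by flag, and Welch's
t-test is provided as a flagged alternative for users who prefer a
location-scale test on these skewed distributions.

# The synthetic cohort

The inference chain is validated by *parameter recovery*: simulate a cohort
whose generating parameters are the published effect sizes, refit with the
package's estimators, and require the truths back. The generator makes the
following choices:

* **Covariate marginals** follow the published population: age N(69.7,
  6.8) truncated at 55 years (cohort entry age, drawn by inverse CDF so
  seeds reproduce exactly), female 51.9%, ever smoking 69.7%, obesity
  24.1%, hypertension 74.2%, diabetes 11.2%, non-HDL cholesterol N(4.2,
  1.0) mmol/L, lipid-lowering medication 24.4%, CHD history 9.2%, CVA
  history 6.3%, 64-slice scanner 68.6%. Smoking enters as the collapsed
  binary "ever smoking", matching the determinant model's single smoking
  term.
* **Independence.** Covariates are drawn independently because no joint
  distribution is published. This is adequate for estimator-recovery tests
  (the fitted model conditions on the realized design) but deliberately
  does *not* emulate real-world confounding; recovered sensitivity-analysis
  retention fractions, for instance, will differ from real data where the
  three exclusion flags are correlated.
* **Ordinal outcome.** A latent variable `u = x'beta + e` with standard
  logistic noise is cut at six thresholds, so `P(Y <= k | x) =
  plogis(alpha_k - x'beta)` holds exactly -- the generative twin of the
  fitted model. Generating coefficients default to the natural logs of the
  published adjusted common odds ratios.
* **Cutpoints** are free parameters (the real category frequencies are
  published only graphically). The default derivation centers the latent
  scale on the mean linear predictor implied by the marginals and places
  cutpoints at logistic quantiles of target category probabilities (16, 20,
  16, 16, 12, 9, 11%), chosen once so every category keeps at least 2%
  mass and refits never face a near-empty category. The spread of the
  linear predictor flattens the realized distribution slightly relative to
  the targets; what matters is non-degeneracy, which is tested.
* **Density-volume pairs.** A Gaussian copula with Pearson parameter
  `r = 2 sin(pi * rho_S / 6)` -- the exact inversion of the
  bivariate-normal rank correlation -- feeds two normal margins on the log
  scale, so the population Spearman correlation equals the target (0.67 by
  default) while the natural-scale margins are right-skewed log-normals
  matched by median and IQR (density 232 HU, IQR 189-287; volume + 1 mm^3,
  median 68, IQR-matched).
* **Subtype arteries.** Scores are drawn uniformly within each subtype's
  range under mixture weights 20.5 / 56.6 / 23.0% (renormalized), and
  densities from log-normals with medians 210 / 255 / 294 HU and sigmas
  matched to the published IQRs by the quartile-ratio identity
  `log(q3/q1) = 2 * qnorm(0.75) * sdlog`.
* **Seeding.** One master seed spawns per-component substreams through a
  fixed Lehmer step, so each component is independently reproducible and
  the whole table is bit-identical under a fixed seed.

# The inference chain

**Spearman correlation.** Pearson correlation of mid-ranks (ties get
average ranks), with a seeded percentile bootstrap (1000 replicates over
participants) for the 95% interval. The interval method is a choice --
percentile bootstrap is what the commonly used correlation-CI helpers in
this field implement -- and a Fisher-z interval is available by flag.
Degenerate (constant) input yields a flagged `NA` rather than an error
deep in `cor()`.

**Proportional-odds model.** Self-contained maximum likelihood. The
cutpoints are reparameterized as `(alpha_1, log successive gaps)` so the
Newton iteration is unconstrained while ordering holds by construction;
gradient and Hessian are analytic (with the chain-rule correction for the
reparameterization), starting values are zero slopes and cutpoints at the
logits of cumulative category frequencies, and each Newton step is
step-halved until the log-likelihood does not decrease -- the trace is
recorded and its monotonicity asserted in tests. Convergence requires a
gradient sup-norm below 1e-8 within 100 iterations; non-convergence is
flagged, never silent. Standard errors come from the observed information
at the optimum, and 95% intervals are Wald on the log-odds scale (the
published intervals are symmetric on that scale; profile likelihood is not
implemented). Correctness anchors: a K = 2 fit equals binary logistic
regression and the closed-form 2x2 odds ratio to 1e-6; an intercept-only
fit returns observed category frequencies; the optimum matches a
derivative-free maximizer and an established independent implementation on
the same data.

**Linear model.** OLS on the z-scored log outcome (so coefficients read
"per SD increase" of the log outcome) with covariates on their natural
scales, solved by QR with classical homoskedastic intervals; rank
deficiency is rejected naming the collinear columns. Outcome-only
standardization is a documented interpretation choice: the published
coefficient table labels covariate rows in natural units (per year, per
mmol/L), which is incompatible with covariate standardization.

**Sensitivity restriction.** Removes participants with prevalent CHD,
prevalent CVA, or lipid-lowering medication, reporting the removed count;
downstream fits on an emptied table fail with a clear error.

# Validation problem sizes

The validation suite and the reproduction script use: 50 seeded phantoms
(48 x 48 x 16 voxels at 0.6 x 0.6 x 3 mm) for exact measurement
equivalence; 50 simulate-refit replicates of n = 2040 cohorts for ordinal
recovery, with 200 replicates for CI coverage (required within 90-99%);
50 replicates of n = 2040 pairs for Spearman recovery (per-replicate
deviation under 0.03, mean deviation under 0.005); and 20 replicates for
linear recovery with 200 for coverage. Fifty replicates put the Monte-Carlo
error of each mean odds ratio near 1-2%, comfortably inside the 5%
recovery band, so a band violation indicates an estimator defect rather
than simulation noise.

# Known limitations

* Independent covariates: the generator recovers estimators, not the real
  joint risk-factor structure.
* Phantoms validate counting, not robustness to acquisition artefacts,
  motion, or delineation error.
* The participant-level "predominantly intimal/medial" labelling of real
  cohort tables has no published derivation rule from artery-level scores
  and is out of scope; subtype analysis here is artery-level.
* Missing-data machinery (multiple imputation) is out of scope: synthetic
  cohorts are complete, and the fitters require complete cases.
* Wald intervals can undercover for rare binary covariates at small n;
  coverage is verified at the sizes used here.
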