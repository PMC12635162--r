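---
title: "Asymmetry-based neurometabolic signature mapping: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymmetry-based neurometabolic signature mapping: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnms)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, what the synthetic phantom
emulates (and does not), and the decisions taken where the design was
genuinely open.

## 1. Asymmetry-index preprocessing

All analysis happens on voxel-wise interhemispheric asymmetry indices

$$\mathrm{AI}(v) \;=\; \frac{i_1(v) - i_2(v)}{\tfrac12\,(i_1(v) + i_2(v))},$$

where $i_2$ is $i_1$ mirrored about the midsagittal plane. The package
assumes volumes are already aligned in a left–right symmetric space with
the midplane at the lattice x-midplane (even x dimension); registration
and template construction are out of scope, and the phantom generator
produces volumes symmetric by construction. For nonnegative images
$\mathrm{AI} \in [-2, 2]$, and the map is antisymmetric under the flip —
both are enforced as test invariants at `1e-12`.

Ahead of AI mapping the pipeline applies, in the default order
**smooth → PVC → standardize → AI**:

* **Gaussian smoothing** (`gaussian_smooth`), per-axis
  $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2}) / \mathrm{voxel}$, default
  FWHM 6 mm (PET only). The discrete kernel is truncated at $4\sigma$ and
  renormalized; boundaries use half-sample reflection, which makes the 1-D
  convolution matrix symmetric and doubly stochastic, so total intensity
  is conserved exactly rather than merely approximately.
* **Müller–Gärtner partial volume correction** (`muller_gartner_pvc`):
  $\mathrm{GM}_{corr} = (\mathrm{PET} - \mu_{WM} G(wm) - \mu_{CSF}
  G(csf)) / G(gm)$ with $G$ the PSF smoothing. Reference activities are
  means over compartment probability $\ge 0.9$ after one 6-neighbourhood
  erosion; the correction is undefined (NA, excluded downstream) where
  $G(gm) < 0.3$ (`gm_floor`). On a noiseless shell phantom the GM core is
  recovered within 2%, which the acceptance suite checks.
* **Standardization** (`zscore_within_mask`): within-brain z-scoring with
  the sample SD ($n-1$; at voxel counts the $n$ vs $n-1$ distinction is
  negligible, the sample convention is simply recorded). Proportional
  scaling (`proportional_scale`) is available as the alternative
  normalization; z-scoring is the default because it is the explicitly
  formulaic variant.
* **Sign guard for the AI.** The AI formula presumes nonnegative
  intensities (PET uptake); z-scored images are not. By default the map
  is therefore computed on a globally shifted copy (within-mask minimum
  moved to 1% of the range, `shift = "auto"`). A global scalar shift is
  flip-invariant, so antisymmetry is untouched; the cost is that the AI
  scale then depends on the image range, which is why phantom AI
  magnitudes are larger than clinical ones. Voxels whose homologue mean
  is below `eps` ($10^{-6}$) are invalid rather than infinite.

## 2. Signature masks and overlap statistics

`binarize_pnms` thresholds the AI map at $\tau$ (default $-0.06$) in the
hypometabolic direction ($\mathrm{AI} \le \tau$) within one hemisphere —
the threshold is negative and the epileptogenic zone is characterized by
ipsilateral hypometabolism, so lower-than-contralateral is the direction
of interest. A hemisphere mask straddling the midplane is an error; an
empty signature is a warning, not an error.

`ablative_rate` is $|\mathrm{pNMS} \cap R \cap \mathrm{ablation}| /
|\mathrm{pNMS} \cap R|$ per structure $R$ (hippocampus and amygdala
separately; a whole-hemisphere variant is just `roi = NULL`). An empty
$\mathrm{pNMS} \cap R$ makes the rate *missing*, never zero — the subject
is excluded from that structure's analysis with a logged count, since a
zero would fabricate a "nothing ablated" observation. Mask agreement is
the Dice coefficient. Per-patient modality features are the arithmetic
mean AI over the ablation cavity (`mean_ai_within_mask`); the aggregator
is not dictated by the formula, so the median is provided as an option
and the mean, the conventional first moment, is the default.

## 3. Dose-response modelling and thresholds

Outcome models are logistic regressions with a restricted cubic spline in
the exposure: Harrell's 3-knot basis $[x, s(x)]$ with

$$s(x) = \frac{(x-t_1)_+^3 - (x-t_2)_+^3\frac{t_3-t_1}{t_3-t_2}
          + (x-t_3)_+^3\frac{t_2-t_1}{t_3-t_2}}{(t_3-t_1)^2},$$

knots at the type-7 empirical 10th/50th/90th percentiles. This is the
de-facto standard basis behind "restricted cubic spline logistic
regression"; it is linear outside $[t_1, t_3]$, which the tests verify by
numeric second differences. Ties that collapse the knots are a hard
error. Model comparison uses $\mathrm{BIC} = -2\ell + k\ln n$ with ties
broken toward fewer parameters. Nonlinearity and overall association are
likelihood-ratio tests (1 and 2 df): at $n = 30$ the LR test behaves
better than Wald, and its size is verified empirically (rejection rate in
$[0.03, 0.07]$ at $\alpha = 0.05$ over 500 null replications of
$n = 2000$).

The clinical reference value is read off the fitted log-odds curve on a
200-point grid spanning the 2.5th–97.5th percentiles
(`find_inflection`): interior sign changes of the first difference are
extrema ("U" for one, "N" for two); with none, the point of maximum
absolute second difference is returned as a curvature *elbow*, labelled
distinctly, and the shape is "L" when one side's mean slope is below 20%
of the other's, else "monotone". The elbow fallback exists because
L-shaped curves have a well-defined bend but no strict direction change.
Flat curves (log-odds range $< 10^{-6}$) return "no inflection" rather
than an arbitrary point.

Cut-off selection (`roc_youden`) maximizes Youden's $J$ over all
empirical midpoints (ties to the lower threshold, verified against
exhaustive search on every random instance tested); AUC is the
trapezoidal/rank statistic, cross-checked against `pROC`. Because the
emulated cohort is imbalanced (≈70% seizure-free), accuracy is reported
three ways: balanced accuracy $(se + sp)/2$, prevalence-weighted accuracy
$w\,se + (1-w)\,sp$, and overall accuracy. For the reconstructed
outcome-by-cutoff table (21/9 classes, sensitivity 0.952, specificity
0.556) the weighted and overall accuracies agree at 0.833 while the
arithmetic-mean definition gives 0.754 — both are always emitted so the
two readings of "balanced" cannot be conflated. Odds ratios for
continuous AI features are reported per 0.01 AI by default, and the scale
is carried in the output, because an OR without its unit is meaningless.
All tests are two-sided at $\alpha = 0.05$ with no multiplicity
correction.

## 4. Structural interpretation

The per-patient PET AI is predicted from five structural features (TIV,
ipsilateral hippocampal and amygdalar volumes, and their volumetric AIs)
by a Gaussian additive model with one unpenalized 3-knot restricted
spline per feature — the smallest model class consistent with "additive
model with smooths" that is exactly reproducible and stable at $n = 30$;
no penalty means no smoothing-parameter selection to condition results
on. Features that cannot support three distinct percentile knots fall
back to a linear term.

* **Cross-validation**: 5-fold, re-partitioned each of 1000 iterations
  (seeded), every subject out-of-fold exactly once per iteration;
  per-subject prediction is the across-iteration mean and the interval
  the 2.5th/97.5th percentile of per-iteration predictions.
* **Shapley attribution** is exact: the payoff of a coalition is the
  in-sample prediction of the model *retrained* on that feature subset
  (all $2^5$ fits; the empty coalition predicts the target mean). With
  five features and 30 subjects exactness is cheap and beats any sampling
  approximation. The subset refits use a pivoted least-squares
  projection, which is well-defined under collinearity — that is what
  makes the symmetry axiom hold exactly for duplicated features, and
  efficiency ($\sum_j \phi_j = \hat y - \bar y$ per subject, to
  $10^{-8}$) holds by telescoping. The reported "feature weight" is the
  signed mean over subjects; the mean absolute value is also emitted and
  is what rankings use, since signed means of centred contributions are
  near zero by construction.
* **Partial dependence** for an additive model equals the feature's
  fitted smooth plus a constant; it is computed by the generic
  set-and-average definition and tested against that identity.

## 5. The synthetic phantom cohort

The generator emulates a 30-subject mTLE cohort: an ellipsoidal brain
(per-subject size scale, SD 3%) with GM shell / WM core / CSF rim,
mirrored spherical hippocampi (radius 5 voxels at $48^3$, 2 mm voxels)
and amygdalae (radius 3), ipsilateral PET activity multiplied by
$1 - d$ (hypometabolism depth $d$: mean 0.30, SD 0.10 across subjects —
the typical 20–40% FDG reduction scale), gray-matter density multiplied
by $1 - a$ (atrophy $a$: mean 0.15, SD 0.06), with $d$ and $a$ correlated
at 0.5 so that structure genuinely drives the metabolic asymmetry.
Segmentation labels are deliberately distinct from the symmetric
intensity geometry — mirrored sub-voxel centre jitter, 2% per-side radius
variation, ipsilateral volumes shrunk by the atrophy fraction — because
anatomical labels in practice are not the lesion model; disease effects
cover label and intensity sphere jointly so every labelled voxel carries
the full planted effect. Noise is additive Gaussian (SD 0.05) after
effect insertion, matching the standardized scale the pipeline operates
on.

The ablation cavity covers a Beta(2.5, 1.8)-distributed fraction
(mean ≈ 0.58, consistent with reported ablative-rate operating points) of
the voxels whose *noiseless* AI falls at or below the planted −0.06
threshold, taken centre-out so cavities are compact. Outcome is
Bernoulli with $\mathrm{logit}\,P(\mathrm{SF}) = \alpha + \beta c$,
$\beta = 6$, and $\alpha$ solved by quadrature so the expected
seizure-free fraction is exactly 0.70; across 1000 simulated cohorts of
30 the mean observed fraction sits within ±0.02 of the target.

Two table-level generators support the statistical recovery studies
without image synthesis: `simulate_threshold_cohort` plants a logistic
dose-response whose direction change (shape "U", $\eta = 1.5 - 50(x +
0.06)^2$, $x \sim N(-0.06, 0.10)$) or slope change (shape "L") sits
exactly at −0.06 — the curvature was chosen once as a strong, clinically
plausible effect (log-odds drop ≈ 2 at two SDs) so that recovery failure
indicates an estimator defect, not an underpowered design; and
`simulate_structural_cohort` plants hippocampal volume as the strongest
AI driver (0.045 AI per SD vs ≤ 0.020 for the other four features,
residual SD 0.03). The packaged `table1_fixture()` reproduces the
emulated cohort's categorical margins exactly and fills continuous
fields with moment- or quantile-matched synthetic draws, flagged
`synthetic`.

What the phantom does **not** emulate: MRI physics, scanner artifacts,
registration error, anatomically shaped structures, or partial
lateralization. Passing tests therefore demonstrate correctness of the
estimators under the planted model — recovery of known truths,
calibration, axioms, determinism — not clinical performance on real
cohorts. Phantom AI magnitudes are larger and cleaner than clinical
ones; the pipeline's thresholds on real data would have to be
re-derived, which is the point of shipping the discovery machinery
rather than the numbers.

## 6. Problem sizes, determinism, degenerate inputs

Analyses are sized for a desk run: $48^3$ lattices, 30-subject cohorts,
500-replication null studies at $n = 2000$, 20-seed recovery ensembles at
$n = 500$, 100-seed attribution studies at $n = 30$ — together a few
minutes. Every stochastic step derives from an explicit integer seed
(cohort seed, subject seed, CV seed), combined through a fixed modular
map and kept below $2^{31}$; reruns of `run_pipeline` with the same
configuration are byte-identical on disk, which is itself a test. The
serialized run configuration excludes the output path, so identity is a
property of the analysis, not of where it was written.

Degenerate inputs fail loudly and specifically: odd x-dimension grids
("asymmetric grid"), constant images, empty masks, collapsed knots,
single-class outcomes, straddling hemisphere masks, rank-deficient
additive designs (with the offending column named). Quasi-separated
logistic fits — likely at $n = 30$ with several covariates — are flagged
with a warning and their coefficients bounded by the fitting machinery
rather than silently diverging. Constant classifier scores return AUC
0.5 with an undefined threshold instead of an arbitrary one.

## 7. Known limitations

* The additive model is unpenalized; at $n = 30$ its repeated-CV
  predictions are high-variance, and the shipped example honestly shows a
  non-significant actual-vs-predicted correlation on some seeds even
  though the in-sample coupling is real and the attribution ranks the
  planted driver first.
* The AI sign guard (global shift) makes AI values scale-dependent for
  standardized inputs; comparisons across preprocessing configurations
  should compare thresholds only within a configuration.
* The elbow fallback for L-shaped curves returns a grid point; its
  precision is limited by the grid (200 points over the central 95% of
  the exposure).
* Exact Shapley is capped at 12 features by design; beyond that a
  sampling approximation would be needed and is deliberately not
  implemented.
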