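# pnms

Personalized neurometabolic signature (pNMS) mapping from interhemispheric
asymmetry of multimodal brain imaging, with everything downstream of the
maps: signature masks, ablation-overlap statistics, spline dose-response
threshold discovery, classifier evaluation, and structural interpretation.

## The problem

In drug-resistant mesial temporal lobe epilepsy (mTLE), MR-guided laser
ablation (MRgLITT) removes part of the hippocampus/amygdala, but roughly a
third of patients are not seizure-free a year later. FDG-PET hypometabolism
ipsilateral to the epileptogenic zone is a well-established marker of the
epileptic network. This package implements a quantitative pipeline that
turns that marker into a patient-specific target map and asks how much of
it must be ablated:

1. **Asymmetry-index (AI) mapping.** Each aligned volume (PET, T1
   gray-matter density, FLAIR) is smoothed (PET, Gaussian FWHM 6 mm),
   partial-volume corrected (PET, voxel-wise three-compartment
   Müller–Gärtner), z-standardized within the brain mask, and compared
   with its midsagittal mirror:
   `AI = (i1 − i2) / ((i1 + i2) · 0.5)`, where `i2` is the left–right
   flipped image. `AI < 0` means lower than the contralateral homologue;
   for nonnegative images `AI ∈ [−2, 2]`.
2. **pNMS construction.** The signature is the binary mask of ipsilateral
   voxels with `AI ≤ τ` (default τ = −0.06), the hypometabolic direction.
3. **Ablative rate.** For a region of interest R (hippocampus or
   amygdala), `rate = |pNMS ∩ R ∩ ablation| / |pNMS ∩ R|` — the fraction
   of the patient's metabolic abnormality that was ablated. Mask agreement
   uses the Dice coefficient `2|A∩B| / (|A|+|B|)`.
4. **Threshold discovery.** Outcome (seizure-free vs not) is modelled by
   logistic regression with a 3-knot restricted cubic spline
   (knots at the 10th/50th/90th percentiles, Harrell basis), model choice
   by BIC, nonlinearity by a 1-df likelihood-ratio test; the reference
   threshold is the inflection of the fitted log-odds curve (or its
   curvature elbow for L-shaped/monotone curves). Classification cut-offs
   come from Youden's J with trapezoidal ROC-AUC, and accuracy is reported
   both as balanced accuracy `(sens + spec)/2` and prevalence-weighted
   accuracy `w·sens + (1−w)·spec`.
5. **Interpretation.** Per-patient PET AI is predicted from five
   structural features (TIV, ipsilateral hippocampal and amygdalar
   volumes, their volumetric AIs) by an unpenalized additive spline model,
   evaluated by repeated 5-fold cross-validation, and attributed by
   *exact* Shapley values (all 2⁵ coalition refits) plus partial
   dependence.

No patient data ship with the package. A synthetic phantom generator
produces aligned multimodal subjects (symmetric ellipsoidal brain,
mirrored spherical ROIs, planted hypometabolism correlated with atrophy,
ablation cavities with controlled coverage, outcomes through a calibrated
logistic link), so the entire pipeline runs end to end from a seed.

## Worked example

```r
library(pnms)

report <- run_pipeline(run_config(seed = 1))
print(report)
#> <pnms_report n=30, seed=1>
#>   PET AI inflection: -1.0881 (L)
#>   ablative-rate Youden cutoff: 81.96%, AUC 0.864
#>   actual-vs-predicted r = -0.245 (P = 0.191)
```

The report says: on this seed's 30-subject phantom cohort the fitted PET
AI dose-response is L-shaped with its curvature elbow at AI = −1.09 (on
the z-scored, shifted scale the phantom produces — far more asymmetric
than clinical cohorts because the planted lesions are large and clean);
the hippocampal pNMS ablative rate best separates outcomes at a Youden
cut-off of 82% with AUC 0.86; and at n = 30 the cross-validated
structural prediction of PET AI does not replicate the in-sample
association (r = −0.25, not significant) — an honest small-sample result,
while the Shapley attribution still ranks hippocampal volume first.

Single pieces work standalone:

```r
s  <- make_phantom_subject(phantom_spec(seed = 1), subject_seed = 1)
ai <- preprocess_subject(s, run_config(seed = 1))
pnms <- binarize_pnms(ai$pet, threshold = -0.06,
                      hemisphere_mask(s$pet, s$ez_side))
ablative_rate(pnms, s$ablation_mask$values != 0,
              s$roi_labels$values %in% 1:2)
```

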