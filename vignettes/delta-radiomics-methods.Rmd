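---
title: "Delta-radiomics screening and response prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-radiomics screening and response prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltarad)
```

## The problem

During fractionated chemoradiation of pancreatic-head tumours, a CT volume
is acquired at every daily fraction (typically 28 over five-and-a-half
weeks). Texture statistics of the tumour region change as the tissue
responds, and the *relative* change of a feature from its first-fraction
baseline — a delta-radiomic feature (DRF) — is a candidate early biomarker
of eventual pathological response. `deltarad` implements the full chain:
texture extraction from masked 3D ROIs, DRF computation, a statistical
screen that discards redundant, motion- or scanner-sensitive and
non-discriminative features, and a response classifier built from a
Bayesian-regularized neural network combined with a Mahalanobis-distance
Gaussian discriminant.

Real daily-CT cohorts of this kind are not publicly deposited, so the
package ships two synthetic generators — one at the image level, one at
the DRF-table level — that reproduce the statistical structure the
analysis assumes. Everything the tests demonstrate is therefore a
statement about the *method* under controlled conditions, not about any
patient population.

## Texture features

Matrix features operate on a quantized ROI: equal-width bins over a fixed
intensity window (default 32 levels over [-200, 400], a soft-tissue CT
range). A fixed window, rather than per-image rescaling, is essential for
longitudinal work: it keeps gray levels commensurable across fractions, so
a DRF measures tissue change rather than windowing change.

* **GLCM** — symmetric co-occurrence counts at distance 1 for the four
  in-plane directions, accumulated over axial slices, summed and averaged
  over directions, then normalized. Fifteen Haralick-style statistics are
  derived; entropies use log base 2, and the information measure of
  correlation is the IMC1 variant (the feature list is ambiguous between
  IMC1 and IMC2; IMC1 is implemented and documented as the fixed choice).
* **GLRLM** — per-slice run-length matrices in the 0 and 90 degree
  directions, summed over slices and averaged over the two directions
  (the sum-then-average order is fixed and documented; whether reference
  implementations normalized before or after feature computation is not
  decidable from their outputs). A masked-out voxel breaks a run.
* **NGTDM** — Amadasun–King statistics with a 26-connected 3D
  neighborhood restricted to in-mask voxels. On a homogeneous ROI the
  coarseness denominator vanishes; it is guarded at `eps = 1e-6`, so
  constant input returns coarseness `1e6` with the other four statistics 0.
* **First-order** — moments (kurtosis is non-excess Pearson: normal = 3),
  quantiles, histogram uniformity/entropy, and the maximum-to-mean ratio.
* **Shape** — voxel volume and sphericity with a face-count surface area.
  Face counting overestimates a smooth surface by up to 3/2 (the
  staircase effect), so sphericity of a digital ball plateaus near 2/3;
  the measure still orders compact against elongated masks correctly.

Every matrix feature is property-tested against an independent
brute-force implementation (explicit per-voxel loops) on random small
ROIs to `1e-10`.

## The NESTD boundary feature

For contour quality assurance, each axial slice is cropped to a box
around the organ, quantized to 256 levels over the box range, and two
3-by-3 neighborhood maps are computed with mirrored (symmetric) border
padding: Shannon entropy of the neighborhood histogram (in bits) and the
sample (n-1) standard deviation. Both maps are min–max normalized to
[0, 1] over the box and subtracted — entropy minus standard deviation,
the order implied by the feature's name — giving the NESTD map in
[-1, 1]. At a boundary between a flat organ and brighter surrounding
tissue the standard deviation spikes while entropy saturates, so strongly
negative NESTD localizes edges; the per-slice overlay PNGs exist for a
human to check contours against (flagging is advisory; the package never
edits a mask). The scalar NESTD feature is the mean of the map over the
masked voxels of all slices. Normalization is per slice by default
(display-style normalization); per-volume normalization would couple
slices and is left as an option for users who want a single scale.
Because the quantization window follows the box range and both filters
are shift-equivariant, the scalar is exactly invariant to adding a
constant to the image.

## Delta-radiomic features and weekly aggregation

For fraction `n >= 2`, `DRF_n = (value_1 - value_n) / value_1`: positive
when the feature decreased from baseline, invariant to rescaling the
whole trajectory, undefined at zero baselines (dropped with a warning by
default). Week `k` covers fractions `5(k-1)+1 .. 5k`; the weekly DRF is
the mean over the week's available fractions (the combiner is not
uniquely determined by the source description; the mean is the documented
default). Week 1 uses fractions 2–5 only, since the fraction-1 DRF does
not exist, and weeks 2–4 aggregate fractions 6–10, 11–15 and 16–20.

## The screening cascade

1. **Spearman redundancy filter** (`|r_s| > 0.9` over all patient-fraction
   rows): greedy clustering, keeping per cluster the member with the
   largest variance (name as tie-break) — the survivor choice is not
   dictated by the method description, so a deterministic rule was fixed.
2. **Motion robustness**: DRFs are compared between low- and high-motion
   patients via the absolute difference of coefficients of variation
   (threshold 5 percentage points), the MSLR test for equality of CVs,
   and a Welch t test. The t test runs on per-patient mean DRFs: motion
   is a patient-level factor and pooled fraction values are correlated
   repeats, so testing them as independent observations would over-reject.
   Features whose group mean is numerically near zero have no stable COV
   and are conservatively marked not robust.
3. **Scanner effect**: Welch t tests between scanners within each
   response stratum (Bonferroni-corrected over strata so the combined
   gate holds level alpha) plus a regression of per-patient mean DRF on
   scanner adjusted for response.
4. **Trend**: pooled OLS with a response-by-fraction interaction; trend
   assessment is often done visually in practice, and the interaction
   p-value is this package's documented formal operationalization of
   "shows a trend".
5. **Group difference**: Welch t test of per-patient mean DRFs, plus
   descriptive per-fraction and per-week t tests with runs of consecutive
   significant fractions reported (these time-resolved tests do not gate
   candidacy).
6. **Mixed-model LRT**: see below.

A candidate passes all gates at `alpha = 0.05`. No multiple-testing
correction is applied by default, matching the screening design this
package follows; Benjamini–Hochberg is available as an option. The gate
is monotone in `alpha` by construction: relaxing it never removes a
candidate.

### The MSLR test

The modified signed likelihood-ratio test for equality of two
coefficients of variation works under a normal model in which
`sigma = tau * mu`. The profile log-likelihood over the common `tau` has
a closed-form inner maximizer for each group mean
(`n tau^2 mu^2 + T mu - S = 0`), leaving a 1-D optimization. The raw
signed root `r = sign(tau1 - tau2) * sqrt(LRT)` is noticeably biased at
moderate n; following the modified construction, its null mean and
standard deviation are estimated from `nr = 200` parametric simulations
at the fitted null and the standardized root squared is referred to
chi-square(1). Monte-Carlo calibration at `nr = 200` keeps one test below
~50 ms; the acceptance suite verifies an empirical type-I error within
[0.03, 0.07] over 2000 equal-CV gamma replicates at n = 30 per group.

### The crossed random-intercept mixed model

`DRF = b0 + b1 * response + u_patient + v_fraction + e`, with `u` and `v`
independent crossed random intercepts (the fraction effect is shared by
all patients — a longitudinal shock common to the cohort) and Gaussian
residuals. The likelihood is profiled over the fixed effects and residual
variance, leaving 2 parameters (log variance ratios) optimized with
multiple `nlminb` starts; all linear algebra runs on the
(patients + fractions)-dimensional random-effect system via the Woodbury
identity, so a 90-patient, 27-fraction feature fits in ~70 ms. ML rather
than REML is used throughout because the likelihood-ratio test compares
models with different fixed effects; the statistic is referred to
chi-square(1). Tests verify exact agreement with an independent
general-purpose mixed-model fitter and with a brute-force dense-covariance
ML fit, and the acceptance suite checks the empirical type-I error at the
study's own dimensions (<= 0.07 at nominal 0.05 over 500 replicates).

## Self-organizing map check

Per-patient OLS slopes of each candidate DRF against the fraction index
are presented to a batch SOM (default 4x4 rectangular lattice, Gaussian
neighborhood, radius decaying linearly to 0 over 20 epochs; dimensions
are declared defaults, not inferred ones). At radius 0 the batch update
is exactly a Lloyd k-means step, which the tests assert. Feature weight
planes with pairwise correlation above 0.9 are flagged; the SOM is
advisory (a redundancy confirmation), never a hard filter.

## Classifier

A 2-3 input, 3-tanh-hidden, linear-output network is trained on +/-1
targets by Levenberg–Marquardt minimization of
`beta * E_D + alpha * E_W`, with `alpha`, `beta` re-estimated by the
evidence framework (`gamma = k - alpha * tr(H^-1)`;
`alpha <- gamma / 2E_W`; `beta <- (n - gamma) / 2E_D`). Inputs are
standardized with training statistics stored in the model; initialization
is seeded, so training is deterministic.

Class models are Gaussian: per-class mean, sample covariance (ridged by
`1e-6 * trace/d` when the condition number exceeds `1e10`) and frequency
priors, fitted by default in the *augmented* space of the inputs joined
with the network output — the composition of network and minimum-distance
classifier is under-determined in the source description, and the
augmented space keeps the learned score in play while the covariance
measures each class's spread around it; a pure input-space variant is a
configuration option. Test points get the discriminant
`g_j = log p(w_j) - 1/2 log|c_j| - 1/2 (t - m_j)' c_j^-1 (t - m_j)`, with
exact ties broken deterministically toward the first class.

Scoring convention: ROC curves and AUCs rank by the (ensemble-mean)
network output; accuracy and confusion tables use the Gaussian
discriminant decision, and patient-level labels are majority votes over
the patient's samples (ties to the positive class). This mirrors the
design being implemented — the ensemble mean of the bootstrap networks
*is* the final model whose AUC is reported, while class assignment uses
the minimum Mahalanobis distance — and it matters in practice: under the
mixture-over-weeks class structure, ranking by the mis-specified Gaussian
posterior costs a few AUC points relative to the network score.

Evaluation is leave-one-patient-out (all of a patient's samples held out
together), pooled over folds; the external experiment trains on patient
-level bootstrap resamples (`nboot = 100`, class-incomplete resamples
redrawn), scores the disjoint test cohort with the ensemble mean, and
reports the 2.5/97.5 percentile (order statistics) of the per-model test
AUCs as the confidence interval. `combo_search` evaluates every 2- and
3-feature combination by CV-AUC with deterministic tie-breaks.

## Synthetic cohorts

**Image level** (`generate_cohort`): per patient, a fixed white-noise
base field; per fraction, the field is smoothed at the fraction's
correlation length and its marginal exactly shaped by a t-copula
transform to the fraction's mean/std/kurtosis, plus fresh voxel noise.
Knobs drift linearly with fraction at group-dependent rates with
per-patient relative offsets; high-motion patients get anisotropic blur,
scanner-B patients a distinct smoothing kernel and extra noise; the
ellipsoid mask is shared across a patient's fractions (contours are
propagated between registered fractions in practice). Baseline texture:
mean 100, std 60 (intensities spanning roughly the soft-tissue window),
kurtosis 4, correlation length 1.5 voxels. Mean/std/kurtosis slopes are
planted in feature units (the marginal transform is exact); note that on
strongly correlated or blurred fields the *sample* kurtosis of a finite
ROI shrinks toward 3, so the slope-recovery property is tested on a white
field with nuisance blurs off. The correlation-length knob moves
coarseness monotonically but without closed-form units — exact control of
matrix-texture features is infeasible, so it is calibrated by
measurement, not promised.

**DRF level** (`simulate_drf_cohort`): the workhorse for validating the
screen and classifier at full study scale (50 good / 40 bad patients, 28
fractions) without rendering 2520 volumes. A planted feature follows
`offset + slope_g * n + u_i + e` with per-(patient, feature) intercepts
`u ~ N(0, 0.03)` and noise `e ~ N(0, 0.08)`; defaults plant three
features ("kurtosis", "coarseness", "nestd") with offsets 0.50/0.45/0.40
and good-vs-bad slopes 0.016/0.006, -0.013/-0.005 and 0.010/0.004 per
fraction. The offsets keep group COVs moderate (DRFs well away from
zero), which is what makes a COV-based robustness grade meaningful; the
slope contrasts were sized once so that the three features jointly
separate the groups at a weekly-value Bayes AUC in the low 0.9s — the
regime the method is meant for — and are not revisited. Non-planted
features are pure noise around zero; real drift magnitudes are not
quantified anywhere, so planted slopes are harness parameters, not
biological claims. Motion and scanner assignments are stratified by
response group, mirroring how acquisition effects are properly assessed.

`bayes_optimal_auc` evaluates the ceiling any classifier can reach on
these cohorts: per class, a weekly value is an equal-weight mixture over
weeks of independent Gaussians with known means and variances; the
optimal score is the mixture likelihood ratio, and its AUC is computed by
a large seeded Monte-Carlo draw from the truth (2e5 per class, standard
error well under 0.002). Because both groups drift in the same direction,
pooling weeks 2–4 overlaps late bad-responders with early
good-responders, so the pooled Bayes AUC (~0.94 at the defaults) is
deliberately below the per-week ceiling — a structural feature of pooled
longitudinal scoring worth knowing when reading any pooled AUC.

What the generators do *not* emulate: anatomy, registration error,
deformable motion, stent artifacts, non-Gaussian noise, inter-observer
contour variability. Passing tests demonstrate the pipeline's statistical
behavior under its own assumptions, not performance on real CT.

## Problem sizes and numerical choices

The validation suite runs the screening recovery at the full cohort
dimensions (10 seeds), MSLR calibration with 2000 replicates, LRT
calibration with 500 replicates, and the classification experiment over
5 seeds with `nboot = 100`; the end-to-end comparison against the Bayes
ceiling is made on the mean CV-AUC over the 5 seeds, because a single
CV-AUC on 150 patient-clustered weekly values has a standard error of
about 0.03 — even the true Bayes rule's empirical AUC fluctuates that
much on one cohort.

Other fixed numerical choices: GLCM/GLRLM matrices use dense `G x Lmax`
storage; the BNN caps `alpha <= 1e6`, `beta <= 1e8` and damps
Levenberg-Marquardt up to `lambda = 1e12` before declaring a step failed;
covariance ridging is logged; `candidates()` requires mixed-model
convergence; all seeds derive from a single base seed via a fixed integer
mixing function, keeping every stage reproducible and independent of
evaluation order.

## Known limitations

* The COV robustness grade is undefined for features whose DRFs are
  centered at zero; such features are conservatively dropped rather than
  passed, which is the safe direction for a screen but means genuinely
  robust zero-mean features cannot become candidates.
* The MSLR test assumes normality within groups; with strong patient
  clustering at small cohort sizes it can over-reject. At the study's
  dimensions the deterministic trend dominates group variance and the
  test is near-nominal, as the calibration checks show.
* The trend regression treats fraction-level observations as independent;
  its interaction p-value is used as a ranking gate, not as a calibrated
  error rate (the mixed model is the calibrated test in the cascade).
* Sphericity uses face-count areas (see above); comparisons are valid
  within this package but not against mesh-based implementations.
* The pooled-weeks AUC ceiling depends on the planted drift geometry;
  cohorts whose groups drift in opposite directions would show higher
  pooled separability.
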