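---
title: "Methods: linking the serum lipidome to white-matter microstructure after TBI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking the serum lipidome to white-matter microstructure after TBI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lipidtract` implements the statistical machinery for relating a quantitative
serum lipid panel to ROI-level brain imaging in traumatic brain injury (TBI):
per-tract fractional anisotropy (FA) and mean diffusivity (MD) over the 48
white-matter tracts of the JHU ICBM-DTI-81 parcellation, and regional volumes
over 51 labels. Because cohorts of this kind are access-controlled, the
package pairs every analysis stage with a synthetic cohort generator whose
planted ground truth makes the whole pipeline testable end to end. This
vignette records the models, the tunable parameters, the numerical choices,
and what the synthetic validation does and does not establish.

## Data model and lipid preprocessing

A cohort couples subject metadata (group, age, sex, scanner site, MRI/CT
lesion status, time from injury to blood draw and to MRI, propofol
administration) with a samples x lipids concentration table (micrograms/mL
scale, strictly positive) and three subjects x ROI tables. Patients carry
lipid data; healthy controls contribute imaging only — they anchor the
harmonization and the normative baselines.

Lipid concentrations are natural-log transformed and standardized per lipid
to mean 0 and unit sample SD (denominator n − 1). The log base is
configurable (`log_standardize(cohort, base = )`); base e is the default
since only the standardized values enter any analysis, making the choice
inconsequential downstream. Standardization is computed over the samples in
the lipid table, i.e. patients, because controls have no serum samples.
Pearson correlation is used throughout on these log-standardized values.

## Scanner harmonization

FA and MD tables are adjusted with parametric empirical-Bayes ComBat,
re-implemented here (rather than wrapped) because the pipeline needs
*reference-anchored* estimation: all model components — per-ROI regression on
sex, age and age² over the reference subjects, pooled residual scale, and the
per-site additive (γ\*) and multiplicative (δ\*) effects shrunk by the
normal/inverse-gamma priors — are estimated on healthy controls only, then
applied to patients scanned at the same sites. A `reference = "all"` switch
estimates from everyone; in that mode the implementation agrees with
`sva::ComBat` to ~1e-8, which the test suite uses as an independent
cross-check. The EB solver iterates the standard conditional posterior means
to a relative tolerance of 1e-4 with a 100-iteration cap. Covariates
preserved during adjustment are sex, age and age² — the same terms as the
normative model — with age centred at the reference mean for conditioning.

Two practical consequences are worth knowing. First, harmonization is affine
per (site, ROI) on the *covariate-adjusted residual* scale, so it preserves
residual ranks within a site but not necessarily raw-value ranks when the
scale factor δ\* differs from 1. Second, with few controls per site the
site parameters carry estimation error that is fitted away for controls but
not for patients; patient deviations from a control-anchored baseline are
therefore slightly over-dispersed relative to the control residual SD. This
inflates abnormality rates above their pure-noise analytic values (see
below) — a generic property of reference-cohort normative pipelines, not an
implementation artifact.

Volumes are not ComBat-adjusted; each subject's ROI volumes are divided by
that subject's total brain volume, which removes head-size (and any global
affine scanner scaling) effects.

## Normative baselines and burden of injury

For each tract and metric, an OLS regression of the control values on sex
and a second-degree polynomial in age defines the expected healthy value;
the residual SD s (denominator n − 4) defines the baseline band. A patient's
tract metric is "out" when it deviates from the covariate-specific
prediction by more than 1 s two-sided, and a tract is *abnormal* only when
both FA and MD are out. The burden of injury is the percentage of evaluable
tracts that are abnormal; tracts with a missing metric drop out of both
numerator and denominator.

The band is deliberately defined on the residual SD around the regression
prediction rather than the marginal control SD: the regression exists
precisely to define the baseline, and a marginal band would mix age and sex
variance into the abnormality criterion. (`flag_abnormal(band = )` exposes
the width for sensitivity analyses.)

Under pure independent Gaussian noise the joint flag has false-positive rate
P(|Z| > 1)² = 0.3173² ≈ 0.1007 per tract. With a baseline *estimated* from
~100 controls the exact rate is slightly higher (≈ 0.108, the
t-distribution analogue), and with reference-anchored harmonization on ~10
controls per site higher again (≈ 0.13–0.14). The test suite checks the
analytic rate in the scenario that isolates the flagging rule (no site
effects, baseline fit directly), and treats the inflation under realistic
conditions as expected behaviour.

Group-level comparisons use a two-sample Kolmogorov–Smirnov test per tract
(exact p-values when both groups have at most 100 subjects, asymptotic
otherwise), with Benjamini–Hochberg FDR correction within each modality and
significance at q < 0.05.

## Correlation-frequency analysis

Every processed lipid is correlated with every ROI metric across patients;
two-sided p-values come from the t distribution on n − 2 df. The Holm
step-down correction is applied jointly over all lipid x ROI pairs of a
modality (family size 201 x 48 or 201 x 51) — the matrix-wide reading of
adjusting a full correlation matrix; a per-lipid family option exists behind
`holm_filter(family = "per_lipid")` for sensitivity analysis. Frequency
tables report, per lipid, the count k of significant tracts and the relative
frequency f = k/N (ties in the ranking broken lexicographically so output is
deterministic), and symmetrically per ROI. Per-ROI sign summaries collect
the significant correlation values (beanplot data) with their mean and sign;
an ROI with no significant lipid is reported missing, never as zero.

The lipid-class versus tract-injury matrix correlates, across patients, the
summed *raw* class concentration with the binary abnormal flag of each tract
(point-biserial). Tracts abnormal in none or all patients are undefined and
reported missing. Rows and columns are ordered by average-linkage
hierarchical clustering on correlation distance, mirroring the dendrogram
ordering of heatmap displays.

## Classifying MRI positivity

The two-stage filter ranks lipids by Welch t-test p-value and, separately,
by random-forest impurity importance (500 trees, √p candidate features per
split), and intersects the two top-30 sets; an empty intersection falls back
to the union with a warning. The selected lipids feed an L1- or
L2-penalized logistic regression whose regularization strength is chosen by
5-fold class-stratified cross-validation on the training split
(`lambda.min`). Performance is the held-out AUC over repeated stratified
70/30 splits (100 by default), with *feature selection re-run inside every
training split* — the design guarantees no information leak, and the test
suite verifies it with permuted labels (mean AUC must stay at chance; a
leaky implementation inflates it). The full grid is 2 penalties x 2 feature
modes x 2 scopes (all patients with known MRI status; the CT-negative
subgroup), eight AUC cells aggregated as mean, median and IQR. Patients with
missing MRI status are excluded from classification only.

Hyperparameters the source analysis leaves open (stratification, forest
settings, λ selection, tie and empty-intersection rules) are set to the
conventional defaults above and exposed as arguments; the validation surface
is calibration and power behaviour on synthetic cohorts, not any specific
AUC value.

## Partial-correlation networks

The 40 lipids (20% of the 201-lipid panel) with the most Holm-significant
correlations — restricted to lipids with at least one — enter a network over
lipids, the 48 tracts (nodes tagged midline/left/right from the registry)
and four covariates: age, time to blood draw, time to MRI, propofol (coded
0/1 and residualized linearly). For each pair of analysis variables both are
residualized on the four covariates and the residuals correlated;
significance uses the t distribution on n − 2 − 4 df. Variable–covariate
edges condition on the other three covariates. Edges are kept at raw
p < 0.05 with their sign; **no multiplicity adjustment is applied to network
edges**, by design, so edge counts scale with the number of hypotheses.

Pairwise partial correlation (not a joint precision matrix) is used: with
n ≈ 103 and > 90 nodes a joint precision estimate is ill-conditioned, and
"controlling for the covariates" is exactly what pairwise residualization
does. Under inert covariates the pairwise partial correlation equals the
marginal correlation up to the df change, which the tests verify.

## The synthetic cohort generator

`simulate_cohort()` draws cohorts with the structure the analysis assumes:
103 patients and 104 imaging-only controls over 9 scanner sites; control
tract values are baseline(age, sex) + site effect + Gaussian noise with a
linear sex offset and quadratic age trend; FA baselines ~ U(0.35, 0.60) with
residual SD ≈ 0.02, MD ~ U(0.70, 0.90) (units of 10⁻³ mm²/s) with SD ≈
0.03. Sites displace ROIs additively (scale `site_additive_sd`, in residual
SDs) and multiplicatively (log-scale SD `site_multiplicative_sd`). Volumes
are a per-subject head-size factor times ROI means with 5% noise, plus a
total brain volume proportional to the head factor, so TBV normalization has
exactly the right thing to remove.

Each patient draws an injury propensity from a Beta distribution (shape 1.2)
with mean `injury_fraction` — a mostly-mild, severe-tailed mix as in
clinical TBI cohorts — and tracts are injured independently at that rate;
injured tracts lose `fa_shift_sd` residual SDs of FA and gain `md_shift_sd`
of MD (default 3, a clearly detectable microstructural lesion). Log lipid
levels are multivariate normal with exchangeable correlation 0.4 within and
0.1 between classes (a co-regulation convention, not an estimate of any real
covariance). Planted lipid–tract couplings replace a lipid's innovation with
`assoc_strength` times the standardized observed tract value (positive for
FA, negative for MD), so the planted population correlation is known; the
default 0.5 is chosen so planted signal survives a matrix-wide Holm family
of 201 x 48 tests at n = 103 with good power (the per-test threshold there
is ≈ 5e-6, i.e. |r| ≈ 0.43). MRI positivity follows a logistic model with
log-odds `mri_effect` per SD of each of `n_mri_lipids` informative lipids;
CT positivity is drawn so that roughly a fifth of MRI-positive patients are
CT-negative. Planted couplings target FA and MD only; volumetric
correlations in synthetic cohorts arise through noise alone. Patient
covariates (times, propofol) are generated independent of the lipids so the
network stage's covariate control can be tested for false positives. FA is
clamped to (0, 1) and MD/volumes to positive values, with clamp counts
recorded in the cohort provenance.

What the synthetic validation shows: correct arithmetic and calibration
(null rates at their analytic values, FWER/FDR control), parameter recovery
(site effects, baselines, planted correlations and their signs), and absence
of information leaks. What it does not show: anything about real serum
lipid distributions, real spatial covariance of tract metrics (tracts here
are independent given covariates and site), LC-MS measurement artifacts, or
the transferability of any specific AUC to CENTER-TBI-like data.

## Numerical choices and degenerate inputs

* Zero-variance lipids or ROIs are hard errors naming the column; constant
  tracts in a KS comparison return D = 0 by convention.
* Correlations are clamped away from ±1 by 1e-15 before the t transform.
* All rankings break ties lexicographically; all outputs have deterministic
  column order, and result files round-trip byte-identically through
  `write_results()`/`read_results()`.
* The pipeline derives per-stage seeds from one master seed, so a full run
  is reproducible and stages can be re-run in isolation.
* Simulation sizes in the test suite are chosen per check: 500 replicates
  for FWER/FDR calibration, 500 patients for null-rate and recovery checks,
  n = 103 for power checks at the cohort's own scale, 600 controls for
  site-effect recovery.

## Known limitations

* Reference-anchored ComBat with few controls per site leaves patient-side
  site noise (quantified above); burden comparisons across sites inherit it.
* The CT-negative classifier scope can be small and unbalanced; evaluation
  errors out rather than silently degrading when a class cannot keep two
  members in every training split.
* Network edges are unadjusted for multiplicity by design; interpret edge
  counts, not individual edges, under the null calibration reported by the
  acceptance script.
* The exact KS p-value is used only up to 100 subjects per group; beyond
  that the asymptotic approximation is standard but slightly conservative
  for mid-sample sizes.
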