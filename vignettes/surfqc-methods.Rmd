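---
title: "Methods: surface-reconstruction QC and quality-impact analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface-reconstruction QC and quality-impact analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfqc)
```

This vignette documents the models, conventions and design decisions
behind `surfqc`. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` compute.

## 1. Snapshot generation

The unit of visual QC is a set of slice views of a subject's T1 volume
with the white and pial surface contours of both hemispheres overlaid.
All voxel/world conversions go through the volume's 4x4 affine
(0-based voxel indices, world millimetres); surfaces are assumed to be
in the volume's world frame, with an optional per-subject rigid offset
(the `cras` translation carried in FreeSurfer surface footers) applied
at load. Ignoring that offset misplaces every contour by the offset
vector, which is why the loader applies it silently when present.

**Slice placement.** Slices are placed at fixed *fractions* of the
per-subject brain bounding box — the tightest world-axis-aligned box
containing all voxels above a fraction (default 0.1) of the maximum
intensity — rather than at absolute coordinates. Fractional placement
generalizes across fields of view and head positions and guarantees no
view falls off the edge of the brain, at the cost of slice positions
that are not anatomically identical across subjects. The defaults are
3 axial and 3 coronal views at fractions 0.30/0.50/0.70 and 4 sagittal
views at 0.25/0.40/0.60/0.75: the sagittal list deliberately omits 0.5
so no view shows the midline, and each hemisphere is captured twice.
All fraction lists and counts are configuration, so 20-view (6/6/8)
or denser sets are one argument away.

**Contours.** For each triangle whose vertices straddle the cutting
plane, the intersection segment follows from linear interpolation of
signed vertex distances along the two crossing edges. Two numerical
choices matter:

* vertices within 1e-9 mm of the plane are nudged to +1e-9 mm
  (a simulation-of-simplicity perturbation), which removes all
  degenerate cases — triangles in the plane, zero-length segments —
  at measure-zero geometric cost;
* intersection points are keyed by their *mesh edge* with the lower
  vertex index first, so the two triangles sharing an edge compute
  bit-identical endpoints and chaining is exact integer bookkeeping,
  not floating-point tolerance matching. The chaining tolerance
  argument (default 1e-6 mm) therefore only enters the closed-polyline
  check.

For a closed mesh and a generic plane every chained polyline is a
cycle; the tests assert this on random mesh/plane pairs, and assert
equality of total chained length with a brute-force per-triangle
enumeration to 1e-9 mm.

**Sampling and rendering.** Slice images are sampled
nearest-neighbour by default so that raw-intensity artifacts — the
ringing/rippling that raters must see to assign "visible motion" —
survive resampling; trilinear interpolation is available but smooths
exactly the evidence the rating scale needs. Rendering writes the
pixel array directly through `png`, making snapshot bytes a pure
function of inputs and style; determinism is tested byte-for-byte.

**Anonymization.** Each image name is replaced by the MD5 digest of a
salt plus the original filename, and the rating order is a seeded
uniform permutation pooled over all subjects and sites, so consecutive
images never cue the rater with same-subject or same-site context. The
salt means identical filenames across studies cannot be linked without
the manifest, which records the salt, seed and the full bijection for
de-anonymization.

## 2. Rating and the FSQC score

Ratings use a four-level ordinal scale: good (1), minor error (2),
visible motion (3), bad (4). "Bad" outranks "visible motion" because
localized motion artifact need not invalidate a reconstruction,
whereas large missing or mis-traced cortex does. Categorical ratings
are converted to 1–4 and averaged with equal weight over a subject's
images, then over raters — no reliability weighting, matching the
simplicity of the protocol. The resulting FSQC score is continuous in
[1, 4], higher = worse. A per-image worst-rating export supports
exclusion rules based on single images rather than the average.

Deliberation-time summaries first drop, per rater, times more than 5
median absolute deviations from that rater's median over all of their
image times (breaks and distractions, not deliberation), then take
medians over images within participant and over participants within
rater. When at least half of a rater's times are identical the MAD is
zero; the filter then falls back to dropping only times exceeding
5 times the median, preserving the intent of the cut without dividing
by zero. The outlier pass runs over a rater's full set of times
(rather than within participant) because ten times per participant
give a uselessly unstable MAD.

## 3. Reliability statistics

Spearman correlations use average ranks for ties and the t
approximation for p-values (`t = rho * sqrt((n-2)/(1-rho^2))`), with an
exact permutation option for n <= 10. The intraclass correlation is
the two-way random-effects, absolute-agreement, *single-measure*
ICC(A,1), computed from the participants-by-raters mean squares. The
single-measure form is the conservative choice when the published
score is a single rater's (or a small average's) rating; the
average-measure ICC(A,k) is available by argument. Absolute agreement
(not consistency) is the right variant because a rater with a constant
offset produces genuinely different scores. Consensus flagging uses a
strict inequality — a discrepancy of exactly 1.0 between two raters is
tolerated, anything greater is flagged for discussion.

## 4. Topology metrics

For a triangle mesh, chi = V − E + F with E counted as unique
unordered vertex pairs over faces. A perfect cortical hemisphere is a
topological sphere (chi = 2); each handle left by reconstruction error
lowers chi by 2, so the defect index (2 − chi)/2 counts handles. The
per-subject index is the *sum* of hemisphere defect counts, higher =
worse, which yields a non-negative integer scale; externally supplied
signed per-hemisphere Euler numbers are harmonized through
(2 − chi)/2 per hemisphere, which preserves ordering exactly. Whether
an upstream pipeline summed or averaged hemispheres is metadata the
user can override when ingesting precomputed columns.

MAD-based thresholds use `median + k * MAD` with a raw MAD (scale
constant 1.0) by default — the published Euler threshold series this
convention mirrors is consistent with an unscaled MAD — and the 1.4826
normal-consistency constant is an argument. Threshold filtering
retains boundary values (exclude strictly worse than the cutoff);
a flag flips to strict retention. Filters report exclusions by site
and by diagnosis, because differential exclusion is itself a finding.

## 5. Quality-impact models

Every regional analysis fits, per region,

```
value ~ quality + age_c + age_c2 + sex [+ diagnosis ...] + (1 | site)
```

by REML via `lme4`, with a single random intercept for site (no random
slopes). Age is mean-centered before squaring, which decorrelates the
linear and quadratic terms without changing the model space. When a
cohort has one site the model degrades to OLS with a warning; singular
fits are flagged but their fixed effects are still reported.

* **Partial correlation.** The quality effect is reported as
  r = t/√(t² + df) with df = n − (number of fixed-effect parameters),
  the residual-df convention. On fixed-effects-only designs this
  equals the correlation of the two residual vectors from regressing
  response and quality on the remaining covariates, which the tests
  verify.
* **Sign convention.** Positive r always means "worse quality, larger
  value": metrics declared higher-is-better are negated at the
  reporting layer, so maps are comparable across metrics.
* **FDR.** Benjamini–Hochberg across the regions of one
  analysis-by-phenotype-by-metric combination; no pooling across
  phenotypes or metrics. Thresholded (significant-only) and
  unthresholded maps are both exported.
* **Cohen's d.** Binary-term effects convert the model t via
  d = t·(n₁+n₂)/(√(n₁n₂)·√df). The mixed-model t absorbs site
  variance, so this is a covariate-adjusted d.
* **Strategies.** Case-control comparisons run under `none`,
  `covariate` (quality in the model), `threshold` (exclude beyond a
  cutoff first) and `hybrid` (threshold on one metric, covary
  another). Degenerate inputs degrade loudly: a constant quality
  column drops the covariate with a warning (reducing to `none`), a
  filter that empties a diagnostic group errors, a sweep point
  excluding more than 95% of rows is flagged rather than fitted.

## 6. The synthetic cohort and what it does (not) show

`simulate_cohort()` draws, in order: site intercepts ~ N(0, tau²);
per participant age ~ U(6, 30) years, sex ~ Bernoulli(0.5), diagnosis
~ Bernoulli(0.45); latent quality
q = beta_age·(age − mean age) + beta_dx·dx + site share + noise, with
beta_age = −0.015/year (younger is worse) and beta_dx = +0.15 on a
quality-noise SD of 0.5 — so cases are about 0.3 residual SD worse,
the size of quality-diagnosis confounds reported in multi-site autism
cohorts. Observed FSQC is clip(1.6 + q, 1, 4); the Euler index is
round(exp(4.6 + 0.8q + eps)), a log-linear readout whose heavy right
skew (median near 100, long tail) mimics real Euler distributions
without claiming distributional equality. Region values add a
baseline, small age and sex effects, an optional diagnosis effect, a
site intercept and a quality effect.

Two design choices deserve emphasis:

* **Quality slopes are specified in partial-r units.** The requested
  per-region partial correlation is converted to a model-unit slope
  using the SD of the quality residual after age, age², sex and site,
  estimated on a large internal reference draw (default n = 50,000)
  from the same generative law. The exported ground truth is therefore
  the *implied* partial r, and tests verify it against brute-force
  partial correlations on 10⁵-row samples to ±0.01. Defaults make
  45% of regions negative (U(−0.45, −0.05)), 35% null, 20% positive
  (U(0.05, 0.35)) — largely negative with a minority of genuine
  positive associations, the qualitative pattern regional
  quality-morphometry maps show.
* **Effects route through observed FSQC by default**, so the analysis
  model is correctly specified under the covariate strategy and
  estimator correctness can be tested separately from model misfit; a
  switch routes effects through latent quality instead, and a
  `tail_pivot` option concentrates effects in the worst-quality tail
  (effects proportional to max(FSQC − pivot, 0)), the regime in which
  threshold-based exclusion, rather than covarying, removes the
  confound.

The default region count is 360 (a multimodal-parcellation-resolution
table), reducible to 68 for a Desikan-Killiany-like run; tests and the
acceptance script use 12–68 regions and n = 1,500–2,000 participants,
sizes at which one analysis (one mixed model per region) takes seconds
while effect-recovery error is a few hundredths in partial-r units.

The phantom and cohort emulate the *statistical* structure the
analyses assume — geometry with known cross-sections and topology,
quality gradients over age/diagnosis/site, both-signed regional
effects — not MRI physics or cortical folding. Passing tests therefore
demonstrate that the estimators recover what the generative model put
in; they do not certify behaviour under misspecification beyond the
latent-channel and tail variants, nor on real scanner artifacts.

## 7. Numerical and statistical caveats

* The BH step controls the *expected* false-discovery proportion; on a
  single cohort the realized fraction of null regions flagged is a
  noisy quantity, so calibration checks pool several seeded cohorts
  (and the all-null calibration uses 200 replicates).
* The mean absolute partial correlation across regions has a noise
  floor of roughly sqrt(2/(pi·n)); as thresholds exclude participants,
  n falls and this floor rises, so attenuation monotonicity is
  asserted with a small allowance (0.02) rather than strictly.
* Under a *linear* quality-effect channel, thresholding can reduce but
  not eliminate a quality-diagnosis confound (the retained sample
  still carries quality variance correlated with diagnosis); full
  elimination by thresholding requires — and in the tail-concentrated
  scenario gets — effects confined to the excluded tail. Covarying
  eliminates the confound exactly when the model is correctly
  specified.
* MGH volumes are written as 32-bit float, FreeSurfer surfaces as
  32-bit float vertices: round-trips are exact for values representable
  in single precision and good to ~1e-6 relative otherwise.
* Missing region values are kept as missing, never imputed; each
  regional fit drops incomplete rows and reports its n.

## 8. Known limitations

No DICOM, annot/label/stats readers, or surface formats beyond the
FreeSurfer triangle format; no vertex-wise analysis, longitudinal
models, site-harmonization (ComBat-style) or Bayesian fits; the
per-site meta-analytic and variance-partitioning extensions are out of
scope, though per-site fits can be exported and meta-analyzed
externally. The rating session is a minimal local loop with the same
data contract as a hosted rating app, not a web deployment.
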