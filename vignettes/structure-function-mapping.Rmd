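---
title: "Mapping structure to function: models, simulations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping structure to function: models, simulations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oct2vf)
```

## The problem

In glaucoma, retinal ganglion cell axons die; their loss is visible
structurally as thinning of the peripapillary retinal nerve fiber layer
(RNFL) on OCT, and functionally as reduced light-sensitivity thresholds on
standard automated perimetry (SAP). The *structure-function (SF) map* — which
visual-field locations respond to damage at which angular position around the
optic disc — underpins the clinical interpretation of both tests. This
package learns that map from data: a small one-dimensional convolutional
network regresses the 52 thresholds of a 24-2 field onto the 768 thickness
samples of the peripapillary circle scan, and the map is then read out by
carving localized defects of controlled position and depth into a normal
average profile and observing the predicted fields.

Because suitable clinical registries are private, the package ships a
synthetic cohort generator with a *known* forward model. Every pipeline claim
is validated against that ground truth; nothing in the package depends on
access to clinical data, and real cohorts in the same CSV layout can be
substituted directly.

## Geometry and conventions

All analysis is in right-eye convention: field x > 0 temporal, y > 0
superior; profile angle 0° temporal, 90° superior, 180° nasal, 270° inferior
(the TSNIT axis). Left-eye exams are mirrored on ingest
(`normalize_laterality()`): the profile index is reflected about the 0°/180°
axis; field values are stored index-aligned across lateralities, so only the
coordinate tags change. Mirroring is an involution and preserves the value
multiset.

The 24-2 grid is built row-wise from superior to inferior, nasal to temporal
within a row; the two points at (15, ±3), adjacent to the blind spot, are
excluded, leaving 52. The per-point assignment to the six Garway-Heath field
regions (central, temporal, superior, superior-nasal, inferior,
inferior-nasal) and the per-point optic-disc entry angle live in an editable
YAML config (`inst/extdata/gh_sectors.yaml`). **This table is an assumption**:
the published map does not print per-point disc angles, so the shipped config
is a reconstruction that respects the anatomy (superior field ← inferior
disc, central points ← temporal disc, temporal wedge ← nasal disc, with
entry angles mirrored about the horizontal). Anyone with a better table can
swap the file without touching code.

## The synthetic cohort and its forward model

`generator_config()` collects every generator parameter; the defaults are
the package's fixed study conditions:

* **Cohort structure** — 1,500 patients, 1–2 eyes each, 1–4 paired exams per
  eye (≈ 4,500 pairs), 60% of patients glaucomatous, ages ~ N(63, 14²) years
  truncated to [25, 95]. These echo the scale and mix of a large clinical
  glaucoma registry at roughly one-sixth size.
* **Healthy profile** — a 360°-periodic double-hump curve: 50 µm temporal
  base plus 45 µm Gaussian bumps (width 35°) at 80° and 280°, the
  superior-temporal and inferior-temporal bundles. Subjects jitter the base,
  amplitudes and peak positions; exams add 2 µm white measurement noise.
* **Disease** — glaucomatous eyes draw a diffuse multiplicative loss
  (U(0.75, 1)) and one or two localized wedge defects: centres biased toward
  the arcuate bundles (70% from Gaussians at 60°/300°), widths U(20°, 70°),
  fractional depths U(0.35, 0.85), cosine-tapered edges. The *generated*
  disease is smooth-edged and multiplicative — deliberately unlike the
  abrupt percentile-replacement defects used later to probe the trained
  model, so the probe is not simply re-presenting training patterns.
* **Forward model** — for field point *i* with disc entry angle α*ᵢ*, local
  thickness *tᵢ* is the circular-Gaussian-weighted profile average around
  α*ᵢ* (σ_map = 15°). Noiseless sensitivity is
  `clamp(N_i(age) + 10·γ·log10((t_i − b)/(t̄_i − b)), 0, 40)` dB with
  γ = 1, residual floor b = 30 µm (non-axonal tissue), t̄*ᵢ* the same
  functional of the healthy mean curve, and
  `N_i(age) = 34 − 0.12·ecc_i − 0.07·(age − 50)` dB. The log-scale, floored
  form encodes the classical dB-vs-structure nonlinearity; the −0.07 dB/yr
  ageing slope is a standard perimetric value, applied uniformly because no
  per-point model was specified.
* **Noise** — threshold noise SD is σ₀ = 1.5 dB above a 25 dB knee and grows
  by 0.4 dB per dB below it, capped at 8 dB. This reproduces the well-known
  explosion of SAP variability once sensitivity falls below ~15 dB, which
  bounds what any predictor can achieve at low sensitivities.
* **Metadata** — 6% of exams are generated unreliable (fixation losses
  > 33% or false positives > 15%), 4% with OCT quality below 15, 3% with the
  OCT more than 180 days from the SAP, so the curation rules have real work
  to do.

What the generator does *not* emulate: media opacities, fixation behaviour,
lens artifacts, floor effects of OCT segmentation, spatially correlated
threshold noise, and learning/fatigue effects. Passing tests therefore
demonstrate that the pipeline recovers a known nonlinear SF relationship at
realistic noise levels — not that the trained weights transfer to clinical
data.

## Curation

Pairing takes, per eye and SAP test, the nearest-in-time OCT within
±180 days (inclusive), ties toward the earlier OCT; one OCT may serve
several SAP tests. The reliability filters follow the exclusion wording
literally: fixation losses above 33%, false positives above 15%, or quality
below 15 exclude; the boundary values 0.33, 0.15 and 15 are retained.
Splitting is at the patient level (test 15% of patients, validation 15% of
the remainder) so no patient contributes exams to two sets — the single most
important guard against optimistic evaluation with repeated measures.

## The models

The network is conv(32 kernels, size 3) → ReLU → conv(64, 3) → ReLU →
flatten → dense(54) → ReLU → dense(52, linear), trained with Adam
(lr 10⁻³, β₁ 0.9, β₂ 0.999, ε 10⁻⁷) on mean squared error, restoring the
weights of the epoch with the lowest validation MSE. The full 768-point
profile feeds every output: no topographic prior is imposed, so any
structure-function correspondence in the trained model is learned from data.

Points the architecture description leaves open were fixed as the simplest
reading and are recorded here as assumptions: valid (no) padding, stride 1,
no pooling (flatten length 764·64); Glorot-uniform initialization; inputs
scaled by 1/100 (µm → ≈[0, 2.5]) with the constant stored in the model;
batch size 128; no circular padding despite the circular geometry. The
implementation is an im2col formulation over BLAS matrix products with small
C++ kernels for the fused elementwise steps; the forward pass is verified
against a brute-force convolution oracle, the backward pass against central
finite differences in a kink-free regime, and training is bit-for-bit
reproducible under a fixed seed in single-threaded BLAS.

The baseline is ordinary least squares per output on the identical inputs.
With fewer exams than 768 predictors it would interpolate; the fit then
falls back to a lightly penalized ridge solution with a warning (training at
the default scale has ~2,900 exams, so the OLS path is the one exercised).

## Reports and normative tables

Normative tables are estimated, not assumed: per-point linear age
regressions of healthy thresholds, empirical total-deviation and
pattern-deviation percentiles ({5, 2, 1, 0.5}%), the pointwise healthy mean
profile, and pointwise 10th/5th/1st percentile profiles of the glaucoma
group (linear interpolation between order statistics, so small-sample tests
can be exact). Total deviation is threshold minus age-corrected normal;
pattern deviation subtracts the 7th-largest total deviation (ties counted,
1-based — the conventional "seventh best" general-height estimate);
probability categories take the most extreme percentile at or below which
the deviation falls, boundaries inclusive toward abnormal. MD is the
unweighted mean of TD and PSD the sample SD about it — proprietary
eccentricity weights of commercial perimeters are deliberately not imitated,
so MD/PSD here are comparable within the package only. Displayed thresholds
are clamped to [0, 50] dB at render time only; model outputs are never
clamped.

Both TD- and PD-based probability plots are computed and rendered, as on
commercial printouts, since either could be the one a reader wants.

## Defect simulation and the SF map

Simulated defects replace the profile inside a half-open 30° sector
`[start, start+30)` by `min(base, P_q)` with q ∈ {10, 5, 1}: abrupt edges
(a step at the boundary, matching how such simulations are conventionally
drawn), pointwise percentile replacement rather than a flat offset, and a
`min` guard so a percentile above the healthy mean can never thicken a
profile. Half-open membership makes the 12 sectors an exact partition of the
768 indices (64 each). The SF map is the 12 × 3 array of simulated profiles,
their predicted fields and derived reports; an "abnormal" point in map
summaries is a pattern-deviation probability worse than 5%.

Under the generator's own forward model used as the predictor, every
simulated defect produces abnormality strictly in the hemifield opposite the
defect's hemiretina, and abnormal-point counts are monotone in depth — both
asserted as tests. The trained network is held to the looser, scientifically
meaningful version: for the deepest (p1) simulations in the arcuate sectors
(30°–90° and 270°–330°), mean pattern deviation is lower in the opposing
hemifield than in the defect's own.

## Problem sizes, tolerances and numerical choices

* The validation experiment uses the generator defaults: 1,500 patients /
  ≈4,500 pairs, 30 training epochs. These sizes were chosen as the package's
  standing desk-scale protocol: large enough that OLS is comfortably
  overdetermined and the network converges to the noise floor (validation
  MSE plateaus near σ₀² plus the age-term variance by ~epoch 20), small
  enough to run routinely. The full 100-epoch protocol is available by
  changing `training_config()`.
* Exact identities (grid counts, report identities, partition counts,
  filter boundaries) are asserted exactly; oracle equivalence of the forward
  pass at 10⁻⁶; stochastic recoveries (ageing slope, mixed-model difference,
  bootstrap coverage) at tolerances implied by their sampling distributions.
* Quantiles use type-7 interpolation everywhere. The forward model guards
  `log10` with an ε = 10⁻³ µm floor above b. Ties in "seventh best" follow
  the sorted order with duplicates counted. `which.min` tie-breaks toward
  the first enumerated simulation.
* Bootstrap clusters are patients, not eyes or exams, matching the level at
  which the mixed model accounts for repeated measures. The equality-of-
  correlations test is primarily a cluster bootstrap of the difference in
  average pointwise r (the average is over the 52 per-point correlations;
  pooling over point-exam pairs is the documented alternative); a Fisher-z
  statistic is reported for reference but ignores the dependence.

## Known limitations

* The Garway-Heath point table and disc angles are a reconstruction
  (above); sectoral summaries depend on it.
* The generator's noise is independent across points; real SAP noise is
  spatially correlated, which would loosen pointwise correlations.
* MD/PSD are unweighted package-internal indices.
* The CNN's behaviour for profile shapes absent from training (e.g. isolated
  temporal wedges) is unconstrained — a property shared by any learned SF
  map and the reason the defect simulations probe only percentile-depth
  sector defects.
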