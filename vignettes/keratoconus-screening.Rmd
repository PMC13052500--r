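---
title: "Methods: simulated PS-OCT keratoconus screening and cross-device model comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated PS-OCT keratoconus screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(kcscreen)
```

## The problem and the pipeline

Subclinical keratoconus (SKC) sits between clearly healthy corneas and
clinically evident keratoconus (KC): the anterior surface is still
near-normal, yet the eye is at ectasia risk. Screening instruments see the
disease through different physics — Scheimpflug tomography (Pentacam),
hybrid Placido/OCT tomography (MS-39), and polarization-sensitive OCT
(PS-OCT), which measures the depth-integrated birefringence of stromal
collagen as a phase retardation (PR) between two orthogonal detection
channels. `kcscreen` implements the full comparison pipeline: simulate a
three-class cohort with realistic class-conditional structure, encode each
device's view as a fixed feature schema, train one random forest per device
under an identical protocol, and quantify where the devices agree and which
subclinical eyes each model reclassifies as healthy.

The signal model is deliberately minimal. With channel amplitudes
$A_1(z), A_2(z)$, reflectivity is $R(z) \propto A_1^2 + A_2^2$ (only
relative reflectivity matters, so the proportionality constant is fixed at
1) and phase retardation is $\mathrm{PR}(z) = \arctan(A_2/A_1) \in [0°,
90°]$. A sample with $A_1 = 0, A_2 > 0$ is exactly 90°; a sample with both
channels zero carries no polarization information and is masked invalid
rather than zeroed. The en-face PR map samples each A-scan at its posterior
corneal surface index (a single sample, not a neighbourhood average — the
simplest defensible reading), because the posterior surface is polarization
preserving and integrates the stromal birefringence above it.

## En-face maps and their processing

Maps are regular grids centred on the apex: PR on a 10 × 8 mm field,
epithelium (ELT) and Bowman's-layer (BLT) thickness on 8 × 8 mm, all at
0.25 mm pitch (41 × 33 and 33 × 33 pixels; fine enough to resolve a
1.6 mm cone, coarse enough that a full 359-eye cohort generates in
seconds). Pixel centres span ±extent/2, so extent = (n−1)·spacing. All maps
pass through a 1 × 1 mm floating-average filter — the window is converted
to the nearest odd pixel count covering the physical size (5 × 5 at
0.25 mm); at borders the window shrinks to the available valid pixels
rather than inventing padding, and masked pixels never contribute.
Cropping (e.g. the 10 × 8 PR field to the common 8 × 8 analysis field) is
centred and spacing-preserving.

## Zernike encoding

Spatial maps are reduced to Zernike coefficients through radial order 6
(28 terms). Convention: OSA/ANSI single indexing $j = (n(n+2)+m)/2$ with
orthonormal (unit-RMS over the unit disk) normalization — the most common
choice in ophthalmic optics; with it, the RMS of any term group is the
root-sum-square of its coefficients, which is how the low-order/high-order/
coma RMS summaries are computed. The fit is ordinary least squares over the
valid pixels inside a centred 8 mm pupil (the largest disk common to both
field sizes; Zernike terms need a disk domain), with coordinates normalized
by the pupil radius, solved by QR decomposition. Rank deficiency — fewer
valid pixels than terms, or degenerate geometry — is an error, never a
silent pseudo-inverse. Classification is invariant to any fixed invertible
linear re-indexing of the coefficients, so the convention choice affects
interpretability, not results.

Feature schemas:

* `psoct84`: PR, ELT and BLT coefficient blocks, 28 each, in that order.
* `pentacam32`: anterior keratometry (K1, K2, K mean, K max, flat axis,
  astigmatism), six derived indices (ISV, IVA, KI, CKI, IHA, IHD), and ten
  front- plus ten back-surface wavefront terms.
* `ms39_23`: anterior and epithelium–Bowman's interface keratometry (4 + 4),
  their five-term wavefront summaries (LORMS, HORMS, ComaRMS, Defocus, SA),
  and five Zernike summaries of the epithelium thickness map, computed from
  the map's own order-6 fit by the RMS-grouping formulas (low order =
  orders 1–2 excluding piston; high order = 3–6; coma = the two third-order
  coma terms; defocus and primary spherical aberration as single
  coefficients).

## Ground-truth labeling

Groups are defined by composite index boxes on KISA%, the inferior–superior
value and BAD-D (healthy: < 60, < 1.4, < 1.65; SKC: < 60, < 1.6, < 2.6;
KC: > 60, > 3.0, > 3.0), read as strict inequalities — equality fails the
criterion. The healthy box is numerically contained in the SKC box; what
separates the groups in practice is clinical context (fellow eye of an
asymmetric KC patient, suspicious imaging), represented by a
`clinical_suspect` flag. Precedence is KC, then healthy (no suspicion),
then SKC (with suspicion); anything else — including eyes in the gap zones,
e.g. IS between 1.6 and 3.0 — is `indeterminate` rather than silently
assigned. Real-data users should treat `indeterminate` as "excluded by the
inclusion criteria", which is how such eyes disappear from curated cohorts.

## The synthetic cohort: what it emulates

The generator's defaults are the package's study conditions and are not
meant to be tuned per analysis.

**Spatial model.** PR = per-eye central level + radial rise
$\cdot (r/4\,\mathrm{mm})^2$ + fourfold angular ("rhombus") modulation
$\cdot (r/4)^2 \cos 4\theta$ — low central retardation rising toward the
periphery with the rhombus pattern characteristic of healthy corneas —
plus, in KC, a Gaussian cone bump (default +18° peak, 1.6 mm radius,
centred near (0.9, −0.9) mm with 0.4 mm per-eye jitter). The epithelium is
uniform except, in KC, a doughnut: focal thinning at the cone apex (10 μm)
with a 35% compensatory annular thickening at 1.8 cone radii. Bowman's
layer is uniform with focal Gaussian thinning (6 μm) in KC. Per-pixel
Gaussian noise (1–1.5° PR, 0.4–1 μm thickness) is added before the 1 mm
smoothing. Central levels, peripheral rise and rhombus amplitude are
per-eye draws — between-eye variability is what keeps any single feature
from being a perfect class discriminant.

**Class levels.** Healthy: central PR 25 ± 3°, ELT 52.3 ± 3.0 μm, BLT
16.0 ± 0.8 μm (the healthy Bowman's layer is 15–17 μm). KC: central PR
38 ± 4° plus the cone, ELT 51 ± 4, BLT 14.5 ± 1.5. The SKC class is a
**two-component mixture**: a "true subclinical" component (central PR
31 ± 3.5°, BLT 15.7 ± 1.7 μm, mildly elevated indices) and a near-healthy
component blended 45% of the way from the healthy parameter set toward the
subclinical one (expected central PR ≈ 27.8°). Fellow eyes of asymmetric
KC patients draw the near-healthy component with probability 0.65,
bilateral suspects with 0.30. This heterogeneity — clinically suspect eyes
whose own imaging is essentially normal — is the mechanism that makes SKC
the hardest class for every device model and produces the asymmetric
SKC→healthy reclassification the pipeline is designed to study; a single
Gaussian SKC class cannot produce it.

**Index records.** Every tomography field is drawn from its
class-conditional mean ± SD (Gaussian, truncated by rejection to stated
physical bounds), with the three labeling indices re-drawn jointly (bounded
at 1000 attempts, then an error signalling inconsistent parameters) until
the eye satisfies its group's box — so `audit_cohort_labels()` is zero by
construction, and a run that violates it indicates a real defect. KC KISA%
is drawn lognormally (arithmetic mean 912, SD 1290 is heavily right-skewed;
a Gaussian would put ~24% of mass below zero). Whether the real
distributions are truncated Gaussians is unknown; this is a modeling
choice, not an empirical claim. Keratometry-derived fields (K mean,
astigmatism) are computed from K1/K2; all other fields are drawn
independently — cross-index correlation is *not* modeled (see
limitations).

**Seeding.** Every stochastic unit (eye, fold, mixture assignment) gets its
own seed via `derive_seed(base_seed, key)`, a two-round
multiply–add–modulo hash into [1, 2³¹−2]. Cohorts are byte-identical under
a fixed seed, any eye can be regenerated in isolation, and fold seeds tie
to eye identifiers rather than row positions.

**What it does not emulate.** No speckle or light-propagation physics, no
Placido/Scheimpflug raytracing, no segmentation errors, no cross-index
correlation structure, no age/sex covariates, no intra-subject (two-eye)
correlation — each simulated eye is an independent subject. Passing tests
therefore demonstrate the pipeline's correctness and the qualitative
class-difficulty structure, not clinical performance on real populations.

## Classifier protocol

One random forest per device: 100 trees, Gini impurity, trees grown to
purity (leaf size 1) — the `randomForest` package's native behaviour; the
minimum-split-of-2 and unbounded-depth settings recorded in `rf_config()`
are implied by those defaults and kept explicit for protocol fidelity.
`mtry` stays at the package default (√p for classification). Evaluation is
leave-one-out: each eye is predicted by a forest trained on all others,
seeded from (base seed, eye id); training rows are sorted by eye id within
each fold so predictions are invariant to row order (bootstrap sampling is
order-sensitive). The predicted label is the probability argmax; exact ties
resolve to the earliest class in the fixed order healthy, skc, kc.
Metrics: per-class one-vs-rest AUC from the held-out probabilities,
precision/recall/F1 from the confusion matrix (a never-predicted class gets
precision 0 with a warning — the usual degenerate convention), macro
averages as arithmetic means, accuracy as the trace fraction. Model pairs
are compared per class with the paired DeLong test on the one-vs-rest AUC
difference; identical score placements (zero variance) return statistic 0,
p = 1.

## Agreement analyses

The Venn partition classifies each eye as all-three-agree, exactly-one-pair
(attributed to that pair), or all-distinct — an exact partition of the
cohort. Reclassification tables restrict to one true group (optionally one
SKC subtype) and tabulate predicted labels. Proportions are compared by
Pearson chi-square on the 2 × 2 table without continuity correction
(Yates available behind `correct = TRUE`, default off). Subgroup contrasts
use Welch's unequal-variance t-test — the safer reading of "independent
sample t-tests" — with degenerate subgroups (n < 2 or zero variance in
both arms) flagged and left untested. For paired designs (the same 109 SKC
eyes under two models) the chi-square is a conservative interpretation;
`compare_model_rocs()` provides the paired alternative on the probability
scale.

## Numerical and testing choices

Problem sizes in the test suite are chosen for desk-scale determinism: the
label-consistency and ordering checks run on the full 359-eye default
cohort; the separability check uses 90 eyes with within-class SDs shrunk to
~2% and map levels pushed far apart; the permutation-null check uses 20
fixed-seed label permutations of that cohort (note that leave-one-out under
permuted labels is slightly pessimistic — removing an eye depletes its own
label's count in training — so the chance-level check uses the pooled
binomial standard error); the class-separation trend uses plain Gaussian
feature tables (10 separation levels × 10 seeds) rather than the cohort
generator, which cannot reach zero separation while keeping its labeling
boxes satisfiable. Zernike recovery is verified to 10⁻⁶ relative error on
100 random order-6 fields; signal round-trips to 10⁻⁹ degrees.

## Known limitations

* Feature independence within class inflates multi-feature separability
  relative to correlated real data; the mixture structure, not marginal
  overlap alone, carries the SKC difficulty.
* The forest implementation reproduces the protocol, not any specific
  historical run: per-eye predictions depend on RNG streams that no fixed
  convention can make portable across implementations.
* Zernike coefficients are convention-dependent; exported tables state the
  OSA/orthonormal convention and the 8 mm pupil.
* The generator's maps are smooth parametric fields; they exercise the
  fitting and classification machinery but not segmentation robustness.
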