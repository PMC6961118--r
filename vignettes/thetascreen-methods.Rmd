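---
title: "Scoring phenotypic divergence across a cell-line panel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring phenotypic divergence across a cell-line panel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetascreen)
```

## The problem

High-content morphological profiling (Cell Painting and its relatives)
measures hundreds of per-cell features — sizes, shapes, intensities and
textures of nucleus, cytoskeleton, ER, Golgi and mitochondria — for every
well of a compound screen. When the same library is screened across a panel
of cell lines with different genetic backgrounds, the interesting compounds
are often not the strongest ones but the *divergent* ones: compounds that
push two cell lines toward visibly different phenotypes. thetascreen
implements a complete, testable pipeline from per-cell feature tables and
plate maps to a ranked list of divergent compound/cell-line pairs.

Two obstacles make this comparison non-trivial. First, cell lines differ
morphologically before any treatment, so raw profiles mostly encode cell
identity, not compound action. Second, hundreds of CellProfiler features are
heavily redundant and plate-to-plate technical variation is multiplicative.
The pipeline addresses both with control-based, plate-wise standardization
and feature selection before any cross-line comparison is attempted.

## The pipeline stage by stage

**Ingest and QC.** Per-cell tables are read from CSV (CellProfiler-style or
generic column naming), objects from saturated or out-of-focus images are
dropped, and single-cell rows are aggregated to per-image medians and then
per-well medians (`n_objects`/`n_images` retained for audit). The median is
used throughout because per-image cell counts are unequal and single-cell
feature distributions are heavy-tailed. The saturation cutoff defaults to a
fraction of 0.2. The focus cutoff is self-calibrating: half the per-plate
1st percentile of the negative-control images' focus scores. The halving
matters — with only 8–16 control images per plate the raw 1st percentile
*is* the sample minimum, and a cutoff at the minimum spuriously rejects
roughly one healthy image in every n+1; the factor of one half keeps the
rule scale-free while leaving a guard band below the in-focus distribution.

**Feature selection.** Features with pooled variance below `1e-5` are
removed, then pairs with `|Pearson r| > 0.9` are greedily pruned: the most
correlated offending pair is located, and the member with the larger mean
`|r|` against all remaining features is dropped (ties broken
alphabetically, keeping the earlier name). This tie-break makes the
procedure deterministic and idempotent, and it keeps the less redundant
member of each pair. Selection is global — one feature basis for the whole
screen — because cross-line comparison requires every cell line to live in
the same feature space. When a plate map is supplied, the variance screen is
applied per cell line and a feature must pass in every line.

**Plate-wise DMSO normalization.** Per plate and feature, values are divided
by the DMSO median and then z-scored with the DMSO mean and SD:

$$x' = x / \mathrm{median}(x_{\mathrm{DMSO}}), \qquad
  z = \frac{x' - \mathrm{mean}(x'_{\mathrm{DMSO}})}{\mathrm{sd}(x'_{\mathrm{DMSO}})}.$$

Because every statistic is computed within the plate, a multiplicative
per-plate, per-feature technical effect cancels exactly (the division step
removes it; the z-step is invariant to it), and because the null is defined
by each plate's own vehicle wells, basal morphological differences between
cell lines are removed along with the plate effects. Two numerical guards
apply: a feature whose DMSO median is within `1e-9 * (pooled SD + 1)` of
zero is shifted rather than divided (CellProfiler features can legitimately
center on zero), and a feature with zero DMSO variation on any plate is
dropped for the run with a warning. Missing values are imputed with the
plate DMSO median before normalization so the denominators stay defined.
`center = "median"` is available as a robust variant (DMSO median exactly 0;
the scale is still the DMSO SD, so the control SD is exactly 1 either way);
the default is the classical mean-centred z-score.

**Phenotype space.** PCA is computed on the normalized matrix with no
further centering or scaling — the data are already standardized against the
DMSO null, and re-centering would reintroduce a dependence on the treatment
composition of the screen. The retained dimension *k* is the smallest number
of components whose cumulative variance fraction reaches `variance_prop`,
floored at two because the angular scoring downstream lives in the PC1–PC2
plane. All wells are projected and the per-component *median* of the
negative-control wells is subtracted, so the control centroid sits exactly
at the origin. Loadings carry a deterministic sign convention (the
largest-magnitude element of each loading vector is positive) so identical
inputs give byte-identical outputs across runs and BLAS builds.

`variance_prop` deserves its own paragraph because the activity rule is
sensitive to it. A compound's activity is judged by its l1 distance to the
origin against a cutoff of `k_sd = 2` standard deviations of all compound
distances in that cell line. The l1 norm of a k-dimensional noise vector
concentrates around a positive mean that grows like *k* while its SD grows
like √k; if `variance_prop` is set high enough to drag in the isotropic
noise floor (k in the hundreds), every null compound sits far from the
origin with small relative spread and the 2-SD rule calls *everything*
active. The default `variance_prop = 0.5` was calibrated once on the
package's simulator, where ground truth is known: at paper scale (8 lines ×
1280 compounds × 340 features) it retains k ≈ 10 components and recovers
planted actives with sensitivity ≈ 0.98 at a minority active-call rate,
which is the regime reported for real screens of this design. Raising
`variance_prop` is safe for the angular scores (they only use PC1–PC2) but
degrades activity calling; the parameter is exposed in `pipeline_config()`.

**Assay quality.** The multivariate Z′ factor projects every control well
onto the axis joining the negative- and positive-control component-wise
medians and applies the classical formula
$Z' = 1 - 3(\sigma_{pos} + \sigma_{neg}) / |\mu_{pos} - \mu_{neg}|$
to the projections, per cell line and pooled over the concatenated
(per-plate-normalized, hence comparable) controls. A median-axis projection
was chosen over a covariance-based discriminant because with hundreds of
features and tens of control wells per class the covariance is badly
ill-posed; the projection needs no inversion.

**TCCS divergence scoring.** For each compound × cell line × replicate the
compound-level coordinates (median over its wells) are reduced to the plane
angle θ = atan2(PC2, PC1) in degrees ∈ [0, 360) and a magnitude. θ is only
meaningful for a compound that actually moved the phenotype, so θ is flagged
undefined when the compound is called inactive in that line — the activity
rule doubles as the direction-validity rule. For every unordered cell-line
pair, Δθ = min(|θ_a − θ_b|, 360 − |θ_a − θ_b|) ∈ [0, 180]. Δθ is symmetric,
satisfies the circular triangle inequality, and is invariant under any
global rotation or reflection of the PC1–PC2 plane — so the arbitrary
orientation of the fitted components cannot affect the ranking. (The l1
activity distance, by contrast, is deliberately *not* rotation-invariant;
that is a property of the published rule, and the test suite documents it.)
A k-dimensional variant (`delta_theta_kd()`, the arccos of the cosine
similarity of the full coordinate vectors) is reported separately; the 2-D
plane angle is the default method.

**Rank product.** Within each replicate, compound/pair items are ranked by
decreasing Δθ (rank 1 = most divergent, fractional average ranks on ties);
the rank product is the geometric mean of the per-replicate ranks and the
hit list ascends in it, so only pairs that rank highly *consistently* reach
the top. The ordering is invariant to replicate order and to any strictly
monotone rescaling of Δθ within a replicate. Items with an undefined Δθ in
any replicate are excluded and counted. Equal rank products are broken by
larger mean Δθ, then lexicographically — determinism again. Compounds
inactive in *any* screened cell line are removed before the final hit list
(a divergence between a response and a non-response is an activity
difference, not a phenotype difference), and a manual exclusion list is
honoured for mechanism-of-action triage, which is deliberately not
automated.

## The simulator: what it emulates and what it does not

`generate_screen()` produces the full screen the pipeline expects, with
known ground truth: per-cell feature rows = cell-line baseline mean + a
draw from a shared 10-factor covariance (factor SDs 4, 3, 1.5 × 8, plus
unit diagonal noise, scaled per feature by a log-normal raw scale) + the
well's compound effect + per-cell noise, all multiplied by a log-normal
per-plate, per-feature technical effect. Baselines differ between cell
lines by 3 baseline-SDs in a random direction (distinct basal
morphologies); plates carry 16 DMSO and 16 staurosporine-like wells in
columns 1–2 of a 384-well plate (8 + 8 on 96-well).

Compound effects are magnitude × unit direction, with the direction confined
to the plane of the top two baseline principal axes. That choice makes the
ground truth commensurate with the estimator: the planted angle between two
lines' directions is exactly the 2-D angle the TCCS method estimates, so
recovery can be asserted quantitatively (the emitted ground-truth vectors
subtend the planted angle to machine precision, verified against a
dot-product oracle). The staurosporine-like positive control is likewise an
in-plane vector of magnitude 20 baseline-SDs, with a panel-wide base angle
and a small per-line rotation (SD 15°). An early full-space random control
direction was rejected: a dominant out-of-plane control rotates PC1–PC2 away
from the treatment plane and destroys the correspondence between planted and
estimated angles; the near-shared in-plane control also reproduces the
pooled-slightly-below-per-line Z′ pattern seen in real panels (simulated
pooled ≈ 0.70, per-line ≈ 0.67–0.81 at full scale).

Defaults chosen once for the emulated study conditions: 8 cell lines × 1280
compounds at one concentration, 384-well plates, 340 features, 80% of
compounds inactive (screens of approved-drug libraries typically see a
10–30% phenotypically active minority), active magnitudes uniform in 2–6
baseline-SDs, plate effect SD 0.1, one field per well and 15–30 cells per
image. The cell count is deliberately below microscope reality (hundreds of
cells per field) — the analysis unit is the image median, and the count only
sets the median's noise; keeping it small keeps the full panel simulation
desk-scale. One replicate is the default because the primary screen's
replicate structure is not fixed by the design being emulated;
`n_replicates` is exposed.

What the simulator does **not** model: pixel-level image content, organelle-
specific feature semantics (stain names are metadata only), spatial plate
gradients (edge effects), cell-density-dependent phenotypes, compound
toxicity gradients, or per-line differences in compound *potency* (an active
compound is active at the same magnitude in every line unless a divergence
is planted). Passing tests therefore demonstrate that the pipeline's
statistics do what they claim under controlled conditions — not that a real
screen's biology will satisfy their assumptions.

## Numerical choices and degenerate inputs

- Same seed ⇒ bit-identical screens, and identical inputs ⇒ byte-identical
  pipeline outputs (manifests carry md5 content hashes and no timestamps).
- Division guards and zero-variance feature handling as described above;
  fewer than 2 surviving features or components is a hard error, as is a
  plate with fewer than two vehicle wells, a profile row without a plate-map
  entry, or an activity call over fewer than 3 compounds.
- Ties: correlation pruning (larger mean |r|, then alphabetical), ranking
  (fractional average ranks), final ordering (rank product, then mean Δθ,
  then ids). Every tie-break is documented and deterministic.
- θ is reported but flagged undefined at zero magnitude, below an optional
  magnitude floor, or for inactive compound/line combinations; undefined
  records propagate as missing Δθ and are excluded from ranking with a
  count.

## Problem sizes used by the test suite

The packaged tests validate the angular scoring against a 10,000-vector
arccos oracle and 1,000 random plane rotations (both to 1e-9 degrees), rank
products against exhaustive computation on ≤ 6 × 3 tables, Z′ against its
closed form on 100 simulated control sets of 64 wells per class,
normalization exactness to 1e-9 on multi-plate simulated screens,
activity recovery on 1,000 null + 50 planted compounds, and end-to-end
planted-divergence recovery (20 compounds at Δθ = 120°, magnitude 5,
2 lines × 96 compounds × 3 replicates; monotone recovery across planted
angles 0–180°). The full-panel configuration (8 × 1280 × 384-well × 340
features) is run twice in its entirety to assert byte-identical manifests;
it completes in a few minutes on a single core.

## Known limitations

- The 2-SD l1 activity rule is threshold-like, not a significance test; its
  false-positive rate depends on the retained dimension k (see the
  `variance_prop` discussion) and on the fraction of truly active compounds,
  which inflates the distance SD.
- Δθ from a single well per compound per line inherits the full well-level
  noise; replicates enter only through the rank product, not through a
  formal variance model, and no p-value is attached to a rank product.
- The pooled Z′ assumes the per-plate normalization has made control
  dispersions comparable across lines; a line with a qualitatively different
  staurosporine response direction lowers the pooled score even when every
  per-line assay is excellent.
- Feature selection is correlation-based and unsupervised; it can discard a
  feature that is redundant overall but uniquely informative for one rare
  phenotype.
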