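---
title: "Methods: from occurrence records to a protection threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from occurrence records to a protection threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquagap)
```

`aquagap` estimates how well a protected-area network serves a poorly
sampled freshwater insect assemblage. This vignette explains each model in
the chain, the assumptions it rests on, the tunable parameters and their
defaults, what the synthetic data generator does and does not emulate, and
the numerical conventions that make the pipeline reproducible to the byte.

## The analysis lattice

Everything lives on a regular grid in decimal degrees (default resolution
0.083°, roughly 9 km at the equator), anchored at its north-west corner.
Cells are half-open boxes — closed on their northern and western edges — so
every in-grid point belongs to exactly one cell; indices are 0-based and
row-major with row 0 northernmost. The nominal cell area (`cell_area_km2`,
default 85 km² for a 0.083° cell near the equator) is used only to express
range-size thresholds in km²; no equal-area projection is attempted, which
is adequate at the tropical latitudes the defaults emulate and increasingly
approximate toward the poles.

## Occurrence cleaning

Two filters precede any modelling:

* **Coordinate precision.** Records whose great-circle (haversine) distance
  to the nearest municipality seat is below 2 km are discarded: such
  coordinates usually mean "the municipality", not a field locality. The
  metric is haversine because the inputs are geographic coordinates; which
  municipality applies is resolved as *nearest seat*, the conservative
  reading when the source municipality is unknown.
* **Modelling floor.** Species with fewer than 3 records are excluded (and
  listed). Downstream, a model additionally needs 3 *distinct occupied
  cells*; records collapsing into fewer cells exclude the species at the
  modelling stage, with a report.

Records are taken as-is in decimal degrees; datum shifts are out of scope.

## Environmental compression

Bioclimatic stacks are notoriously collinear, and the models here use few
occurrences, so the stack is compressed before fitting. Layers are
standardized to mean 0, SD 1 over valid cells (constant layers are dropped
with a warning) and decomposed by PCA — on the correlation matrix, since the
layers' units are incommensurable. The retained axis count is the smallest
k whose cumulative explained variance reaches `target_cumvar` (default
0.95). Axis signs are arbitrary in PCA; for reproducibility each axis is
oriented so its largest-magnitude loading is positive. The PCA is fitted
over all valid grid cells rather than only occupied cells: the axes are
meant to describe the landscape, not the sample, and the choice is stable
under resampling of occurrences.

## Distribution models

Each species is modelled by a ridge-penalized logistic regression of
presence cells against a background sample, on linear and quadratic terms of
the retained axes. This is a deliberately explicit member of the
maximum-entropy family of presence–background models: the feature set and
penalty are visible and testable rather than buried in a binary. Settings:

* `background_n` — 10,000 cells or all cells if fewer (the long-standing
  presence–background convention). Background cells may coincide with
  presences; they represent the landscape, not confirmed absences.
* `regularization` — ridge penalty λ = 1 on standardized features, the
  intercept unpenalized. An unpenalized fit that fails to converge
  (complete separation) is refitted at the default penalty and flagged.
* Optimization is Newton/IRLS with step-halving, converged when the
  penalized gradient's max-norm falls below 1e−8.

Evaluation is k-fold cross-validation on presences (default 5 folds,
reduced with a warning for sparser species; the background is reused across
folds): the reported `auc` and `cv_tss` are fold means. AUC uses the
rank-statistic formulation (ties count ½), which equals trapezoidal ROC
integration. The reported `threshold`, `sensitivity`, `specificity` and
`tss` come from the full-data fit, where the identity
tss = sensitivity + specificity − 1 holds exactly for the binarization used
downstream. The max-TSS threshold scans all classification-distinct
candidates — midpoints between consecutive distinct pooled scores plus
±∞ sentinels — and breaks ties toward the *higher* threshold, i.e. the more
range-restricted map. Binarization uses the ≥ rule; missing cells stay
missing.

The max-TSS statistic is a maximum over thresholds and is therefore
positively biased for small presence sets; near-zero TSS under a no-signal
null is an adequate-sample property (the suite's null simulation uses 60
presences), and TSS values for very sparse species should be read with that
bias in mind.

## Diversity

Binarized maps stack into a cells × species 0/1 community matrix (cells
with any missing prediction are excluded and reported). Richness is the row
sum. Compositional structure uses the pairwise Sørensen partition: with a
shared species and b, c unique to either cell,

$$\beta_{sor} = \frac{b+c}{2a+b+c}, \qquad
  \beta_{sim} = \frac{\min(b,c)}{a+\min(b,c)}, \qquad
  \beta_{sne} = \beta_{sor}-\beta_{sim},$$

so total dissimilarity splits into species replacement (turnover) and
richness-difference (nestedness) parts. The pairwise (not multi-site) form
is used because a principal coordinates analysis needs a pairwise matrix.
Declared conventions for empty cells: empty-vs-empty pairs are identical
(0, 0, 0); empty-vs-non-empty is complete dissimilarity attributed to
turnover (1, 1, 0). Each component matrix is spatialized by classical PCoA:
Gower double-centering of −½D∘D, leading eigenpair, scores scaled by the
square root of the leading eigenvalue. PCoA signs are arbitrary, so scores
are oriented to correlate non-negatively with per-cell mean dissimilarity;
negative scores are legitimate axis values and are never shifted. A
non-positive leading eigenvalue returns zero scores with a warning. Dense
pairwise matrices need n² memory, so landscapes beyond `max_cells`
(default 4000) raise an instructive error rather than silently
approximating.

## Monte Carlo null models

Three randomization procedures, all seeded and reproducible:

* **AUC vs occurrence count.** Species are binned into occurrence classes
  ([4,15], then width-15 classes). The sparsest class is the control; its
  observed mean AUC is the critical value. For each other class of k
  species, k species are drawn from the pool `n_rand` times and the p-value
  is the fraction of random means ≥ the *control* mean, with the plain
  `n_rand` divisor this test traditionally uses. Note the design's
  direction: it flags AUC *inflation in the sparse control class* (the
  classic small-sample artifact). A variant comparing each class with its
  own mean is available (`reference = "own_class"`). The control-reference
  p is only near-calibrated when the control class dominates the assemblage
  (as it typically does), since its observed mean is then stable.
* **Biome test.** Per biome, the observed mean of a per-cell metric over
  its N cells is compared with means of N-cell draws from *all* cells,
  without replacement.
* **Protection test.** Cells with protected coverage ≥ 0.5 are "protected";
  their observed mean importance is compared with equal-sized draws from
  the *unprotected* cells, for the whole region and per biome.

Cell-based tests use the add-one convention p = (#{random ≥ observed}) /
(n_rand + 1); when no random value reaches the observed one the label
reports the resolution bound `< 1/(n_rand+1)`. A lower-tail companion is
always returned so negative deviations can be reported. Draws are without
replacement within a draw; the comparison rule is ≥ everywhere. All of
these conventions are recorded in the pipeline manifest.

**Known limitation.** Because the protection test's null draws come only
from the unprotected complement, the complement's mean is negatively coupled
to the observed protected mean: the observed-vs-null deviation is
effectively scaled by N/(N − n_protected). The test is therefore mildly
anti-conservative as protected coverage grows, approaching its nominal size
only when coverage is small relative to the landscape. The suite's
calibration accordingly runs at 3% coverage; at realistic coverages
(~13%) upper-tail p-values are slightly liberal, which matters little for
the procedure's typical conclusion (p near 1, reserves no better than
random) but should be remembered when a marginal significance appears.

## Greedy prioritization

The additive benefit of a landscape state is
$V=\sum_j w_j (n_j/N_j)^z$ over species j with $n_j$ of $N_j$ range cells
remaining. The exponent z = 0.25 (the established default of
additive-benefit reserve software; the analysis is robust to moderate
changes and the value is surfaced in configuration and manifest) makes the
curve concave: the last cells of a range are worth far more than the first,
so a cell holding a species' final occurrence carries that species' entire
remaining term. Greedy removal deletes, at each step, the cell with the
smallest marginal benefit loss, recomputing losses after every removal
(batches > 1 are supported for speed, with the caveat that near-ties can
reorder). Ties break deterministically — lower current richness first, then
lower cell id — so the ranking is a pure function of the community matrix
and needs no seed. Importance is the normalized removal rank: first removed
→ 1/n, last survivor → 1. Species weights and cell costs default to 1.

## The gap regression

Each modelled species contributes one observation: range size in cells
(community-matrix column sum) and protected status (1 if any occupied cell
is protected). A logistic regression of status on range size is fitted by
maximum likelihood (`glm`); the reported χ² is the likelihood-ratio
statistic against the intercept-only model (1 df). Complete separation is
detected (non-convergence or an unbounded linear predictor) and handled by
a ridge-penalized refit, flagged in the result — at desk-scale species
counts this is common and the flag should temper interpretation. The
protection threshold is the smallest integer cell count whose fitted
probability reaches 0.5 (configurable); it is undefined, and flagged, when
the slope is not positive or the crossing lies beyond the observed range
span. Cells are the native unit; km² is derived reporting via
`cell_area_km2`, deliberately kept separate because published cell/area
pairs do not always reconcile with the stated grid resolution.

## The synthetic study system

The generator replaces the field inputs with a landscape whose ground truth
is stored, so recovery can be measured:

* **Layers.** `n_layers` (default 19, bioclim-like) rasters are linear
  mixtures of `ceiling(n_layers/3)` latent Gaussian random fields (white
  noise smoothed at `autocorr_scale` = 5 cells) plus 5% independent noise,
  then given arbitrary gains and offsets. This reproduces the one property
  that matters here — strong collinearity with a low-dimensional latent
  structure — via simple Gaussian smoothing rather than explicit variogram
  models.
* **Species.** Each species has a logistic suitability surface over the
  latent fields; its threshold is set so the true range has exactly its
  assigned size. Default range quantiles span ~0.1% to 20% of the
  landscape (a couple of cells to hundreds), mirroring assemblages that mix
  narrow endemics with widespread species; the pipeline default spreads
  occurrence counts (6–74) across the AUC-test classes. Records are sampled
  uniformly within the true range and jittered within the cell;
  `snap_fraction` (default 0.1) of records are snapped exactly onto the
  nearest municipality seat so the precision filter has real work to do,
  and clean records are rejection-sampled away from seats so the snapped
  count is exact. Seats are a fixed Poisson point set (one per ~100 cells).
* **Masks.** Biomes are nearest-seed (Voronoi-like) contiguous partitions —
  all the null models need is contiguous label regions. Protected coverage
  (default 0.13 of cells, a realistic national figure) is placed at random
  or on the top-importance cells; a band of cells receives fractional
  coverage on both sides of the 50% rule.

Everything is a pure function of the seed. What the generator does *not*
emulate: real climate physics, irregular study-region boundaries and
coastlines (every grid cell is valid land), spatial sampling bias beyond
seat-snapping, taxonomic error, and spatially autocorrelated *residuals* in
species' responses. Passing tests therefore demonstrate that the machinery
recovers known structure under clean conditions; they do not certify
performance under the biases of real occurrence databases.

## Numerical conventions and problem sizes

Degenerate inputs have declared behaviours rather than accidents: constant
layers are dropped; a species whose statuses are all identical refuses the
gap regression (the pipeline records the undefined fit and continues);
biomes with no cells are skipped with a warning; scopes with no protected
cells return flagged, undefined results. The test suite runs its
simulations at deliberately modest sizes — 16–40-cell-wide grids, 999
randomizations for calibration, 100–500 replicates for recovery and size
checks — chosen so the full suite exercises every stage, including two
complete pipeline runs compared byte-for-byte, in a few minutes on one CPU.
`scripts/acceptance.R` reruns the default 40 × 40, 25-species system from a
single seed and writes every headline quantity it computes as JSON.
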