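---
title: "Modelling a truncated niche: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a truncated niche: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nichecast)
```

## The problem

Species distribution models (SDMs) relate occurrence records to
environmental predictors and project habitat suitability across a
landscape, and under future climate. The projection is only as good as
the occurrence data's coverage of the species' *fundamental* niche —
the full set of conditions under which it can persist. When a species
has been removed from part of its range by human land use (logging,
pasture, cultivation), its occurrences sample only the *realized*
niche, and a model trained on them will call the cleared conditions
unsuitable. Projected onto a warming climate, such a model can predict
a catastrophic range collapse that is an artefact of the training data,
not of the species' physiology.

`nichecast` implements a hierarchical ensemble workflow built around
that problem, for the canonical case of a mountain conifer cleared
from the lowlands and a bird that feeds almost exclusively in its
mature stands. The tree is modelled first; its suitability map is
binarized under three alternative thresholds that span the
realized-to-fundamental continuum; the bird is then modelled with the
binary tree layers as habitat predictors and projected under each
variant. Because the original field data are not distributable, the
package pairs the pipeline with a virtual-species simulator in which
the fundamental and realized ranges are known exactly, so every claim
about threshold behaviour is testable.

## The synthetic world

`generate_island()` builds a mountainous island on a regular grid:
a radial dome perturbed by spatially correlated noise, sea cells as
nodata. Defaults are chosen to caricature a western-Mediterranean
island: 128 x 128 cells of 1 km², ~9000 land km², a 2700 m summit, a
coastal monthly climatology with hot dry summers, a lapse rate of
6.5 °C/km, and precipitation increasing by 90% per km of elevation.
Monthly temperature and precipitation carry correlated noise (sd 0.3 °C
and 5 mm) so that predictors are not exact functions of elevation.

`define_virtual_species()` gives a species a fundamental suitability
surface: independent Gaussian responses per bioclimatic variable,
multiplied and max-normalized to [0, 1]. This is the simplest response
family with a controllable optimum and breadth; nothing in the
workflow depends on its particular shape. Suitability at or above an
*occupancy cutoff* (default 0.5) defines the fundamental range; the
cutoff is explicit so that recovery tests have an unambiguous truth.
Anthropogenic clearing is then simulated: every fundamental cell below
a truncation elevation (default 1000 m) is removed from the realized
range independently with probability 0.95. Bernoulli removal is
deliberately the default — spatially clustered clearing would be more
realistic but makes the truth harder to reason about in tests. A small
number of relict *coppice* cells (default 20) is sampled uniformly
from the cleared zone: lowland survivors that witness the fundamental
niche without entering any model fit. The default tree niche (annual
mean temperature optimum 11 °C, sd 5 °C, with a broad annual
precipitation response) puts the fundamental range from the coast to
roughly 1500 m, so the realized range after clearing is the 1000–1500 m
mountain belt — a species that looks montane but is not.

The bird's truth is its own Gaussian climate response multiplied by
the indicator of host-tree fundamental presence; its realized range is
intersected with the trees' realized ranges, so it inherits the
truncation. Occurrences are cell-center points sampled without
replacement from realized cells (optionally thinned by a detection
probability).

Future climate arrives as coarse anomaly grids — one lattice roughly
an order of magnitude coarser than the landscape per scenario, 12
monthly temperature and precipitation anomaly grids each, spatially
smooth around the scenario's stated mean. The three default scenarios
(labelled A1, A2, B1) warm the island by +3.5, +4.0 and +2.5 °C with
monthly drying of 15, 20 and 8 mm — magnitudes typical of
end-of-century Mediterranean projections. The anomalies are downscaled
by bilinear interpolation anchored at coarse cell centers (edge values
held outside the center hull, so borders are defined) and added to the
baseline monthly grids.

What the simulator does *not* emulate matters for interpreting green
tests: real topography and coastline shape, spatially autocorrelated
sampling bias, dispersal limitation, fire, vegetation dynamics, and
land-use change are all absent. A pipeline that recovers the
fundamental range here is shown to be *internally* coherent — it says
nothing about whether a particular real data set satisfies the
assumptions (notably, that relict stands exist and are attributable to
clearing rather than to microhabitat).

## Climate predictors

Ten variables are derived from the 12 monthly grids: annual mean
temperature (tm), warmest- and coldest-month temperature (twm, tcm),
temperature seasonality (tsd), annual precipitation (pm), wettest- and
driest-month precipitation (pwm, pdm), precipitation seasonality
(psd), growing degree days (gdd) and a moisture index (mi). Two
conventions are fixed once and used everywhere: **tsd** is the plain
standard deviation of the 12 monthly means in °C (not the x100
convention of some gridded bioclim products), and **psd** is the
coefficient of variation of monthly precipitation, defined as 0 where
annual precipitation is 0. **gdd** uses the monthly approximation
`sum_m max(0, t_m - 5 °C) * days_m` — base 5 °C is the standard
threshold for temperate tree growth, and calendar month lengths are the
default. **mi** is annual precipitation over annual Thornthwaite
potential evapotranspiration, capped at 10; cells whose every month is
at or below freezing have PET 0 and are assigned the cap. The
Thornthwaite form (standard 30-day/12-hour variant, no daylength
correction) was chosen because it needs only the monthly temperatures
already in hand; any index monotone in the same quantities would drive
the synthetic species identically.

## The modelling engine

Five suitability learners are supported, all emitting a continuous
suitability in [0, 1] (class-probability outputs for the classifiers):

* **CTA** — classification tree (`rpart`), grown deep and pruned at the
  cost-complexity value minimizing the internal cross-validated error
  (50 folds by default, capped at n−1).
* **ANN** — single-hidden-layer feed-forward network (`nnet`), inputs
  standardized, 8 hidden units, weight decay 0.01; the reported
  prediction is the mean of 3 independently initialized fits, which
  tames initialization variance. A fixed size was preferred over
  size selection by cross-validation: with standardized inputs and
  decay regularization the suitability *ranking* is insensitive to the
  exact width, and the fixed size keeps the fit deterministic and
  cheap. The size is a config entry for users who disagree.
* **MDA** — mixture discriminant analysis (`mclust::MclustDA`), up to 3
  Gaussian components per class (fewer when a class is small).
* **GBM** — gradient-boosted regression trees (`xgboost`), 2000 rounds
  of depth-3 trees at shrinkage 0.01, single-threaded for exact
  reproducibility.
* **RF** — random forest (`randomForest`), 500 trees.

If no predictor column varies, every technique degenerates to
predicting the training prevalence — the honest "no information"
answer.

Pseudo-absences are sampled uniformly without replacement from valid
cells not hosting a presence (5 sets of 5000 by default). Excluding
presence cells is a convention choice: it avoids contradictory labels
at a cell, at the cost of a minuscule negative bias in apparent
prevalence. Cases are equally weighted; prevalence reweighting is
deliberately not applied (the threshold stage handles asymmetries
explicitly).

Evaluation is by class-stratified 70/30 split-sampling repeated 5
times: holdout AUC, and holdout TSS at the holdout's own
TSS-maximizing threshold. TSS is sensitivity + specificity − 1.
Stratification guarantees both classes in every holdout, which AUC
requires; a degenerate split is re-drawn a bounded number of times
before erroring. The final model for prediction is always refit on
100% of the rows. Per-variable importance is 1 minus the Pearson
correlation between standard predictions and predictions with that
column permuted (mean of 3 permutations, clamped to [0, 1]; degenerate
constant predictions score 0).

## Consensus

Within each pseudo-absence run the techniques are ranked by mean
holdout AUC (ties: mean TSS, then a fixed technique order) and combined
as a weighted mean with geometric decay weights: the model ranked `r`
of `n` gets weight proportional to `decay^(n - r)`, normalized. At the
canonical decay of 1.6 and n = 5 the weights are 0.41, 0.26, 0.16,
0.10, 0.06. Ranking AUC (not TSS) is the default criterion because the
comparison happens within one species, one region and one
pseudo-absence design, where AUC's incomparability caveats do not
bite. Consensus is computed per run first and then averaged across
runs, and future maps are averaged across scenarios before any metric
is computed; the order only matters for nodata handling (a cell nodata
in any member is nodata in the consensus).

## Thresholds: realized vs fundamental

Three binarization rules, all using the `>=` boundary convention so a
threshold's own defining point stays inside its binary range:

* **maxTSS** — the threshold maximizing TSS over the finite candidate
  set of observed scores plus midpoints between consecutive scores
  (exact maximization; ties resolved to the smallest candidate). It is
  resolved on the 100%-data consensus predictions at the presence and
  pseudo-absence cells, and recorded in the threshold's provenance.
  This is the "accurate" threshold — and precisely thereby tracks the
  realized range.
* **LPT** — the lowest consensus suitability at any presence point.
  Binary maps at the LPT retain every presence by construction.
* **coppice LPT** — the lowest consensus suitability at any relict
  coppice point. Coppices sit in the cleared lowlands where the model
  (trained without them) assigns low suitability, so this threshold is
  typically far below the LPT and the resulting binary range
  approaches the fundamental one. Coppice points never enter model
  fitting.

## The two-stage pipeline

Stage one models each tree on the ten climate variables and emits
consensus maps and the three binary variants for current and future
climate. Stage two fits the bird on the eight basic climate variables
plus one binary layer per tree — binarized at maxTSS, the variant
closest to the observed tree distribution, because fitting against a
hypothetical fundamental range would mislabel cells where the bird was
actually absent for lack of host trees. Projection then substitutes
the tree layers binarized under each variant in turn (species without
coppice records contribute their plain LPT layer to the coppice
variant). The bird's own threshold is its LPT, resolved once on each
variant's *current* consensus map and applied unchanged to the future
map — one numeric cutoff per variant; a bird maxTSS is also resolved
for the conventional all-TSS analysis. Range metrics (area, mean
suitability over the range, presence-point retention, presence-point
mean suitability) use the same cutoff for filtering and for averaging,
per variant; presence-point suitabilities are read from the raw
consensus maps before any zeroing, so they remain meaningful even when
they fall below the variant's cutoff. Scenario averaging precedes
metric computation. Pixel area is a constant per landscape (km² per
cell) with no latitude correction — adequate for a synthetic island a
few degrees across.

## Numerical and degenerate-input conventions

* Grids are row-1-north, half-open pixel indexing, cell-center point
  coordinates; every cross-grid operation checks shape and
  geotransform and rejects mismatches.
* Sea/nodata cells are excluded from sampling and statistics and
  propagate through every derivation.
* All randomness flows from one master seed through a deterministic
  child-seed derivation, so every stage — and the whole study — is
  bit-reproducible; learners with internal randomness are seeded or
  single-threaded accordingly.
* An empty binary range reports area 0 and an undefined (NA) mean
  suitability rather than 0, which would fake a measurement.
* `percent_change` requires a positive baseline and rounds to integer
  percent for reporting.

## Problem sizes used in the shipped checks

The package's own verification suite runs the full two-stage pipeline
on five replicate 128 x 128 worlds with the default world parameters
(truncation 1000 m, clearing 0.95, 20 coppices, 300 tree presences),
1000 pseudo-absences in 2 sets, 2 split repetitions and the two
cheapest strong learners (RF, CTA) — sizes at which the recovery
contrast is already unambiguous, while a laptop reproduces the suite in
minutes. The headline checks are: the coppice-LPT binary recovers the
known fundamental range with far higher recall than the maxTSS binary
(which conversely scores the higher TSS against the realized truth),
and the bird's future/current range ratio is non-decreasing as the
tree threshold moves from maxTSS through LPT to the coppice LPT — in
at least 4 of the 5 worlds for each claim, leaving room for an
occasional adversarial draw.

## Known limitations

* The Gaussian-product niche cannot express interactions or skewed
  responses; recovery results should be read as a best case.
* The coppice LPT inherits the minimum's fragility: a single
  mis-georeferenced relict point can swing the threshold. Real
  applications should audit the defining point.
* MDA silently reduces its mixture component count when a class is too
  small to support three components.
* The pipeline treats tree layers as binary; propagating continuous
  tree suitability would carry the realized-niche bias analysed here
  into the bird model (the reason the binary-threshold design exists),
  but intermediate designs are not explored.
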