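---
title: "Methods: habitat-stability refugia, spatial phylogenetics, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat-stability refugia, spatial phylogenetics, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `paleorefugia`, the decisions
taken where the methodology is genuinely open, and what the synthetic
world does and does not emulate. It states no empirical result beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The analysis grid

All layers share one grid of square cells (the 4.5 km sampling unit of
the study design). Cell (1, 1) is the upper-left cell and centers sit at
`origin + (index − 0.5)·cell_size`; every operation asserts bitwise
grid equality before combining layers, and a deliberately misaligned
fixture in the test suite confirms the rejection path. Distance-based
operations (buffers, distance-to-refugium) require a projected metric
CRS and refuse geographic degrees, because "4.5 km cells" and "100 km
buffers" are meaningless in degrees. Rasters are exchanged as plain-text
ESRI ASCII grids; values are written at full precision (`%.17g`) so
write → read round-trips are lossless.

## Niche models

The suitability model is a ridge-penalized logistic regression of
presences against a uniform random background (default 10,000 points,
drawn with replacement from non-nodata cells) on z-standardized linear
and quadratic terms of each climate variable. This is a transparent
maximum-entropy-style surrogate: with quadratic features it can express
exactly the Gaussian-optimum responses that the synthetic species
possess, so the model family is correctly specified for the generator's
truth. The ridge penalty (default `reg = 1`, expressed for the summed
log-likelihood; glmnet's per-observation lambda is `reg/n`) stabilizes
coefficients without materially biasing the optimum.

Screening follows the standard workflow: species with ≤ 10 unique
records are not modeled (`rejected_records`); models with AUC ≤ 0.70
are excluded (`rejected_auc`). AUC is the Mann–Whitney probability that
a presence outscores a background point (ties count one half), computed
single-pass on the full presence/background sets — replicate averaging
is a calibration detail we deliberately leave out, and the tests verify
the rank-based value against explicit pair enumeration.

The binarization threshold is the *95% minimum occurrence* rule: the
nearest-rank 5th percentile of suitability at the occurrence points
(sort ascending, take rank `⌈0.05·n⌉`), so at least 95% of known
occurrences are classified suitable; ties at the threshold count as
suitable. Nearest-rank is chosen over interpolated percentiles because
it is deterministic, convention-free and slightly conservative. The
threshold is computed once from the contemporary fit and **frozen** for
every hindcast slice: occurrences exist only in the present, so a
per-slice percentile would have nothing to be computed from; freezing is
the only coherent reading. Likewise the feature standardization
constants are frozen at fit time, so hindcasts are comparable through
time. Projections are restricted to a buffer (default 100 km,
center-to-center) around the species' range map before thresholding.

## Forest stability and refugia

For `S` indicator species and `T` paleo slices, the persistence table
counts, per cell and species, the slices in which the thresholded
hindcast is suitable. Summing over species gives the stability surface;
`counts/(S·T)` is the normalized 0–1 estimate. A cell is refugial for
species fraction `p` and temporal cutoff `τ` when at least `⌈p·S⌉`
species each persist ≥ `τ` slices there. Two readings of the refugium
phrase are possible; we use *per-species-then-count* (each qualifying
species must itself persist ≥ τ slices) rather than counting slices in
which `p·S` species co-occur, matching the per-species phrasing of the
underlying workflow. `⌈·⌉` is used for fractional species counts
(p = 0.75, S = 10 → 8 species). The reference cutoff τ = 230 of 257
slices is applied to all four fractions (the source text states it
explicitly only for the strictest class; applying it uniformly keeps the
classes nested by construction, which the tests verify exhaustively on
random tables), and is rescaled proportionally (`round(230/257·T)`) for
shorter axes.

Climate stability uses consecutive-pair deviations: for slices `t_i`,
`t_{i+1}`, the pair deviation is the population SD of the two values,
`|a − b|/2`, divided by the elapsed time; the per-cell deviation is the
mean over the `T − 1` pairs, and stability is its inverse divided by the
finite maximum. Constant series would give infinite inverse deviation;
they are assigned stability 1 (the maximum) rather than propagating
infinities, and the tests pin this. Present-day layers never enter the
stability calculations, keeping past and contemporary predictors
structurally independent.

Distance to a refugium is the Euclidean distance between cell centers,
computed by an exact two-pass distance transform and verified against an
all-pairs brute-force scan; at 4.5 km resolution the center-to-center
value is an adequate stand-in for polygon-edge distance, which we treat
as out of scope.

## Diversity metrics

PD uses Faith's root-inclusive spanning definition: every branch on the
path from an occurring tip to the root counts, so the full assemblage
returns the tree's total branch length. The RPD comparison tree keeps
the topology and sets every branch to `total length/branch count`,
preserving total length so that a full assemblage has RPD exactly 1
(a unit-branch comparison tree would only shift a global constant but
breaks that anchor). PE weights each branch by the inverse of its range
in cells, counted over a configurable *endemism extent* that may exceed
the reporting extent (range sizes must reflect whole distributions even
when maps are clipped); summed over the endemism extent PE equals the
occurring subtree's total length, a conservation law the tests check on
random fixtures alongside exact (1e-12) agreement of all four metrics
with an independent path-enumeration oracle. Metrics are reported raw
and rescaled by their observed maximum (the 0–1 reporting convention
specifies no operation; dividing by the per-run maximum is the simplest
choice and raw layers are always kept). Taxa absent from the tree stay
in SR but are excluded from PD/RPD/PE with a message; unsequenced taxa
can instead be grafted onto their hypothesized sister's stem branch at a
calibrated age, preserving ultrametricity.

## Regressions

Response and predictors are z-standardized before fitting, so estimates
are standardized coefficients and univariate R² equals the squared
Pearson correlation (asserted to 1e-10). The SLX model regresses the
response on each predictor plus its spatially lagged copy `Wx`;
reported effects are the direct coefficients, with fit measured by
adjusted R². The weight matrix is row-standardized queen contiguity on
the analysis grid — the construction is never specified in this
literature's tables, so it is a configurable choice (`rook` and
symmetric `knn` are available) recorded in the output. With all-zero
weights SLX reduces exactly to OLS, which doubles as a correctness
check. Stepwise selection is forward-only AIC (Gaussian likelihood,
intercept never penalized away), deterministic with ties broken by
candidate order. All effects are reported with p-values; significance
filtering is left to presentation. Distance-decay fits regress each
metric on distance from the strictest refugium edge, optionally
restricted to a forest mask; decay significance is assessed on the OLS
slope (the SLX lag absorbs most of a smooth monotone signal, which is
expected behavior, not evidence against decay).

## Conservation

Refugium protection is the cell-count overlap with the protected-area
mask (raster overlap is exact on the shared grid, consistent with
cell-based richness averaging). The scenario experiment samples
`n_cells` cells *without replacement* within each replicate
(replicates independent) from three pools: protected cells; protected ∪
refugium cells; and protected ∪ a uniform random set of unprotected
cells equal in count to the refugium, redrawn every replicate.
Uniform (non-contiguous) random cells and per-replicate redraw are
choices the underlying design leaves open; both are the most neutral
null. The reference design is 1000 cells × 100 replicates; the synthetic
default uses 500 cells, proportionate to its 100 × 100 grid (the
protected pool alone holds only ~1500 cells).

## The synthetic world

The generator's job is to plant a known truth with the statistical
structure the analysis assumes:

- **Climate.** Two variables (labelled BIO1/BIO12, dimensionless
  synthetic units) ramp linearly across columns/rows over 0–10, so
  climate space maps affinely onto the grid. Each of the `T = 60` slices
  (610 → 20 kyr BP, 10 kyr steps — a shorter axis with the same spacing
  as the 257-slice reference, sized for desk-scale runs) adds an
  independent zero-mean Gaussian anomaly with SD 0.2 inside the planted
  30 × 30 core and 2.0 outside; that variance asymmetry *is* the
  stability signal. Anomalies are temporally independent — the stability
  statistic only responds to variance structure, and independence keeps
  analytic expectations available — so the generator does not emulate
  autocorrelated climate cycles, orbital forcing, or spatially
  correlated anomalies.
- **Species.** Gaussian suitability kernels in climate space with
  niche breadth 1.5 units: a specialist's tolerance well inside the
  0–10 regional span, chosen so that outside-core noise (SD 2.0)
  repeatedly expels cells from the suitable set while inside-core noise
  (SD 0.2) never does — the regime in which persistence thresholds
  separate core from non-core. The 10 indicator species get optima
  jittered ±0.3 around the core's mean climate; the 40 focal species
  get optima offset by half-normal magnitudes (scale 1.5) in random
  directions, with offsets ranked by terminal branch length so the most
  evolutionarily distinct lineages sit nearest the core climate. This
  plants, mechanically rather than by simulating diversification, the
  museum pattern the analysis is designed to detect: richness, PD and
  RPD all decline away from the stable core. Occurrences (200 per
  species) are cell centers sampled without replacement proportional to
  contemporary suitability.
- **Forest.** Tree density is a broad envelope (kernel SD twice the
  niche breadth) on the long-term mean climate surface plus independent
  observation noise — standing forest integrates over decades, so it is
  deliberately *not* a function of the single contemporary anomaly
  draw.
- **Protected areas.** Random non-overlapping rectangles to a target
  coverage of 15% ± 2%, oblivious to diversity — as real protected-area
  placement largely is to amphibian diversity.

What passing tests therefore show: the pipeline recovers a planted
variance-asymmetry signal end-to-end through model fitting,
thresholding, stacking, delineation, diversity mapping and regression.
What they do not show: performance under niche misspecification,
temporally autocorrelated or spatially structured climate change,
sampling bias in occurrences, or range dynamics driven by dispersal
limitation — all absent from the generator. Because the planted core
boundary is sharp, the four refugia fractions can coincide on the
default world; real, noisier landscapes produce genuinely nested
classes, which the tests exercise with random persistence tables
instead.

Determinism: one master seed derives fixed per-stage seeds
(`seed·101 + stage offset`), so each stage is individually rerunnable
and the full pipeline is byte-reproducible; the acceptance script takes
the seed on the command line.

## Problem sizes and runtime

Default study conditions: 100 × 100 cells, 60 slices, 10 + 40 species,
10,000-point backgrounds. A full pipeline run takes on the order of ten
seconds; the complete test suite (including 100-fixture oracle sweeps
and a full default-world run) about a minute.

## Known limitations

- No reprojection: real-data users must supply pre-gridded layers on a
  shared metric grid.
- The Maxent surrogate implements linear + quadratic features only; no
  hinge/product features, clamping, or MESS-style extrapolation maps.
- Refugium "edge" distance is cell-based, not polygon-based.
- No randomization-based significance (e.g. null-model tests for
  RPD/PE), and no correction for the modifiable areal unit problem;
  cells are the sampling units without thinning.
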