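# paleorefugia

Did tropical diversity accumulate where habitat stayed stable through the
Pleistocene, or does it simply track today's climate? `paleorefugia`
implements a quantitative workflow for answering that question with
hindcast ecological niche models (ENMs): build a *forest stability*
surface by stacking thresholded ENM hindcasts of forest-obligate
indicator species across a paleoclimate time series, delineate refugia
from it, map spatial-phylogenetic diversity of a focal clade, and
contrast past stability against contemporary climate with spatial
regressions and a protected-area gap analysis.

The package is aimed at biogeographers and conservation planners working
on grid-based (sampling-unit) analyses. Because the empirical inputs of
such studies are large and external, the package ships a fully seeded
synthetic-world generator with a *planted* stable core, so every stage of
the workflow can be validated against a known ground truth.

## The quantities at the core

With a rooted ultrametric phylogeny and per-cell species assemblages, the
package computes, per sampling unit (grid cell):

- **SR** — species richness, the number of species present;
- **PD** — Faith's phylogenetic diversity, `PD = Σ_b L_b` over all
  branches `b` (root-inclusive) spanned by the species present;
- **RPD** — relative PD, the ratio of PD on the true tree to PD on a
  comparison tree with identical topology and every branch set to
  `total length / branch count`;
- **PE** — phylogenetic endemism, `PE = Σ_b L_b / range_b`, each branch
  down-weighted by the number of cells occupied by its descendants.

Past habitat stability is estimated as the stacked persistence of `S`
indicator species over `T` hindcast slices: a cell's stability is
`counts / (S·T)` where `counts` is the number of suitable
(species, slice) pairs; refugia are cells where at least `⌈p·S⌉` species
are each suitable in at least `τ` slices (default fractions
0.50/0.75/0.90/0.95 and `τ = 230` of 257 slices, rescaled
proportionally for shorter axes). Climate stability is the inverse of
the mean per-pair deviation `SD(x_t, x_{t+1}) / Δt`, rescaled to [0, 1].
Regressions use z-standardized OLS and the spatial lag-of-X (SLX) model
on queen-contiguity weights.

## Worked example

The numbered drivers under `analysis/` run the whole study on the
default synthetic world (100 × 100 grid of 4.5 km cells, 60 paleo
slices, 10 indicator + 40 focal species, a 30 × 30 planted stable core):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_enm.R
Rscript analysis/03_stability.R
Rscript analysis/04_diversity.R
Rscript analysis/05_regressions.R
Rscript analysis/06_conservation.R
```

which prints, among other things:

```
temporal SD of BIO1: 0.200 inside core, 1.991 outside
fitted 50 models: 50 accepted, 0 rejected by AUC, 0 by records
Jaccard(strictest refugia, planted core) = 1.000
mean richness: 37.7 inside core vs 11.2 outside
SR   best univariate predictor: forest_stability (coef 0.58, R2 0.33)
PD   best univariate predictor: forest_stability (coef 0.54, R2 0.29)
distance-decay standardized OLS slopes:
  metric  ols_slope         ols_p
1     SR -0.5322224  0.000000e+00
2     PD -0.5088780  0.000000e+00
3    RPD -0.2630429 3.157787e-125
4     PE -0.5087394  0.000000e+00
scenario mean richness: PA 16.21 +- 0.53; PA+refugia 24.26 +- 0.61 (50% gain); PA+random 14.95 +- 0.68
```

Reading this: the generator planted a low-variance core (temporal SD 0.2
vs 2.0); the stability stage recovers that core exactly (Jaccard 1.0);
forest stability is the strongest univariate predictor of richness and
phylogenetic diversity, with a positive standardized coefficient; all
four diversity metrics decline with distance from the refugium edge; and
adding refugia to the protected-area network raises mean protected
richness far more than adding an equal random area. Tables and layers
land under `results/`. The same computations are available
programmatically via `run_pipeline(sim_config(seed = 1))`.

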