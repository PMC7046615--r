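---
title: "From niche models to landscape connectivity: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From niche models to landscape connectivity: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pondscape)
```

# The problem

Pond-breeding amphibians such as the crested and marbled newts depend
simultaneously on two things: *suitable habitat* (breeding ponds embedded in
favourable terrestrial cover, under a tolerable climate) and *connectivity*
between habitat patches, because their dispersal capacity is on the order of
a kilometre. A warming climate moves the suitable areas; whether populations
can follow depends on whether the patch network stays connected.

`pondscape` implements a five-step analysis linking ensemble ecological-niche
modelling (ENM) to graph-theoretic connectivity:

1. **Climate-only ensemble** on a coarse grid: pseudo-absence sampling,
   per-run 70/30 train/evaluation splits, TSS and AUC scoring, and a mean
   across all runs whose TSS exceeds 0.7, with a coefficient-of-variation
   surface as the uncertainty ledger and a MESS surface flagging
   extrapolation when the model is projected to other conditions.
2. **Land-cover-only ensemble** on a fine grid (surface-compactness and
   distance covariates; "disk" pseudo-absences at least 50 m from any
   presence).
3. **Habitat suitability index (HSI)**: the coarse climate surface is
   disaggregated (block replication) to the fine grid and multiplied
   cellwise with the land-cover surface. A Moran's I permutation test on
   residuals at the occurrence cells checks for unexplained spatial
   structure.
4. **Landscape graph**: the HSI is binarized at the 10th percentile of
   training-presence HSI; 8-connected suitable cells form patches (nodes)
   whose capacity is their mean HSI; movement resistance is an exponential
   function of HSI; edges carry least-cost distances; the interaction-flux
   (IF) metric scores each patch's contribution to connectivity, and is
   interpolated across the landscape.
5. **Combination**: per-species IF maps are z-normalized, averaged across
   species, and differenced between current and future scenarios.

Future scenarios change climate only: future HSI pairs the future climate
surface with the *current* land-cover surface. Multiplying the two
probabilities assumes climate and land cover act independently; both
assumptions are inherited from the framework, stated here, and not
mitigated.

# Model components and their conventions

## Evaluation statistics

`auc_roc()` is the rank (Mann–Whitney) AUC with ties counting one half.
`tss()` maximizes sensitivity + specificity − 1 over the distinct score
values, predicting presence at scores `>= t`; ties on the optimum are
broken toward the lower threshold. Ensemble membership requires TSS
*strictly above* the cutoff (default 0.7). The ensemble uncertainty
surface uses the *population* standard deviation in its per-cell
CV = sd/mean (0 where the mean is 0); sample vs population is not
specified by the framework, so the choice is declared here.

## Pseudo-absences and weights

Pseudo-absences are drawn uniformly from cell centres without replacement
within a set; sets are independent, so a cell may recur across sets. The
disk method excludes cells strictly within `min_dist` (default 50 m) of any
presence. Class weights are presence = 1, pseudo-absence =
n_presence/n_pa, so both classes carry exactly equal total weight.

## Learners

The single-model algorithms are pluggable (`register_learner()`); two
families ship: weighted logistic regression (`"glm"`) and a probability
random forest (`"rf"`, 200 trees, single-threaded for reproducibility).
A design of `n_learners × n_pa_sets × n_runs` single models is enumerated
exactly — the classic designs are 8 × 5 × 5 = 200 and 8 × 10 × 5 = 400
models — and `run_enm()` fits every enumerated run.

## MESS

`mess_variable()` implements the standard similarity formula with `f` the
percentage of reference values *strictly below* the projection value (ties
resolved by strict comparison; the source formula is ambiguous on ties).
Negative values mean the projection leaves the calibration envelope. Note
the interior branches are step functions with jumps of `200/n_ref`; the
curve is only approximately continuous for large reference sets, and its
maximum of 100 at the median is attained exactly for even `n_ref`.

## Resistance and cost distance

With binarization threshold `τ`,

resistance(HSI) = 1 if HSI ≥ τ, otherwise `exp(ln(0.001)·HSI/τ)·1000`,

which is 1000 at HSI = 0, decreases exponentially, and meets the suitable
value 1 continuously at `τ`. Moves between 8-neighbour cells cost
`cell_size × mean(incident resistances)`, times √2 for diagonal moves — the
standard cost-distance convention. Patch-to-patch cost distance is the
multi-source shortest path between member cells (computed with Dijkstra's
algorithm via igraph on the grid graph). Because resistance is exactly 1
inside suitable habitat, cost units coincide with metres in ideal terrain;
the dispersal cap (default 1000, i.e. a 1 km maximum dispersal distance) is
therefore applied directly in cost units. Edges above the cap are pruned;
the graph is otherwise complete (no planarization).

## Interaction flux and interpolation

`IF_i = Σ_{j≠i} a_i a_j exp(−α d_ij)` over retained edges, with capacities
`a` and `α = −ln(0.05)/d_max` so that the interaction probability is 0.05
at the dispersal cap. The capacity exponent is fixed at 1. A single or
isolated patch has IF = 0 (the empty sum), and `IF_i ≤ a_i Σ_j a_j`.

Interpolation assigns each cell inside a patch that patch's IF; outside, the
*weighted mean* of the IF of all patches within `d_max` in cost distance,
weights `exp(−α·costdist)`; cells beyond the cap of every patch get 0. The
weighted mean (rather than a sum) recovers a patch's own value at its edge;
the exact kernel of the original interpolation tool is not published, so
this is a declared convention. Cost distance (not Euclidean) is used for
consistency with the graph. Note one consequence: around an isolated patch
the map is flat at the patch's IF out to the cap, then 0 — the map decays
with distance only through the cap and the competition of nearer patches.

## Moran's I residual diagnostic

The framework asks for spatial autocorrelation of "residuals" of the HSI
map at species locations without defining them; here residual = 1 − HSI at
each occurrence cell (observed presence minus predicted index), with
inverse-distance, row-standardized weights among the occurrence cells, and
a two-sided permutation test `p = (1 + #{|I*| ≥ |I|})/(n_perm + 1)`.

## Degenerate inputs

Zero habitat patches is a *recorded outcome* ("no graph"), not an error —
the pipeline continues, mirroring what a severe warming scenario produces.
Constant connectivity maps cannot be z-normalized (error); an empty
ensemble (no run above the TSS gate) is an error; `n_ponds = 0` leaves the
pond-distance covariate undefined and is flagged. Multi-patch overlap at a
cell centre in `rasterize_sc()` resolves to the later patch in the input
list.

# The synthetic landscape

Because the original occurrence and pond-inventory data are not publicly
deposited, the package ships a generator (`synthetic_config()`,
`generate_climate_grids()`, `generate_landcover_layers()`,
`sample_occurrences()`) that reproduces the *statistical structure* the
analysis assumes, so every stage is testable end to end:

* **Grids.** A coarse climate grid with a nested fine land-cover grid.
  Defaults: 64 × 64 coarse cells of 200 m with `fine_factor = 4` (50 m fine
  cells) — the same coarse/fine pairing idea as a 1 km² climate grid over a
  50 × 50 m land-cover grid, shrunk so the whole pipeline runs in tens of
  seconds on one CPU. Coordinates are planar metres; no geographic CRS
  handling.
* **Fields.** Climate and land-cover variables are Gaussian random fields:
  white noise convolved (FFT, torus) with a Gaussian kernel of sd
  `autocorr_range/2` cells (default range 8 coarse cells), standardized to
  mean 0, sd 1. Spatial autocorrelation is what makes disaggregation,
  patch formation and distance decay meaningful.
* **Scenarios.** Future climate = current + an additive shift per variable
  (defaults +0.75 sd for a mild scenario, +2.5 sd for a severe one), land
  cover unchanged — exactly the assumption set of the analysis.
* **Species.** A logistic "true suitability" model with known coefficients
  generates presences (cells drawn with probability proportional to true
  suitability, reported at cell centres). The default species are
  low-prevalence habitat specialists (about 12% of the landscape suitable,
  strong pond-distance response): with weak, diffuse responses the
  theoretical best-achievable TSS of *any* model falls well below the 0.7
  ensemble gate, so a gate-based ensemble is only meaningful for a species
  whose habitat is genuinely distinct — which is also the regime the real
  newt ensembles evaluate in. The two default species share the
  pond-distance response and differ in their climate niche; the first is
  more exposed to warming (its coefficient sum is more negative).

What the generator does **not** emulate: real covariate semantics
(bioclimatic variable definitions), sampling bias of volunteer surveys,
detection error, land-cover change, or biotic interactions. Passing tests
demonstrate that the pipeline recovers known structure from data of this
idealized form — not that any particular real landscape satisfies these
assumptions.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `thin_dist` | 50 | m | one occurrence per 50 m neighbourhood (greedy, input order) |
| `min_dist` (disk PA) | 50 | m | pseudo-absences outside the presence neighbourhood |
| `split_fraction` | 0.7 | — | 70/30 train/evaluation per run |
| `tss_cutoff` | 0.7 | — | ensemble gate, strict |
| `percentile` | 0.1 | — | binarization at the presence 10th percentile (linear-interpolation definition, `quantile type 7`) |
| `dispersal_dist` | 1000 | cost units ≈ m | maximum newt dispersal; also calibrates `α` |
| `corr_threshold` | 0.7 | — | absolute-correlation grouping for variable selection |

Percentile dialects differ across software; the linear-interpolation
definition is declared (presence HSI {0.1, …, 1.0} gives 0.19).

# Sizes used by the bundled tests

The test suite runs the complete pipeline at the default study scale
(64 × 64 coarse grid, fine factor 4, 300 presences, 2 learners × 2 PA sets
× 2 runs per scale), plus oracle comparisons at deliberately tiny sizes:
exhaustive path enumeration on ≤ 4 × 4 resistance grids, a double-loop
interaction-flux oracle on ≤ 12-patch graphs, pairwise-concordance AUC at
n ≤ 50, and a 200-replicate calibration check that Moran permutation
p-values are uniform under a spatially random null. These sizes are the
package's chosen worked-example conditions; all structural results (formula
endpoints, enumeration counts, monotonicities) are scale-free.

# Known limitations

* The two probability surfaces are multiplied as if independent; no
  interaction between climate and land cover is modelled.
* Thresholding at the presence 10th percentile inherits all the caveats of
  presence-based thresholds (sensitivity to sampling bias).
* Cost units are identified with metres through the resistance-1 interior;
  if a study needs an empirical cost↔distance calibration, the dispersal
  cap must be re-expressed accordingly.
* The learner registry intentionally does not reproduce any specific
  legacy algorithm suite; conclusions that depend on a particular
  algorithm's inductive bias are out of scope.
* The Moran residual definition (1 − HSI at presences) is a declared
  stand-in; no model-fitting residual exists at the HSI stage.
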