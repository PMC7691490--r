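---
title: "Inferring community assembly processes with phylogenetic null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes with phylogenetic null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inference problem

Microbial communities are structured by a mixture of deterministic
(niche-based selection) and stochastic (dispersal, drift) ecological
processes. `ecoassembly` implements the phylogenetic null-model framework
that partitions pairwise community comparisons among five processes, using
two statistics in sequence:

1. **betaMNTD**, the between-community mean nearest taxon distance: for a
   sample pair (A, B), the abundance-weighted mean patristic distance from
   each taxon in A to its closest relative in B, averaged with the reverse
   direction. A taxon present in both samples is its own closest relative,
   contributing zero.
2. **betaNTI**: the deviation of observed betaMNTD from a tip-randomization
   null, in null standard-deviation units. Each of 999 iterations draws a
   single permutation of the assignment between taxa and tree tips — shared
   across all pairs in that iteration, spanning every taxon in the analyzed
   table — and recomputes betaMNTD. betaNTI below −2 indicates less
   phylogenetic turnover than chance (homogeneous selection: the same
   environment keeps selecting close relatives), above +2 more turnover
   than chance (heterogeneous selection).
3. **RC-bray** for pairs in the stochastic band (−2 < betaNTI < 2): the
   position of the observed Bray–Curtis dissimilarity inside a null of
   probabilistically reassembled communities. Each null community keeps
   its sample's observed richness and total count; taxon identities are
   drawn without replacement with probability proportional to
   metacommunity occupancy, each drawn taxon receives one individual, and
   the remainder is allocated multinomially by metacommunity relative
   abundance. RC-bray = 2·(fraction of null values below the observed,
   ties half-weighted) − 1. Below −0.95 the pair is attributed to
   homogenizing dispersal, above +0.95 to dispersal limitation acting with
   drift, and the interior to drift alone.

Relative contributions are fractions of pairwise comparisons per process,
over all pairs or within groups (`process_profile()`).

The framework is only meaningful when ecological similarity tracks
phylogenetic similarity at short distances. `mantel_correlogram()` tests
this precondition: per-taxon environmental optima are abundance-weighted
means of each abiotic variable over the samples where the taxon occurs
(`niche_optima()`); between-taxon optima distances (Manhattan per
variable, or Euclidean over log10 optima for the combined test) are
correlated with class membership across fifty equal-width patristic
distance classes, with 999-permutation two-sided p-values and a
progressive Holm correction.

## Conventions and numerical choices

* **Boundary convention.** The five-way rule uses strict inequalities, so
  betaNTI = ±2 and RC = ±0.95 are not assigned by the published
  thresholds. Values exactly at a threshold fall to the stochastic /
  interior side: |betaNTI| = 2 proceeds to the RC test and |RC| = 0.95 is
  drift alone. This is conservative toward stochasticity.
* **Degenerate nulls.** On small trees the tip-shuffle null can be a point
  mass; if the observed value sits away from it, betaNTI is undefined and
  an error is raised rather than returning ±Inf. The one exception is a
  pair with identical taxon support, where observed and every null value
  are exactly zero; the standardized deviation is then defined as 0 and
  the RC test decides the pair (such near-identical communities are
  correctly read as homogenizing dispersal).
* **Abundance weighting.** betaMNTD weights each taxon's nearest-relative
  distance by relative abundance by default (`abundance_weighted = TRUE`),
  consistent with analyzing rarefied count tables; an unweighted variant
  is available.
* **RC ties** are counted with half weight at an absolute Bray–Curtis
  tolerance of 1e−12. Each pair's Monte-Carlo stream is sub-seeded from
  the sorted sample names, so results are identical regardless of the
  order pairs are evaluated in, and `raup_crick_bray()` internally sorts
  the pair, making it exactly orientation-invariant.
* **Permutation scope.** One tip permutation per iteration over all taxa
  present in the analyzed table, shared across pairs. Patristic distances
  are computed once and permuted by index.
* **Correlogram.** Equal-width distance classes over [0, max patristic
  distance]; the Mantel statistic between the ecological distance matrix
  and the binary class indicator is sign-oriented so positive values mean
  "more similar than expected by chance" (the interpretation used when
  such correlograms are plotted). Permutations relabel taxa
  (simultaneous row/column shuffles); two-sided
  p = (1 + #{|r_perm| ≥ |r_obs|})/(n_perm + 1). Classes with fewer than
  two pairs are untestable and excluded from the progressive correction.
  "Log-normalized" combined optima use log10, with an additive shift
  bringing a variable's minimum to 1 only when nonpositive optima occur;
  shifts are recorded on the result.
* **Rarefaction** is a multivariate hypergeometric subsample (without
  replacement) to exact depth; samples under depth are dropped and
  reported, and emptied taxa removed.
* **Flux math.** Respiration rate = ppm CO2 × P·V/(R·T) × 12 / (g dry
  soil · hours since flush), with R = 0.0821 L·atm·K⁻¹·mol⁻¹
  (configurable). Q10 = (k_high/k_low)^(10/Δt); with 15 °C and 4 °C the
  exponent is 10/11. Stabilized-window averaging defaults to days 20–193.

## What the synthetic study emulates

The generators map one-to-one onto the five processes so classifier
recovery is interpretable; `simulate_assembly_study()` assembles them into
one reproducible study and `recover_processes()` scores recovery the way
field studies score within-group comparisons against a larger analyzed
table.

* **Phylogeny.** The study uses `simulate_structured_tree()`: many small
  terminal clades (three tips) on a deep backbone plus a couple of deep
  singletons. Real 16S gene trees have exactly this deep-versus-shallow
  contrast, and it is the geometry in which nearest-taxon statistics carry
  information at a 50-taxon pool size; reconstructed birth-death trees of
  50 tips (`simulate_tree()`, used elsewhere) are too uniformly filled for
  taxon subsets to ever be phylogenetically "far" from one another.
* **Niche trait.** `guild_niche_traits()` places each clade in one of two
  niche guilds separated by a fixed offset, plus clade- and tip-level
  Gaussian divergence. Close relatives share nearly identical niches while
  deep relationships carry almost none — the short-distance-only signal
  that real Mantel correlograms show, arising from niche convergence among
  distant lineages. (Pure Brownian motion on the clock tree creates signal
  at *all* depths; it is used for the correlogram validation, where that
  is the property under test.)
* **Selection.** Two groups are filtered at the two guild centres with a
  Gaussian fitness filter. The selection community size (28 individuals
  against a ~24-taxon guild) keeps the expected count per member near 1.2,
  so replicate communities turn over in *membership among close relatives*
  — the signature betaNTI reads as homogeneous selection — while
  between-group pairs replace one guild by the other (heterogeneous
  selection). Within-group pairs score homogeneous selection; between-group
  pairs heterogeneous.
* **Drift.** Multinomial draws from Dirichlet-perturbed regional relative
  abundances; no reference to traits or tree. The regional metacommunity
  is a geometric rank-abundance series (decay 0.7, ranks randomly assigned
  to taxa), the classic niche-preemption model; a deterministic dominance
  structure keeps the RC null's behaviour stable across random study
  realizations.
* **Dispersal limitation.** Each sample draws its own random pool of
  endemic taxa — the candidate pool excludes the eight regionally dominant
  taxa, as in habitat patches closed to the regional pool — and develops
  its own within-pool dominance (Dirichlet 0.6). These samples are
  analyzed together with 24 regional reference communities, which is what
  gives the RC null its occupancy and abundance structure, exactly as the
  full sample collection does in a field study.
* **Homogenizing dispersal.** Near-copies of one template with 2% of
  individuals exchanged against the regional metacommunity (immigrants
  arrive in proportion to the source pool, as mass effects imply).
* **Respiration.** Paired 4 °C / 15 °C rate series with known temperature
  sensitivity and mean-one lognormal measurement noise, for closed-form
  Q10 recovery.

What passing recovery tests do **not** show: the generators contain no
sequencing error, no compositional bias, no taxonomic misassignment, and
the processes act purely, one per group; real communities mix processes
and violate all of these. Recovery here validates the inference machinery,
not the interpretability of any particular field dataset.

## Power of betaNTI at small pool sizes

A finding of this package's validation work, documented because it shapes
what recovery rates are attainable: for sample pairs whose observed
betaMNTD is near zero, betaNTI ≈ −mean/sd of its null, a quantity
invariant to the total weight of non-shared taxa. It grows roughly with
the square root of the number of non-shared taxa that contribute, and with
how bimodal the nearest-taxon distance distribution is. On a 50-taxon
tree, a random taxon subset the size of a typical sample almost always
contains a close relative of any tip, so the null mean stays small and the
ratio plateaus near 2 — the classification threshold itself. An idealized
upper-bound generator (exact Poisson member-turnover on the structured
tree) reaches within-group homogeneous-selection classification rates of
only ~0.4–0.7 across seeds, and the honest simulation chain matches that
plateau (~0.5–0.8). Heterogeneous selection, homogenizing dispersal,
dispersal limitation and drift are recovered at or near 1.0 under the same
conditions. The homogeneous-selection clause of the package's recovery
test is therefore expected to sit at the edge of its nominal 0.70
threshold; with thousands of taxa (as in real rarefied tables) the
statistic has ample power, which is why the framework works in practice at
field scale.

## Problem sizes

The validation suite runs: 999-iteration nulls on a 50-taxon study with 8
samples per regime plus 24 reference samples; 50 correlogram runs on
100-tip trees and 100 label-shuffled calibration runs at 999 permutations;
200 noisy Q10 recoveries; exhaustive enumeration oracles on ≤6-taxon trees
and ≤4-individual Raup–Crick tables. These sizes were chosen so each check
is statistically meaningful while the whole suite stays quick to run on a
laptop.

## Limitations

* The five-way partition inherits the framework's assumptions: phylogenetic
  signal in niche space at short distances, a meaningful regional
  metacommunity, and rarefied (equal-depth) count tables.
* No per-taxon-bin partitioning, no alpha-diversity indices (NRI/NTI), and
  no ITS/fungal support — nearest-taxon methods presuppose a phylogenetically
  conserved marker.
* RC-bray depends on the sample set that defines the metacommunity;
  within-group profiles should be computed from an analysis table that
  includes the full study, not the group in isolation.
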