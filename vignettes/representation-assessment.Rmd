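---
title: "Complementary sets and protected-area representation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complementary sets and protected-area representation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csrep)
```

## The problem

A protected-area (PA) network can satisfy an areal target (such as Aichi
Target 11's 17% of terrestrial area) while still missing the places that
matter most for biodiversity. A species-based way to ask "does the network
represent biodiversity?" is to (i) find a *complementary set* (CS) of
planning units — counties, grid cells, any assessment unit — that jointly
contains every species of interest at least once, and (ii) measure how much
of that set the PA network actually covers. Units of the CS without
meaningful protection are *conservation gaps*; species whose occurrences
fall entirely outside protected units are unprotected species.

`csrep` implements this assessment end to end on binary species-by-unit
incidence data, plus a stratified bootstrap that quantifies how sensitive
the selected set is to which units happened to be sampled.

## Complementarity and the selection algorithm

For two sites $j$ and $k$ with species richness $S_j$ and $S_k$ sharing
$V_{jk}$ species, the complementarity score is

$$C_{jk} = 1 - \frac{V_{jk}}{S_{jk}}, \qquad S_{jk} = S_j + S_k - V_{jk},$$

i.e. one minus the Jaccard similarity of the two species sets: 0 for
compositionally identical sites, 1 for fully complementary (disjoint) ones.
It is undefined when both sets are empty, and `complementarity_score()`
errors in that case.

`build_complementary_set()` assembles the CS greedily:

1. **Seed** with the unit of greatest species richness, counted within the
   configured universe (all species, threatened species only, or a custom
   filter), so a threatened-species run seeds on threatened richness.
2. **Stage loop.** Species are processed in priority stages — by default
   nationally protected or threatened species first, then everything else.
   Within a stage, the algorithm repeatedly scores every unit not yet
   selected that would add at least one uncovered species of the stage's
   class, picks the winner, and adds it, until the stage's class is fully
   covered (or no remaining unit can help, which cannot happen when every
   species occurs somewhere).

Two selection criteria are provided because both appear in the
reserve-selection literature for this algorithm and they are not equivalent
step by step:

* `mode = "complementarity_score"` (default): maximise $C$ between the
  candidate and the *pooled* species of the current set, treating the set
  built so far as one composite site;
* `mode = "new_species_count"`: maximise the number of not-yet-covered
  species the candidate adds (classic richness-gain greedy).

Three decisions here were genuinely open and are the package's own:

* **Pooled union, not pairwise.** The score of a candidate against "the
  set" is computed against the union of the members' species, which is the
  reading under which "until the set covers all species" is the natural
  termination condition. A pairwise-minimum variant is not implemented.
* **Zero-gain candidates are ineligible.** Under a literal score-maximising
  rule, a tiny unit whose species are all covered already can outscore a
  unit adding many species (its $C$ approaches 1 as the pooled set grows),
  and the loop would stall short of full coverage. Excluding candidates
  that add nothing preserves the termination condition and makes both modes
  cover 100% of the universe.
* **Stage-restricted scoring.** In the priority stage, scores and coverage
  targets are computed on the priority class only (otherwise "the stage
  covers all priority species" is ill-defined); every species a selected
  unit carries still counts as covered from then on.

Ties break by criterion, then by universe richness (the tie-break the
algorithm specifies), then by lexicographic unit identifier. The last rule
is ours, purely so that identical inputs give identical traces.

The greedy CS is an approximation to minimum set cover, which is NP-hard;
no exact solver is in the product path. The test suite checks against
exhaustive-search optima on small instances that the greedy cover is
complete, monotone, and never smaller than the optimum, and that on planted
block structures with a unique minimal cover it recovers that cover exactly
in both modes.

## Representation, gaps and summaries

With $S_P$ the units meeting a protection criterion — PA presence, or PA
coverage $\ge$ a threshold $t$ (inclusive, `select_protected_units()`) —
and $a = |CS \cap S_P|$, $b = |CS \setminus S_P|$, the ecological
representation index is

$$I_E = \frac{a}{a+b} \times 100\%.$$

`representation_index()` computes $I_E$ on exact counts and rounds only for
presentation (half-up, one decimal), so printed values are reproducible
bit-for-bit from the integer counts. `assess_representation()` evaluates
the presence criterion plus a threshold grid (default 10/20/30/40%);
$I_E$ is non-increasing in the threshold by construction.

`identify_gaps()` reports the gap units ($CS \setminus S_P$) and
unprotected species under two selectable definitions, because "not covered
by existing PAs" is ambiguous:

* `"rangewide"` (default): species with zero occurrences in any protected
  unit, anywhere in the study region — the literal reading;
* `"cs_only"`: species whose occurrences *within the CS* lie entirely in
  gap units, i.e. species unique to the gaps from the set's perspective.

Neither definition contains the other in general, so each is tested against
its own brute-force evaluation rather than against the other.

Further summaries: `congruence_summary()` (units and area shared between
the CS and the PA-present units, as percentages of their union);
`coverage_class_areas()` (unit counts and area shares of the CS by coverage
class, with a distinguished exact-zero class followed by half-open
intervals $[e_i, e_{i+1})$, reconciling "meets a threshold" reporting with
"greater than 0 but below 5%" tallies); `regional_effectiveness()` (the
share of each biogeographic region's species captured by CS units *inside*
that region, with mean and SD across region-by-taxon cells); and
`representation_time_series()` (the index re-evaluated against a per-year
coverage layer; no monotonicity is imposed, since PAs can be downsized or
degazetted).

PA registries often report only a PA's total area plus the units it
intersects. `allocate_pa_area()` divides the total equally among those
units when no per-unit breakdown exists, and `compute_pa_coverage()` sums
contributions per unit, capping at the unit's land area (coverage 1.0, with
a warning) where PAs overlap — registries are silent on overlap, and
capping is the conservative choice.

## Bootstrap robustness

County-level occurrence data carry geographic sampling error, and greedy
selection is potentially sensitive to it, especially through rare species.
`bootstrap_robustness()` measures this: for each sampling fraction
(default 60/70/80/90%) and replicate, it draws a stratified sample of
units — `round-half-up(fraction × n)` per stratum, minimum 1, without
replacement; stratification by biogeographic region keeps every
environmental zone in each subset — restricts the incidence matrix to the
sample (species losing all occurrences drop out of that replicate's
universe rather than aborting it), rebuilds the CS with the same selection
configuration, and computes the proportional overlap $N_c / N_s$ with the
full-data CS ($N_s$ the subset CS's size, $N_c$ its units shared with the
original). High mean overlap across replicates means the selection is
robust to sampling.

Sampling is of planning units, not of presence records. Each replicate runs
on its own seed derived deterministically from the master seed and the
(fraction, replicate) indices, so the full replicate table is reproducible
and a 200-replicate run shares its first 200 draws with a 1000-replicate
run.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical shape of a national
county-level occurrence database so the whole pipeline is testable without
any download. What it reproduces:

* six taxon groups of very unequal size — the defaults, 520 woody plants,
  115 ferns, 20 amphibians, 23 reptiles, 68 birds and 30 mammals across
  240 units in 8 strata, are a 1/20-scale rendition of a national
  flora/fauna database (a scale at which a full build-assess-bootstrap
  cycle runs in seconds);
* heavy-tailed occupancy: per-species occupancy is drawn from a truncated
  log-series (default $\theta = 0.98$; P$(n) \propto \theta^n/n$ on
  $1..n_{units}$), so most species are narrow-ranged and a few are
  widespread — the regime that actually drives complementary-set behaviour;
  a truncated lognormal is available for sensitivity checks;
* range cohesion: a species' occurrences fall in its home stratum with
  probability mass 0.8 by default, uniformly elsewhere, giving the
  within-region clustering that regional-effectiveness and stratified
  resampling assume;
* threat concentrated among narrow-ranged species via rank weights
  (configurable strength), with per-group threatened fractions defaulting
  to national Red-List ratios (e.g. ~14% of woody plants, ~43% of
  amphibians);
* a zero-inflated, right-skewed PA layer: 30% of units with no PA and
  Beta(0.6, 4) coverage elsewhere, i.e. mostly under 10%.

Strata double as the bootstrap stratification and as the region assignment
of units and species (home stratum) unless configured otherwise. What the
generator does *not* emulate: spatial contiguity (no coordinates or
adjacency), detection error, taxonomic mis-assignment, or correlation
between unit area and richness. Tests passing on synthetic data therefore
demonstrate algorithmic correctness and statistical behaviour under the
stated generative model, not fidelity to any particular real fauna.

`simulate_planted_cover()` builds known-answer fixtures: designated units
that are sole holders of an endemic (and threatened) species and hence
irreplaceable, decoy units carrying only subsets of already-covered
species, and a machine-readable ground-truth manifest. The unique minimal
cover is the designated units, for any correct selection rule; decoys can
enter a subset-derived CS only when sampling removes a designated unit,
which is what gives the bootstrap's overlap statistic something to detect.
`simulate_pa_timeline()` generates nondecreasing per-unit coverage paths
(or paths with occasional decreases at a configurable degazettement rate)
for time-series testing.

## Numerical choices and edge cases

* Percentages are computed on exact rational counts; rounding (half-up) is
  presentation-only.
* Threshold comparison is inclusive ($\ge t$); `t = 0` degenerately selects
  every unit.
* Duplicate presence records collapse with a warning count; they are data
  reality, not an error.
* An empty species universe, an empty CS passed to scoring, both-empty sets
  in the pairwise score, a PA naming zero units, and coverage outside
  $[0,1]$ are errors with the offending identifiers named.
* Bootstrap replicates whose restricted universe is empty are flagged
  failed and excluded from means, not silently dropped.

## Worked example

```{r example, eval = FALSE}
ds <- simulate_dataset(simulation_config(seed = 42))
cs <- build_complementary_set(ds$incidence, ds$species, selection_config())
assess_representation(cs, ds$units)
br <- bootstrap_robustness(ds$incidence, ds$species, ds$units,
                           selection_config(),
                           bootstrap_config(replicates = 100, seed = 42))
br$summary
```

The `run_*` functions chain the same steps through files on disk and write
delimited tables plus JSON manifests, so a full analysis is reproducible
from its output directory alone.

## Limitations

The greedy CS is not the unique minimum cover, and near-ties mean distinct
data subsets can yield rather different sets of equal quality — which is
precisely what the bootstrap overlap quantifies, and why representation is
assessed against the CS as a reference frame rather than as "the" optimal
network. Representation treats all protected units as equally effective;
management effectiveness, costs, connectivity and spatial design are out of
scope, as is any GIS geometry — location enters only as unit attributes.
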