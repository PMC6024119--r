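# csrep — complementarity-based assessment of protected-area representation

`csrep` is an R package for species-based gap analysis of protected-area
(PA) networks, aimed at conservation planners and biodiversity informaticians
working with county- or grid-level occurrence data. It answers the question:
*if a minimal-ish set of planning units sufficed to represent every species
at least once, how much of that set does the existing PA network actually
protect?*

## The method

**Complementary set (CS).** From a binary species-by-unit incidence matrix,
a set of units jointly covering every species of a target universe (all
species, or threatened species only) is assembled greedily: seed with the
richest unit, then repeatedly add the unit maximising the complementarity
score against the pooled species of the set so far,

    C_jk = 1 − V_jk / S_jk,   S_jk = S_j + S_k − V_jk,

(one minus Jaccard similarity; a richness-gain criterion is available as an
alternative mode), processing nationally protected and threatened species in
a priority stage first, until the universe is covered. Ties break by
richness, then unit id, so runs are deterministic.

**Representation.** With `a` CS units meeting a protection criterion (PA
presence, or PA coverage ≥ a threshold) and `b` failing it, the ecological
representation index is

    I_E = a / (a + b) × 100%.

CS units failing the criterion are conservation gaps; species without any
protected occurrence are unprotected species. Congruence, coverage-class,
per-region capture and time-series summaries round out the report.

**Robustness.** A stratified bootstrap resamples 60–90% of units per
biogeographic stratum, rebuilds the CS on each subset, and reports the
proportional overlap `N_c / N_s` with the full-data CS.

A seed-reproducible synthetic generator (heavy-tailed occupancy, range
cohesion within strata, threat concentrated in narrow-ranged species,
zero-inflated right-skewed PA coverage) makes the whole pipeline testable
without external data.

## Worked example

```r
library(csrep)

ds <- simulate_dataset(simulation_config(seed = 42))
ds$incidence
#> incidence matrix: 776 species x 240 units, 9569 presence records

cs <- build_complementary_set(ds$incidence, ds$species, selection_config())
cs
#> complementary set (all species, mode complementarity_score): 170 units covering 776/776 species

assess_representation(cs, ds$units)
#>   criterion threshold   a   b       i_e i_e_rounded
#> 1  presence        NA 123  47 72.352941        72.4
#> 2  coverage       0.1  54 116 31.764706        31.8
#> 3  coverage       0.2  28 142 16.470588        16.5
#> 4  coverage       0.3  13 157  7.647059         7.6
#> 5  coverage       0.4   7 163  4.117647         4.1

identify_gaps(cs, select_protected_units(ds$units, "presence"),
              ds$incidence, species_table = ds$species)
#> gap report (rangewide): 47 gap units; 58 uncovered species (17 threatened, 25 endemic)

br <- bootstrap_robustness(ds$incidence, ds$species, ds$units,
                           selection_config(),
                           bootstrap_config(replicates = 50, seed = 42))
br$summary
#>   fraction n_ok n_failed mean_overlap sd_overlap min_overlap max_overlap
#> 1      0.6   50        0    0.8217803 0.03149256   0.7500000   0.8907563
#> 2      0.7   50        0    0.8573028 0.02751585   0.7972028   0.9338235
#> 3      0.8   50        0    0.9032548 0.02514253   0.8269231   0.9659864
#> 4      0.9   50        0    0.9403126 0.01819656   0.9030303   0.9745223
```

Reading: 170 of 240 simulated units are needed to represent all 776 species
once; 72.4% of them contain some PA, but only 4.1% reach 40% coverage — the
gap between areal protection and representation the method is designed to
expose. The 47 gap units leave 58 species (17 threatened) with no protected
occurrence anywhere. Mean bootstrap overlap rises from 0.82 at 60% sampling
to 0.94 at 90%, i.e. the selection is reasonably robust to which units were
surveyed.

The `run_simulate()` / `run_build_cs()` / `run_assess()` / `run_bootstrap()`
/ `run_report()` functions chain the same steps through delimited files and
JSON manifests on disk. `vignettes/representation-assessment.Rmd` documents
the model, the design decisions and the generator's scope.

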