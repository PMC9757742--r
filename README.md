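# coexsim

Simulation of coextinction cascades in spatially explicit vertebrate food
webs under climate and land-use change.

## What it is for

When climate or habitat loss removes a species, the loss rarely stops
there: consumers lose resources (bottom-up coextinction), surviving
consumers concentrate their pressure on fewer resources (top-down
overexploitation), and whole branches of a web can become disconnected from
its basal species. Estimating how much these network effects *amplify*
direct, driver-caused extinctions requires a model in which the same forcing
can be run with and without the network. `coexsim` provides that model for
ecologists studying community disassembly: a lattice of localities, each
holding a community of virtual vertebrate species assembled into a
weighted directed food web, forced by monthly climate and yearly land-use
series, with dispersal, niche adaptation, and cascading coextinctions — and
a matched control arm in which primary extinctions are plain removals. The
per-replicate **coextinction effect** is
`100 × (loss_coext − loss_control) / loss_control`.

The core pieces:

* **Climatic niche** — per climate variable, an asymmetric pair of logistic
  tails calibrated so that local extinction probability is exactly
  `1 − p_thresh = 0.05` at the extreme values a species experienced in its
  calibration window, near 0 at the mean; the two variables combine by the
  minimum-survival rule `p = max(p_T, p_P)`.
* **Virtual species** — body mass, trophic level and breadth transferred by
  body-size matching from trait tables, a 1–10-letter functional phenotype
  scored through a random 26×26 trait-compatibility matrix, an adaptive
  capacity `A ∈ [0, 1]`.
* **Web assembly** — a link from resource to consumer requires trophic
  ordering within breadth, a body-mass ratio inside taxon-pair limits
  (central 90% of empirical prey–predator ratios), and functional
  compatibility > 0.55; weights are the compatibility rescaled linearly to
  (0, 1].
* **Coextinction engine** — competition rescaling `A′_ij = A_ij² / Σ_j A_ij`
  (weights 0.5, 0.2, 0.1 on one resource become 0.3125, 0.050, 0.0125);
  frozen thresholds at the worst-off consumer and the most-pressured
  resource; cascades iterate bottom-up, top-down and disconnection
  extinctions to a fixed point.
* **Fixtures** — a synthetic generator for every input: seasonal gridded
  climate with a secular trend, land-use trajectories, and trait tables
  with log-normal masses, mass-linked trophic levels and taxon-structured
  mass-ratio records. The whole package builds and tests with no external
  data.

See `vignettes/coexsim-methods.Rmd` for the full model description,
parameter defaults, and design decisions.

## Worked example

A desk-scale experiment: a 5×5 world warming at 0.8 °C/decade for 40 years,
constant land use, five paired replicates.

```r
library(coexsim)

set.seed(20)
climate <- make_climate()        # 5x5 grid, 45 years, warming trend
landuse <- make_landuse()        # constant natural-land fraction
tables  <- make_trait_tables(climate)

ex <- run_experiment(climate, landuse, tables,
                     config = desk_config(replicates = 5),
                     master_seed = 20)

aggregate(mean_loss ~ arm, ex$summary, mean)
#>       arm mean_loss
#> 1   coext 0.3561903
#> 2 control 0.2013537

ex$effect
#>   replicate mean_loss_coext mean_loss_control coextinction_effect
#> 1         1       0.4636504         0.2416159            91.89562
#> 2         2       0.3793545         0.2484222            52.70558
#> 3         3       0.4480195         0.1745277           156.70404
#> 4         4       0.2128691         0.1561748            36.30181
#> 5         5       0.2770581         0.1860279            48.93368
```

`mean_loss` is the mean relative local diversity loss across occupied
cells between the post-burn-in snapshot and the final year; the last column
is the percentage amplification of that loss caused by modelling the
networks — here the webs raise primary losses by roughly 36% to 157%
depending on the replicate. `ex$metrics` holds the per-cell, per-year records
(richness, links, connectance, diameter, largest weakly connected
component, trophic and body-mass summaries, and extinction-cause tallies),
and `write_outputs(ex, dir)` serializes everything with a JSON manifest.

A thin command-line wrapper covers the same workflow from a shell
(`inst/cli/coexsim.R fixtures|run|sweep`; `sweep` is the uniform
parameter-randomization harness).

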