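---
title: "coexsim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coexsim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coexsim` simulates a lattice world of virtual vertebrate species whose
local communities are organized into weighted, directed food webs, and asks
how much of the diversity loss under climate and land-use forcing is due to
the *network* — coextinction cascades, overexploitation by colonizers,
competitive displacement — rather than to the direct (primary) effects of
the forcing itself. Every simulation therefore runs twice from the same
snapshot: a coextinction arm with full network dynamics and a control arm
in which primary extinctions are plain removals. The percentage increase in
loss of the first arm over the second is the coextinction effect.

This vignette documents the model, its parameters and defaults, the
synthetic data generator, and the numerical and design decisions taken
where more than one faithful implementation was possible.

## The climatic niche

A species' niche along one climate variable (monthly temperature in degrees
Celsius, or monthly precipitation in millimetres) is an asymmetric
bell-shaped curve of local extinction probability built from two logistic
tails:

$$
p(x) \;=\; \begin{cases}
1 - \dfrac{1}{1+e^{-c\,(x-d)}} & x \le \bar{x}\\[2ex]
\dfrac{1}{1+e^{-a\,(x-b)}} & x > \bar{x}
\end{cases}
$$

where $\bar{x}$ is the mean of the monthly values in the species'
calibration window and the curve is calibrated so that $p = 1 - p_{\rm
thresh} = 0.05$ exactly at the most extreme values recorded in that window
($v_{\min}$, $v_{\max}$). The slope $a$ starts at $10^{-4}$ and is raised
in steps of $0.01$, with the intercept recomputed at every step from the
closed form $b = [\log(p_{\rm thresh}/(1-p_{\rm thresh})) + a\,v_{\max}]/a$
(which is what keeps the edge condition pinned), until the right tail
evaluated at $\bar{x}$ falls to $\le 0.001$; the left tail is calibrated
analogously with a $0.9998$ survival criterion. Two decisions here were
genuinely open:

* the stopping rule does not name its evaluation point; we evaluate at
  $\bar{x}$, which makes the curve essentially flat-bottomed at the niche
  optimum and matches the intended shape (near-zero risk under optimal
  conditions);
* constant calibration samples ($v_{\min}=v_{\max}$) admit no iteration;
  such axes are flagged degenerate and the closed forms alone pin
  $p = 0.05$ at the single tolerated value.

An iteration cap (default $10^6$) turns pathological samples into an error
rather than an endless loop. The two axes combine by the minimum-survival
rule: the bidimensional extinction probability at $(T, P)$ is
$\max\{p_T(T),\, p_P(P)\}$.

**Adaptation.** With probability $p_{\rm adp} = 0.001$ per species, cell
and year, a species shifts its whole niche (center and both tolerance
edges, rigidly, per axis) along the segment towards the previous year's
local mean conditions, by a length $C_{\rm adp} \times A \times d_N$ with
$C_{\rm adp} = 0.01$ and $A \in [0,1]$ the species' adaptive capacity.
$d_N$ is measured with each axis standardized by its world-wide standard
deviation so degrees and millimetres are commensurable; note that because
the shift length is itself proportional to $d_N$, the move reduces to the
fraction $C_{\rm adp} A$ of the remaining distance on every axis, so the
standardization affects the reported distance but not the trajectory. After
the shift the logistic parameters are re-derived by the same calibration.
Whether the edges shift by the center's length or are translated rigidly
was open; we translate rigidly (the niche keeps its width). Adaptation is a
species-level property: a lottery win in one cell shifts the species' one
niche (kept per arm), not a per-population copy; at $p_{\rm adp}=0.001$
conflicting wins are rare enough for this to be immaterial.

## Virtual species

Species are built from three empirical-shaped tables: a niche/body-mass
table (mass plus the monthly climate samples the niche is calibrated on), a
trophic table (trophic level, i.e. maximum distance from a basal resource,
and trophic breadth per taxon and mass), and resource-consumer interaction
records. Trophic structure transfers by body-size matching: two masses
match when their relative difference $(\max - \min)/\max$ is below a
threshold that starts at $0.01$ and escalates by $0.01$ until a same-taxon
record matches; the matched record's trophic level and breadth are copied.
Scanning candidates in random order at each escalation and taking the first
hit is equivalent to drawing uniformly among the records admitted at the
first successful threshold, which is how it is implemented.

Functional traits are a random phenotype string of 1–10 lowercase letters.
A 26x26 matrix of letter-pair compatibilities, uniform on $[-1, 1]$, scores
any ordered pair of phenotypes by summing over all ordered letter pairs
(resource letters index rows; the matrix is not symmetric, matching
directed trophic links — an open point we resolved towards directedness).
Raw scores are normalized to $[0,1]$ with constants estimated as the
extremes of $10^6$ random phenotype pairs, and clipped (the constants are
Monte-Carlo estimates, so fresh scores can fall marginally outside).
Adaptive capacity $A$ is uniform on $[0,1]$. After trophic assignment the
taxon tag is retained *only* to look up mass-ratio limits during web
assembly; it never enters niches, extinction rules or reporting.

A species whose trophic breadth reaches down to the plant/invertebrate
level (trophic level 1 by convention) is **basal**: herbivores,
insectivores and omnivores with invertebrate access. Their non-vertebrate
resources are treated as non-depletable, which makes them immune to
bottom-up coextinction but subject to a colonization cap (below).

## Web assembly

For a community, every ordered pair is tested against three rules: (i) the
consumer's trophic level strictly exceeds the resource's and the resource
is within the consumer's trophic breadth; (ii) the resource:consumer mass
ratio lies strictly inside the taxon-pair limits $(l_l, l_u)$, the 5th and
95th percentiles of the ratio distribution in the interaction records
(pairs with fewer than 20 records fall back to the pooled distribution);
(iii) normalized functional compatibility exceeds $c_f = 0.55$. Admitted
links get the weight $1 - (1-c_f)/(1-0.55)$, a linear map sending the
threshold to 0 and perfect compatibility to 1. Non-basal species with no
resource link are dropped, iterating to a fixed point because a dropped
resource can strand its consumers. Connectance uses the squared-richness
denominator $E/n^2$ since no interaction is excluded a priori; the strict
trophic-level inequality incidentally forbids self-links. Diameter is
computed on the undirected projection (longest finite shortest path),
consistent with the use of weakly connected components.

## Coextinctions

With $\mathbf{A}_{ij}$ the weight between resource $i$ and consumer $j$,
each row entry is divided by the row's total consumer pressure and
multiplied by its original value:
$\mathbf{A}'_{ij} = \mathbf{A}_{ij}^2 / \sum_j \mathbf{A}_{ij}$
(e.g. weights 0.5, 0.2, 0.1 on one resource rescale to 0.3125, 0.050,
0.0125). Column sums of $\mathbf{A}'$ are resource availability per
consumer; row sums are consumer pressure per resource. Two thresholds are
taken at assembly and re-taken once when the burn-in ends, then frozen:
$\theta_{\rm consumer}$ is the minimum availability over non-basal nodes
(basal nodes are excluded — their zero vertebrate availability is
legitimate), $\theta_{\rm resource}$ the maximum pressure over consumed
resources. A cascade then iterates to a fixed point: against one snapshot
of $\mathbf{A}'$, mark (a) non-basal consumers strictly below
$\theta_{\rm consumer}$, (b) resources strictly above
$\theta_{\rm resource}$, (c) non-basal species with no directed path from
any basal node; remove all marked simultaneously; repeat. Simultaneous
evaluation makes sweeps order-independent and reproducible; when several
criteria fire together the recorded cause follows the priority bottom-up,
top-down, disconnected. By construction a frozen web with no perturbation
is a fixed point: nothing dies if nothing changes.

**Colonization.** A migrant that passes the climate draw enters the target
web by rebuilding it with the migrant included, under the *frozen resident
thresholds* (thresholds are never recomputed on colonization). A non-basal
migrant with no resource link is rejected; one whose added pressure or
competition violates a threshold triggers the cascade, which may remove
residents and the migrant itself. Basal migrants always find a place, so
their number is capped at the cell's initial basal richness: on overflow,
basal species are removed in decreasing order of combined climatic
extinction probability, ties broken against the most recent arrival
(favouring incumbents, deterministic). In the control arm the same cap
logic is extended to all species at the cell's snapshot richness, and
climate is the only other entry test.

## Land use

The yearly fraction of primary+secondary land lost, $P_{\rm LUC}$,
translates into a diversity-loss fraction through a one-parameter curve
family: with $R_1 = 1-|S_{\rm LUC}|$, the loss is $1-(1-P_{\rm LUC})^{R_1}$
for $S_{\rm LUC}<0$ and $P_{\rm LUC}^{R_1}$ otherwise; $S_{\rm LUC}=0$ (the
default) is the linear response, $1$ means total loss under any
disturbance, $-1$ means invariance. The fractional casualty count is
rounded stochastically (the remainder becomes one extra death with
probability equal to the remainder), avoiding systematic bias in small
communities. Casualties are picked by sorting on decreasing mass and
perturbing the order with $\lfloor V_{\rm LUC} \times S \rfloor$ random
transpositions of the whole list (one global swap budget, not one per
selection): $V_{\rm LUC}=0$ always removes the largest species, 1
approaches random. Land-use casualties are primary extinctions: they feed
the cascade in the coextinction arm and are plain removals in the control
arm.

## Simulation schedule

Seeding assigns each cell $4500 \times u$ species at random ($u$ = fraction
of natural land), filters them to those with combined extinction
probability $< 0.05$ in *every* month of the calibration window, and
assembles the web. A burn-in follows (default 100 steps): each step, every
cell sends one random resident a distance $1 + \mathrm{log}\mathcal{N}(0,1)$
(in cell units; one cell whose rounded grid distance matches the rounded
draw is picked uniformly, and an empty candidate set is a silent failure —
so the shortest draws still reach adjacent cells), accepted iff the
calibration-window filter passes at the target. Webs are rebuilt every 10
steps with the basal cap enforced; at the end, thresholds are recomputed
once and frozen. Both arms then run independently from this snapshot.

Each simulated year applies, in order: twelve monthly climate-mortality
rounds (probability $p$ at that month's conditions is immunity-gated:
$p \le 0.05$ never dies, otherwise death is a Bernoulli draw at $p$ — a
deterministic cutoff would collapse the progressive curve into a step);
the yearly land-use loss; the adaptation lottery; one cascade over all the
year's primary losses (coextinction arm); one dispersal round (the
within-year position of dispersal, and whether it is monthly or yearly, is
not dictated by anything upstream; it is yearly and last, and the ordering
is fixed in code); metrics. The main-run colonization climate test is a
survival draw at the current year's mean conditions.

All randomness flows from one master seed through named child streams
(pool, burn-in, and per-cell mortality, land-use, adaptation and dispersal
streams). Both arms clone the same stream states at the snapshot, so
paired-arm comparisons share their initial draw sequences; each replicate
regenerates its own species pool and trait matrix.

## The synthetic data generator

The fixture generator emulates exactly the structures the algorithms are
sensitive to, with defaults chosen once as a plausible strong-forcing
desk-scale scenario:

* **Climate**: a 5x5 grid; latitudinal gradient 1.5 °C per row, seasonal
  amplitude 8 °C, monthly noise 1 °C, warming 0.8 °C/decade (a
  high-emissions-like trajectory); precipitation analogous (clamped at 0)
  with no trend. The first five years are the calibration window. A
  *stationary* variant tiles the calibration block periodically, so
  "conditions never change" holds literally — this is the equilibrium
  scenario, run with dispersal and adaptation off (no immigration, no
  niche movement), under which zero extinctions is an exact expectation.
* **Niche sources**: each record's samples are the calibration series of a
  3x3-cell home region, not a single cell. A species calibrated on one
  cell would sit exactly at $p = 0.05$ at its own home extremes and fail
  the strict $< 0.05$ filter everywhere; region-wide extremes emulate
  multi-cell ranges and leave the interior strictly tolerable.
* **Traits**: log-normal masses per taxon (means 500, 150, 80, 20 g for
  mammals, reptiles, birds, amphibians; log-sd 1.2); trophic level rising
  stochastically with within-taxon mass rank (reproducing the positive
  mass-trophic level association) and breadth drawn so small low-level
  species are usually basal; interaction mass ratios log-normal with
  taxon-pair-specific log-means.
* **Land use**: geometric decay of $u$ at a per-cell annual rate (0 by
  default; the warming experiments isolate the climate-network pathway).

What the fixtures do *not* emulate: real geography and covariance between
climate variables, phylogenetic signal, empirical interaction sampling
biases, and planetary problem sizes. Passing tests therefore demonstrate
the mechanics and directional behaviour of the model, not its calibrated
global numbers.

## Problem sizes and defaults

The standard configuration (`sim_config()`) carries the full-scale
defaults: 4500 species seeded per fully natural cell, a pool of
5513 mammals, 10425 birds, 10038 reptiles and 7302 amphibians, $10^6$
normalization pairs, 100 burn-in steps, 100 replicates, and an 80-year
horizon. The desk profile (`desk_config()`) keeps every model constant at
its standard value and scales only the problem: 150 species per taxon, 60
seeded per cell, $10^5$ normalization pairs, 20 replicates, 40 years. The
package's tests and worked examples use the desk profile; at these sizes a
full paired 20-replicate experiment runs in minutes on one CPU.

## Numerical choices and degenerate inputs

* Strict inequalities throughout where the rules state them: the mass-ratio
  window, the compatibility threshold, the persistence filter, both
  coextinction thresholds. Nodes sitting exactly at a frozen threshold
  survive — equality is the equilibrium state.
* Webs with no non-basal consumer store $\theta_{\rm consumer} = -\infty$
  (never fires); webs with no consumed resource store
  $\theta_{\rm resource} = +\infty$.
* Degenerate ratio distributions (a single repeated ratio) are widened by
  machine epsilon and flagged.
* Empty cells and empty webs are legal everywhere; metrics report zeros by
  convention.
* The basal-cap and control-cap tie-break removes the most recent arrival.
* `coextinction_effect` is undefined (NA, excluded from averages) when the
  control loss is zero.

## Known limitations

Interaction weights stand in for abundances; there are no partial declines,
no rescue memory (recolonization is just a new dispersal event), and no
rewiring beyond weight recomputation. The taxon tag survives only inside
the mass-ratio lookup. Dispersal distance is Euclidean in cell units
(haversine is a drop-in for geographic grids but not wired to a projection).
The sensitivity harness draws parameter combinations uniformly
(`param_ranges` of `run_experiment()`); analysing those outputs with a
regression emulator is out of scope.

## A minimal run

```{r}
library(coexsim)

set.seed(20)
climate <- make_climate()                    # warming 5x5 fixture
landuse <- make_landuse()                    # constant natural land
tables  <- make_trait_tables(climate)

ex <- run_experiment(climate, landuse, tables,
                     config = desk_config(replicates = 5),
                     master_seed = 20)

aggregate(mean_loss ~ arm, ex$summary, mean)
ex$effect                                    # per-replicate amplification
write_outputs(ex, "results/run1")
```
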