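---
title: "An individual-based eco-evolutionary model of plant range dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based eco-evolutionary model of plant range dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ecoevorange` simulates how long-lived plants distributed over a gridded
landscape respond to shifting climate when demography, dispersal and the
evolution of quantitative traits all operate at once. This vignette is
the package's account of the model itself: its assumptions, its tunable
parameters, the choices made where the design was genuinely open, and
what the synthetic test bed does and does not demonstrate.

## The model

### Genetic architecture

An individual's phenotype consists of three quantitative traits, one per
environmental variable (mean annual temperature, annual precipitation,
percent carbonate bedrock). All three traits are controlled by the same
`L = 10` unlinked, purely additive diploid loci; every allele carries one
real-valued effect per trait (pleiotropy). Mutation follows the
continuum-of-alleles model: each of the `2L` alleles mutates
independently with probability `mu` per genome-copying event, drawing a
three-dimensional Gaussian deviate (mean zero, variance `v = 0.05` per
trait, no correlation between traits) that is *added* to the allele's
existing effects. The per-trait mutational variance entering a patch each
generation is therefore `2 L mu v`, independent of current trait values.
Mutation counts are Bernoulli per allele rather than Poisson per genome,
matching the definition of `mu` as a per-allele rate. There is no
linkage, dominance, epistasis or mutational correlation.

The genotypic value of a trait is the sum of the `2L` allelic effects;
the phenotype adds an environmental deviate, independent per trait and
individual, with variance `V_E,k`. `V_E` is calibrated *once*, at
initialisation, from the realised within-patch genetic variance of the
founders so that mean narrow-sense heritability is `h2 = 0.3`
(`V_E = V_G (1 - h2) / h2`); it is then held fixed, and heritability is
emergent thereafter as the genetic variance evolves.

### Life cycle

Four stages: seeds, seedlings, pre-reproductive adults, adults. Each
simulated year executes, in fixed order: (1) mating and seed production —
every adult mothers a Poisson(`fecundity`) brood, each seed's father
drawn uniformly from the adults of the same cell, selfing permitted
(individuals are hermaphroditic and no selfing rule is imposed); (2) seed
dispersal — a seed leaves its natal cell with probability
`disperse_frac` and travels a negative-exponential distance in a uniform
direction, seeds crossing the grid edge being lost; (3) aging — adults
and pre-adults survive with probability `s_a`, pre-adults mature for two
years before adulthood, and last year's surviving seedlings become
pre-adults; (4) germination and seedbank survival — every banked seed,
including the current year's cohort, germinates with probability
`germination`, non-germinating seeds survive with probability
`seed_survival` and age, and seeds older than `max_seed_age` are
discarded; (5) clonal reproduction — adults and pre-adults each produce
Poisson(`clonal_rate`) seedlings carrying a (mutated) copy of the parent
genome; (6) seedling competition — each seedling survives the
established plants of its cell with Beverton-Holt probability
`1 / (1 + k_c N)`; (7) viability selection on seedlings — survival
`exp(-1/2 sum_k (z_k - theta_k)^2 / V_s_k)`, a multivariate Gaussian
fitness surface with diagonal selection matrix, the optimum
`theta` being the cell's current environment. The census — stage counts,
trait means and variances, mean seedling survival — is taken between
competition and selection, so the recorded adaptive seedling survival
reflects selection alone, not competition.

Decisions where the design was open:

* *Pre-adult survival* is not separately specified anywhere we could
  anchor it; pre-adults survive at the adult rate `s_a`.
* *Competitors* in the Beverton-Holt term are adults plus pre-adults
  (both are established and both reproduce clonally); a documented
  switch (`competition_pool = "adults"`) restricts it to adults.
* *Clonal copies pass through mutation*: mutation is attached to every
  genome-copying event, sexual or clonal.
* *Seed timing*: the new cohort joins the bank before its production
  year's germination event, so a species with `max_seed_age = M` gives
  each seed germination chances at ages 0..M — the oldest banked seed
  ever observable is exactly M (7 years for the Primula-like preset),
  and an M = 1 species carries seeds across at most one year boundary.
* *Burn-in "generations" are years*: the model is an annual cycle, and
  the burn-in length is expressed in simulated years (configurable).

### Density regulation and the carrying capacity

The competitive weight `k_c` is not a free parameter: it is calibrated by
root-finding so that the deterministic mean-field stage recursion of a
single, isolated, perfectly adapted patch has its adult fixed point at
the species' nominal capacity `K_max` (1,000 / 300 / 500 / 5,000 adults
for the four presets). The same recursion provides two oracles used in
the tests: its fixed point, and the stage projection matrix evaluated at
the equilibrium competition survival, whose leading eigenvalue is 1 and
whose leading eigenvector is the stable stage structure. Populations in
full simulations sit below `K_max` because of migration and mutation
load.

### Selection scale: niche-width units

The selection variances `V_s,k` are anchored to the niche width
`V_SENM,k` — the variance of environmental variable `k` across the cells
the static niche model predicts occupied — treated as the weakest
plausible stabilising selection, with multipliers 1, 0.5 and 0.33 for
the standard sensitivity grid.

Traits, optima and selection all live on *niche-width units*: each
environmental variable is centred and scaled by its mean and standard
deviation over the predicted-occupied cells of the grid, so
`V_SENM = 1` per trait by construction and the multiplier acts directly
as the selection variance. This choice is load-bearing. The mutational
variance `v = 0.05` and the heritability-calibrated `V_E` are fixed
numbers on the trait scale; had we standardised by the whole landscape's
spread instead, any species occupying a minority of a steep gradient
would face `V_E / V_s >> 1` — so much environmental noise relative to
the fitness surface's width that even a perfectly adapted population
could not recruit (we observed exactly this collapse on the synthetic
landscape). Scaling by the occupied cells keeps `v`, `V_E` and `V_s`
mutually commensurate in the way the niche-width anchoring presumes, and
makes the multipliers comparable across variables. Raw units are used
for all input and output rasters. Degenerate cases are handled
explicitly: a variable with zero spread over the occupied cells falls
back to the landscape scale with a warning, and a grid with fewer than
two occupied cells (single-patch calibration rigs) uses the multiplier
directly on the landscape scale.

### Initialisation, burn-in and scenarios

Founders are placed as adults in every predicted-occupied cell with
genotypic values equal to their cell's optimum (every allele set to
`optimum / 2L`), then standing variation is created by jittering every
allelic effect by `N(0, v)` — populations start locally adapted with
large genetic and environmental variation, and the burn-in equilibrates
them. The burn-in freezes the optima at their initial values and adds a
ceiling-regulation event after selection: capacity 0 outside the
predicted range (preventing geographic expansion) and a large ceiling
inside (preventing demographic explosion during the initial growth
phase; ranges on static gradients can otherwise grow without bound).
Burn-in diagnostics report the trend in adults and genetic variance over
the final 10% of years; global extinction is signalled as an error with
the series attached.

The scenario phase simulates calendar years 2000–2150 with optima
interpolated linearly between decadal climate anchors (2010–2090), held
constant before 2010 and after 2090. Census records are emitted every 10
years. Replicates restart from one shared burn-in population, each with
its own stream drawn from the master seed; a run is fully deterministic
given (seed, configuration). The no-evolution baseline
(`single_genotype = TRUE`) gives every individual the grid-average
genotype of the occupied cells, disables mutation, and calibrates `V_E`
from the nominal initial genetic variance `2 L v` so both modes face
comparable environmental noise; the genotype disperses but cannot
evolve.

### Static-niche-model post-processing

Fitting the correlative models themselves is out of scope; the package
consumes per-model occurrence-probability maps plus truth labels. It
implements the True Skill Statistic, TSS-weighted ensemble averaging
with raw-TSS weights (models below TSS 0.3 discarded), the
TSS-maximising presence threshold (exhaustive scan over distinct
predicted values, ties resolved to the lowest threshold so the most
inclusive of the equally skilled masks is chosen), the niche summary
(`V_SENM`, mean environment) and the grid-average genotype. Suitability
through time — used by the suitability-class recorder and the static
occupancy series — comes from a logistic response in width-scaled
distance from the niche centre applied to the interpolated climate, a
documented stand-in for externally projected niche-model output; after
2090 the 2090 surface is reused.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `L` | 10 | loci | architecture of each trait |
| `mu` | 0.001 | per allele per generation | sensitivity grid 0.01 / 0.001 / 0.0001 |
| `v` | 0.05 | trait-units² | mutational effect variance per trait |
| `h2_target` | 0.3 | — | heritability realised at initialisation |
| `s_a` | 0.9 | per year | adult (and pre-adult) survival; grid 0.7 / 0.8 / 0.9, life expectancies 3.3–10 yr |
| `vs_multiplier` | 1 | × `V_SENM` | selection strength; grid 1 / 0.5 / 0.33 |
| `K_max` | preset | adults | nominal single-patch capacity; fixes `k_c` |
| `ceiling_K` | 8,000 (presets) | individuals | burn-in ceiling, above equilibrium |
| `fecundity`, `germination`, `seed_survival`, `clonal_rate`, `max_seed_age` | preset | — | life-history contrasts of the four presets |
| `disperse_frac`, `disperse_mean` | preset | —, m | emigration probability and kernel mean |

The four species presets encode the intended qualitative contrasts — a
high-capacity producer of many dispersive seeds (`campanula`), a clonal
poor disperser with a 5-year seedbank (`dianthus`), a well-germinating
subdominant with a 7-year seedbank (`primula`), and an abundant,
poorly germinating dominant (`festuca`) — with fecundities, germination
and dispersal values that are *synthetic defaults*, chosen once so each
preset reaches its capacity and expresses its contrast; they stand in
for unavailable demographic estimates and are all configurable.

## The synthetic test bed

`fixture_spec()` emulates a 32 × 32-cell grid of 250-m cells (64 km²) on
a montane-alpine elevation ramp (800–2,000 m by default): temperature
follows a 6 °C/km lapse rate with small local noise, precipitation rises
with elevation, carbonate bedrock forms thresholded smooth patches, and
warming scenarios add 1.4 / 2.6 / 4.0 °C between 2010 and 2090 in
uniform decadal steps (mild / moderate / severe), with slight
precipitation declines. The synthetic species' niche is centred at 60%
of the ramp on carbonate, so warming displaces the suitable zone upslope
into finite terrain. Pseudo-niche-models distort the truth probability
on the logit scale with per-model shrinkage and noise, spanning TSS from
~0.9 down to a deliberately skill-free model that the 0.3 discard rule
removes.

What the fixtures do *not* emulate: realistic topography, spatially
autocorrelated weather, temporally varying interannual noise, real
dispersal kernels, or observational error in the presence data. Passing
tests therefore demonstrate the *mechanisms* — colonisation credit,
extinction debt, maladaptation accumulating under forcing and releasing
after stabilisation, age-structure shifts, the cost of a single global
genotype — not calibrated forecasts for any real species.

The default desk-scale study (the "micro-study") uses a 16 × 16 grid,
the small fast `synthetic` preset (capacity 300, ceiling 2,400), a
200-year burn-in and 3 scenario replicates; these sizes are the
package's default compromise between stochastic stability of the
recorded statistics and the few minutes of runtime appropriate for an
example, and every one of them scales up by configuration (the presets
retain the full capacities and the 8,000 ceiling).

## Numerical choices and degenerate inputs

* All stochasticity runs through R's RNG; replicate seeds are drawn from
  the master seed and logged in the run manifest.
* The threshold scan uses observed predicted values as candidates; ties
  break to the lowest threshold. All-equal predictions, single-class
  truth, empty confusion margins, empty grids, fewer than two occupied
  cells, zero phenotypic variance and nonpositive selection variances
  are errors, not silent results.
* `calibrate_kc()` brackets `log(k_c)` in [−20.7, 6.9] and requires the
  zero-density growth rate to exceed 1, otherwise the life history is
  signalled as infeasible.
* Ceiling regulation retains a uniform random subset without
  replacement, so it is genotype-blind by construction.
* The burn-in aborts with diagnostics on global extinction and on a
  patch exceeding 10× the ceiling (an invariant violation, not a
  tunable).
* Population snapshots serialise to plain-text tables (one row per
  allele); a save–load–save round trip is byte-identical.

## Known limitations

Selection acts on seedling survival only — selection on adult fecundity
or survival, truncation selection, and correlated selection
(non-diagonal fitness surfaces) are not implemented. Pollen moves only
within cells; between-grid migration is disallowed. The environmental
variables are treated as independent both genetically (no mutational
correlations) and selectively, which real bioclimatic variables are not.
The static-model layer reproduces the *logic* of ensemble
post-processing, not any particular fitting stack's numerics. And the
stochastic engine is pure R: practical grid sizes are thousands of
cells, not millions.
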