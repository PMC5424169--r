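# ecoevorange

Individual-based, genetically and spatially explicit simulation of
perennial plant range dynamics under climate change.

Correlative species distribution models treat a species' climatic envelope
as fixed: when the climate shifts, predicted ranges contract instantly and
nothing can adapt. Long-lived mountain plants violate both assumptions —
established adults persist for decades in deteriorating sites while
selection acts on their seedlings. `ecoevorange` is a forward-in-time,
stochastic simulator for exactly this situation: local populations on a
gridded landscape adapt to their local conditions through the evolution of
quantitative traits, while birth, death, dispersal and density regulation
play out individual by individual. It is aimed at population and
evolutionary ecologists who want to ask how demography and evolution
reshape range forecasts that a static niche model would make, and at
methodological work on eco-evolutionary forecasting itself.

## The model

Each individual carries three quantitative traits, one per environmental
variable (mean annual temperature, annual precipitation, % carbonate
bedrock). Every trait is controlled by the same *L* = 10 unlinked,
additive, diploid loci with pleiotropic effects. A mutation occurs at each
allele with probability *μ* per generation and adds a three-dimensional
Gaussian deviate — mean zero, variance *v* = 0.05 per trait, no
correlation — to the allele's existing effects (continuum-of-alleles), so
the mutational variance input per patch and generation is 2*Lμv*. The
phenotype is the genotypic value (sum over all 2*L* alleles) plus an
environmental deviate with variance *V*<sub>E,k</sub>, calibrated once at
initialisation so that mean heritability is *h*² ≈ 0.3.

The yearly life cycle per 250-m grid cell runs: mating and seed production
(Poisson fecundity, uniform mate choice with selfing), seed dispersal
(negative-exponential kernel, absorbing grid boundary), aging of adults
and pre-adults (annual survival *s*<sub>a</sub>; two pre-adult years
before maturity), germination and seedbank survival (species-specific
longevities of 1–7 years), clonal reproduction, then density-dependent
seedling competition against the established plants of the cell,

> p = 1 / (1 + *k*<sub>c</sub> · *N*<sub>established</sub>),

and finally Gaussian viability selection on seedlings,

> w(**z**) = exp( −½ Σ<sub>k</sub> (z<sub>k</sub> − θ<sub>i,t,k</sub>)² / *V*<sub>s,k</sub> ),

where **θ**<sub>i,t</sub> is the cell's environmental optimum in year *t*
and *V*<sub>s,k</sub> the selection variance, anchored to the niche width
*V*<sub>SENM</sub> (the variance of each environmental variable across the
cells a static niche model predicts occupied). The competitive weight
*k*<sub>c</sub> is calibrated by root-finding on the deterministic stage
recursion so a perfectly adapted single patch equilibrates at the species'
nominal adult capacity. Census happens after competition and before
selection.

A static-niche-model post-processing layer supplies the simulator's
inputs: per-model suitability maps are combined by TSS-weighted averaging
(models with TSS < 0.3 discarded), thresholded at the TSS-maximising
presence cut-off, and summarised into the niche width and the presence
mask used to seed founders and the burn-in ceiling (capacity 0 outside the
predicted range, a large ceiling inside). Simulations run a burn-in to
mutation–selection–migration equilibrium, then a 2000–2150 scenario phase
driven by decadal climate anchors (2010–2090, constant afterwards). A
no-evolution baseline assigns every individual the single grid-average
genotype with mutation disabled.

Everything is testable offline: a fixture module generates alpine-like
elevation-ramp landscapes, RCP-like warming scenarios of graded severity,
and pseudo-niche-model predictions with controlled skill.

## Worked example

```r
library(ecoevorange)

species_preset("campanula")
#> Species preset 'campanula'
#>   s_a = 0.90, fecundity = 40, germination = 0.30, clonal = 0.05
#>   seedbank: survival 0.30, max seed age 1 yr
#>   K_max = 1000 adults (k_c = 0.0949), burn-in ceiling = 8000
#>   dispersal: 12% of seeds move, mean distance 80 m

# full pipeline on a synthetic 16 x 16 grid: pseudo-model ensemble,
# presence threshold, niche width, burn-in, severe warming, 3 replicates
res <- run_micro_study(seed = 1, replicates = 3, burn_in_years = 200,
                       severity = "severe")
round(res$senm$model_tss, 3)
#> [1] 0.875 0.868 0.791 0.082      # the skill-free model is discarded
sum(res$senm$mask)
#> [1] 127                          # predicted-occupied cells

occ  <- rowMeans(sapply(res$records,
                        function(r) occupancy_change(r)$occupancy_change))
surv <- rowMeans(sapply(res$records,
                        function(r) adaptive_seedling_survival(r)$adaptive_survival))
data.frame(year = seq(2000, 2150, 10), occupancy_change = round(occ, 3),
           adaptive_survival = round(surv, 3))
#>  year occupancy_change adaptive_survival
#>  2000           -0.032             0.128
#>  2010            0.000             0.127
#>  2020            0.053             0.121
#>  2040            0.092             0.098
#>  2060            0.132             0.064
#>  2080            0.159             0.041
#>  2090            0.136             0.030
#>  2110            0.009             0.047
#>  2130           -0.099             0.065
#>  2150           -0.120             0.079
```

Read: occupancy (cells holding at least one established plant, relative
to 2010) first *rises* — dispersal colonises newly suitable cells — then
declines and keeps declining after the climate stabilises in 2090: an
extinction debt. Mean seedling survival against the local optimum drops
four-fold during warming and rebounds after stabilisation as adaptation
catches up. A static niche model run on the same scenario contracts its
presence mask immediately (`senm_occupancy()`), with no transient
expansion and no rebound.

The command-line tool exposes the same pipeline
(`exec/ecoevorange fixtures|burnin|run|sweep|stats`, YAML-configured; see
`inst/extdata/microstudy.yaml`).

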