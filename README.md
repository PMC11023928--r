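# camtrappair

Paired camera-trap analysis of forest-mammal communities: does certified
forest management (for example an FSC certificate, which obliges
concession holders to control hunting) leave more wildlife in a logging
concession than conventional management?

The credible way to ask that question is a *paired* design: each certified
concession is matched to a nearby non-certified concession with similar
terrain, both are surveyed simultaneously with systematic camera-trap
grids, and the pair structure is carried through every inferential step.
`camtrappair` implements the complete analysis for such surveys, and ships
a hierarchical synthetic-data generator so the whole pipeline is testable
and demonstrable without any field data.

## What it computes

Starting from photo-level annotation tables (camera, timestamp, species,
individual count), deployment metadata and a species-trait table:

1. **Independent detection events** — photos of one species at one camera
   chain into one event while consecutive photos are < 10 min apart
   (configurable; a gap of at least the threshold separates events). The
   event's group size is the maximum per-photo count.
2. **Sampling effort** — active camera-days: deployment span bounded by
   the last (12-hourly status) photo, minus reported downtime.
3. **Encounter rates** — group-size-weighted observations per camera-trap
   day:  r = Σ group sizes / effort, reported for all species pooled, per
   species, per body-mass class ((0,1], (1,10], (10,30], (30,100],
   (100,∞) kg), per IUCN category and per taxonomic group, plus a relative
   biomass index Σ rateₛ × massₛ.
4. **Inference** — nested linear mixed models on camera-level rates,

       rate ~ status (* group) + (1 | pair) + (1 | concession) + (1 | camera),

   REML estimates with ML refits for BIC covariate selection; FSC:non-FSC
   ratios of marginal means with delta-method errors; pairwise contrasts
   adjusted by the multivariate-t max-|T| distribution (seeded
   quasi-Monte-Carlo); containment degrees of freedom (n_pairs − 1).
5. **Paired tests and checks** — exact Wilcoxon signed-rank tests
   (full-enumeration p-values, tie- and zero-safe) for hunting signs and
   biomass; an event-count sensitivity table over thresholds of
   10/30/60/1440 min; and a habituation regression of log daily detections
   on deployment day × status over the first 68 days.

## Worked example

Simulate a default survey (7 concession pairs, 28–36 cameras each, 80-day
deployments, a 28-species heavy-tailed community whose certification
effect grows with body mass) and run the full analysis:

```r
library(camtrappair)

sim <- simulate_dataset(default_community(), sim_design(seed = 1))
res <- run_pipeline(sim$photos, sim$deployments, sim$traits,
                    run_config(seed = 1))
res
#> Paired camera-trap analysis (config 1c204e3e)
#>   86861 independent detections from 446 cameras; 34639 camera-days of effort
#>   FSC:non-FSC ratios (all): all = 1.9
#>   FSC:non-FSC ratios (body_mass_class): 0-1 kg = 1.1, 1-10 kg = 1, 10-30 kg = 3.6, 30-100 kg = 2.7, >100 kg = 2.6
#>   FSC:non-FSC ratios (iucn): CR = 2.6, EN = 2.4, LC = 1.5, NT = 3.4, VU = 3.2
#>   FSC:non-FSC ratios (taxon): carnivores = 1.2, elephants = 2.6, pangolins = 1.1, primates = 2.4, rodents = 1, ungulates = 2.5
#>   hunting-sign test p = 0.0156 | biomass test p = 0.0156
```

The per-class contrast table shows the pattern the design is built to
detect — a strong certification effect above 10 kg, none below it
(generator truth: multipliers 1, 1, 3.5, 2.5, 2.7 from light to heavy):

```r
res$ratios$body_mass_class[, c("group", "mean_nonfsc", "mean_fsc",
                               "ratio", "p.adjusted")]
#>       group mean_nonfsc mean_fsc ratio p.adjusted
#> 1    0-1 kg       0.575    0.605  1.05   0.957462
#> 2   1-10 kg       0.855    0.887  1.04   0.942961
#> 3  10-30 kg       0.464    1.689  3.64   0.000017
#> 4 30-100 kg       0.277    0.742  2.68   0.005956
#> 5   >100 kg       0.190    0.503  2.65   0.033490
```

Means are encounter rates (observations per camera-trap day); `ratio` is
the FSC:non-FSC ratio of model-estimated marginal means; `p.adjusted` is
the multivariate-t adjusted p-value of the per-class contrast. The
hunting-sign p of 0.0156 is the exact two-sided Wilcoxon floor for seven
pairs that all move the same way (2/2⁷).

`autoplot(res, "body_mass_class")` draws the paired boxplots with the
model means overlaid; `autoplot(res$ratios$taxon)` gives a forest-style
ratio plot. `write_results(res, "out/")` writes every table of record as
CSV (each stamped with the configuration hash) plus a JSON summary.

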