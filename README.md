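# seedasm

Community-assembly analysis for the bacterial microbiota of **individual
seeds**. Single seeds host tiny bacterial communities — a few amplicon
sequence variants (ASVs), usually one dominant taxon of variable identity,
and frequent non-detection. `seedasm` asks which ecological processes
assemble those communities, from three angles:

* **Neutral immigration/replacement model.** Each seed is a Moran-type
  community of size *N<sub>c</sub>*: a dying resident is replaced by an
  immigrant from an *S*-species pool (probability μ) or by a local
  offspring (probability (1−μ)C). The stationary composition is
  Dirichlet-multinomial with concentration θ<sub>c</sub> = R (N<sub>c</sub> − 1),
  where R = μ/((1−μ)C) is the only identifiable dispersal parameter; a
  single taxon's abundance is beta-binomial. The package fits *S*, *R*, and
  the dispersal index I<sub>c</sub> = R/(N<sub>c</sub> − 1) per plant and
  date by generalized moment estimation on the first three moments of
  species proportions, with the error criterion J reported. An exact
  stationary-distribution oracle (`moran_stationary_exact()`) validates the
  closed form to 10⁻¹⁰ in the test suite.
* **Phylogenetic turnover null models.** Abundance-weighted βMNTD between
  plant-level communities, standardized into βNTI by shuffling ASV
  positions across the reference tree (999 nulls, seeded); an
  abundance-based Raup–Crick index on Bray–Curtis dissimilarity; and the
  quantitative process estimates (QPE) rule classifying each community pair
  as homogeneous/variable selection, dispersal limitation, homogenizing
  dispersal, or drift (|βNTI| > 2, |RC| > 0.95 thresholds, all
  configurable).
* **Descriptive statistics.** Rank-abundance and dominance profiles,
  richness, Faith phylogenetic diversity, detection rates, seed→seedling
  transmission (ASV overlap and dominance transmission), and source-habitat
  attribution.

A first-class synthetic-study generator (`simulate_study()`) emulates the
single-seed survey design — 5 plants, tens of seeds per plant across
developmental stages, partial detection, sequencing-depth resampling, with
neutral / drift / selection scenarios and full ground truth — so every
estimator in the pipeline is testable offline.

## Worked example

```r
library(seedasm)

# a synthetic study under the neutral scenario
cfg <- scenario_config("neutral", n_plants = 3, seeds_per_plant = 30,
                       stage_days = c(26, 65), rng_seed = 11)
study <- apply_observation_model(simulate_study(cfg))
study
#> <synthetic_study> scenario 'neutral': 180 samples, 44 ASVs, 100-tip tree

# neutral fit per plant and stage
fits <- fit_neutral_by_group(study$table, study$metadata)
print(fits[, c("plant_id", "stage_day", "S_hat", "R_hat", "I_hat", "n_seeds")],
      digits = 3)
#>   plant_id stage_day S_hat   R_hat    I_hat n_seeds
#> 1      P01        26    20 0.02082 5.21e-06      14
#> 2      P02        26    20 0.01760 4.40e-06      14
#> 3      P03        26    20 0.01577 3.94e-06      17
#> 4      P01        65    20 0.01053 2.63e-06      17
#> 5      P02        65    20 0.01319 3.30e-06      16
#> 6      P03        65    20 0.00821 2.05e-06      19

# assembly processes at the plant level
qq <- qpe(study$table, study$metadata, study$tree, n_null = 199, rng_seed = 1)
subset(qq$summary, fraction > 0)
#>           group              process  fraction
#> 5  synthetic|26 dispersal limitation 0.6666667
#> 6  synthetic|65 dispersal limitation 0.6666667
#> 9  synthetic|26                drift 0.3333333
#> 10 synthetic|65                drift 0.3333333
```

Reading the output: every fitted pool size Ŝ recovers the generator's
S = 20 exactly (the first moment of mean proportions pins 1/S). The fitted
ratio R̂ is expressed per observed community size — here every detected
seed was resampled to 4,000 reads, so θ̂ = R̂·3999 ≈ 30–80 is the identified
concentration, matching the generator's θ = 0.05·(N<sub>c</sub>−1) for
N<sub>c</sub> ∈ [500, 2000]. The small dispersal index I places these
communities in the replacement-dominated regime (local processes outweigh
immigration). The QPE panel labels most plant pairs dispersal limitation —
the generator gives plants largely disjoint species pools (20% overlap) —
and the rest drift, with no spurious selection signal on neutral data.

The per-sample view (`dominance_profile()`, `detection_summary()`,
`transmission_report()`) and the full orchestration (`run_pipeline()`,
which writes per-stage TSV/JSON outputs plus a manifest and is
byte-reproducible under a fixed seed) are documented in the vignette
(`vignettes/seed-microbiota-assembly.Rmd`), along with the model
assumptions, tunable parameters, and known limitations. A thin CLI wrapper
lives at `inst/scripts/seedasm.R` (`simulate` and `run` subcommands).

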