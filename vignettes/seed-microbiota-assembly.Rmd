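---
title: "Community assembly of single-seed microbiota: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community assembly of single-seed microbiota: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedasm)
```

## The scientific setting

Individual seeds carry very small bacterial communities: a handful of
amplicon sequence variants (ASVs), usually with a single dominant taxon whose
identity varies from seed to seed and from plant to plant, and a substantial
fraction of seeds in which no bacteria are detected at all. `seedasm`
provides the statistical machinery to ask, from single-seed count tables, a
metadata table and a reference phylogeny, *which ecological processes put
those communities together*: immigration from a local species pool,
neutral replacement and drift inside the seed, or selection.

Three complementary instruments are implemented:

1. a **neutral immigration/replacement model** fitted to species-proportion
   distributions by generalized moment estimation (`fit_neutral_gmm()`),
2. **phylogenetic turnover null models** — betaMNTD, betaNTI, the
   abundance-based Raup–Crick index and the quantitative process estimates
   (QPE) classification (`bnti()`, `raup_crick_bray()`, `qpe()`),
3. **descriptive statistics** of dominance, richness, detection and
   seed-to-seedling transmission (`dominance_profile()`,
   `transmission_report()`, ...).

A synthetic-study generator (`simulate_study()`) emulates the sampling
design these analyses assume, so every estimator can be scored against
ground truth without any external data.

## The neutral model

Each seed is modeled as a community of fixed size $N_c$ individuals drawn
from a pool of $S$ equivalent species. Per event, a uniformly chosen
resident dies and is replaced by an immigrant (a uniform pool species) with
probability $\mu$, by the offspring of a uniformly chosen surviving resident
with probability $(1-\mu)C$, and by its own kind otherwise. Only the
composite **replacement ratio**

$$R = \frac{\mu}{(1-\mu)\,C}$$

is identifiable from stationary composition data. Detailed balance of this
chain gives a Dirichlet-multinomial stationary composition with symmetric
concentration

$$\theta_c = R\,(N_c - 1),$$

so a single taxon's abundance is beta-binomial with shapes
$\alpha = \theta_c/S$ and $\beta = \theta_c (S-1)/S$. This is not taken on
faith: `moran_stationary_exact()` builds the full transition matrix on small
state spaces and the test suite checks the closed form against it to
$10^{-10}$:

```{r moran}
res <- moran_stationary_exact(N = 6, S = 3, mu = 0.3, C = 0.6)
lc <- local_concentration(R = 0.3 / (0.7 * 0.6), N = 6, S = 3)
max(abs(res$marginal - bb_pmf(0:6, 6, lc$alpha, lc$beta)))
```

Small $\theta$ means monodominance (one resident lineage takes over between
rare immigration events); large $\theta$ means even communities near $1/S$.
The per-seed **dispersal index** $I_c = R/(N_c-1)$ compares per-capita
immigration with per-capita replacement: large $I$ means dispersal dominates
seed-internal processes. (The package reads the ratio this way for
consistency with $R$ being a ratio itself; the product convention
$I_c = R\,(N_c-1)$ is available via `i_convention = "dispersalnumber"`,
and both are monotone in $R$, so cross-stage comparisons are unaffected.)

### Moment fitting

For one plant at one date, per-seed proportions are computed relative to
each seed's **unfiltered** read total, keeping the pool size identifiable
above the observed richness; ASVs are kept when they carry strictly more
than 0.1% of the group's total abundance (`filter_by_total_abundance()`,
threshold configurable). The across-seed mean proportion of each retained
ASV is formed and its first three raw moments taken across ASVs
(`empirical_mean_moments()`).

On the model side, $N$ is taken uniform on $[N_{\min}, N_{\max}]$, the 0.1
and 0.9 quantiles (type-7, rounded, floored at 2) of the per-seed totals
(`estimate_n_range()`). Read totals are used as the size proxy by default;
a per-seed richness option exists because "community size" is genuinely
ambiguous for censored count data. Closed-form beta-binomial factorial
moments are mixed over that range and propagated to moments of the mean of
$M$ seeds (`mixed_mean_moments()`). The fit minimizes the scale-free
criterion

$$J(S, R) = \sum_{k=1}^{3} \frac{(\hat m_k - T_k(S,R))^2}{\hat m_k^2}$$

over $\log S \in [\log 2, \log 10^6]$, $\log R \in [-14, 7]$ — a 25×25
log-grid scan refined by Nelder–Mead from the three best grid points.
Relative weights are used because the three moments differ by orders of
magnitude; no asymptotically optimal weighting matrix is attempted, since
the moment count barely exceeds the parameter count. $S$ is optimized as a
real number and reported unrounded. Seeds with no retained counts are
excluded from $M$: the model describes colonized seeds, and non-detection
is summarized separately (`detection_summary()`).

Two interpretation switches are exposed rather than decided silently:
`moment_mode = "pooled"` uses per-(ASV, seed) proportions instead of
across-seed means, and is the informative choice for strictly monodominant
data (where the across-seed-mean moments degenerate); the default `"mean"`
follows the plant-level reading of the analysis.

### What recovery looks like

With the generator's study conditions ($S = 20$, $R = 0.05$,
$N \in [500, 2000]$, 50 colonized seeds), the median fitted pool size over
20 replicates sits within a fraction of a percent of the truth and the
fitted ratio within a few percent (see `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`). Two structural facts are worth knowing:

* the error of $\hat S$ shrinks rapidly with the number of seeds $M$;
* when all seeds are sequenced to one fixed depth, the per-seed read total
  is that depth, not the biological community size: the fitted concentration
  $\hat\theta = \hat R\,(N-1)$ is then the identified quantity, and $\hat R$
  rescales with whatever size proxy is used. Comparisons of $\hat R$ or
  $\hat I$ are meaningful across groups measured the same way;
* the *spread* of $\log \hat R$ does not shrink with $M$: $\hat R$ is
  identified through the across-ASV variance of mean proportions, whose
  relative sampling error is roughly $\sqrt{2/A}$ for $A$ retained ASVs
  regardless of how many seeds are averaged. More seeds debias $\hat R$;
  only more taxa tighten it. Comparisons of fitted indices across stages
  should therefore lean on medians over plants, as the fitted values for a
  single plant carry an irreducible factor-of-order-one uncertainty.

## Phylogenetic null models

Communities are first aggregated at the plant level
(`aggregate_by_plant()`): within-plant seed-to-seed variation is the
neutral model's subject, while the null models ask whether *plants* host
phylogenetically structured communities.

`bmntd()` computes the abundance-weighted mean nearest-taxon distance
between two communities,

$$\beta\mathrm{MNTD} = \tfrac12\Big(\sum_i f_i \min_j d_{ij} +
  \sum_j g_j \min_i d_{ij}\Big),$$

with $d$ the cophenetic matrix of the reference tree and $f, g$ relative
abundances (an incidence-weighted mode is available). `bnti()` standardizes
the observed value against a null in which the observed ASVs are reassigned
to tip positions drawn from the whole reference tree, one reassignment per
replicate applied to all pairs (999 replicates by convention; seeded).

The tip set of the shuffle matters and the package is deliberate about it:
permuting positions only *within the set of observed ASVs* cannot detect
clustering that all communities share — if every community sits in one
clade, the union is that clade and the null is the observation. The default
therefore shuffles across all tips of the supplied tree, which is what the
index exists to measure; the union-only variant is kept as
`null_tips = "union"` for sensitivity analysis. Consequently the reference
tree should represent the plausible regional pool, not merely the observed
taxa.

`raup_crick_bray()` complements betaNTI with a taxon-identity (rather than
phylogeny) null: null communities preserving each community's richness and
total abundance are assembled by occurrence-weighted taxon draws and
abundance-weighted individual placement, and the observed Bray–Curtis value
is rank-rescaled to $[-1, 1]$ (ties counted half, making the score
symmetric around zero). `qpe_classify()` then applies the standard decision
rule — betaNTI below $-2$: homogeneous selection; above $+2$: variable
selection; otherwise Raup–Crick beyond $\pm 0.95$: dispersal limitation or
homogenizing dispersal; else drift — and `qpe_summarize()` reports per-group
fractions. All thresholds are arguments, not constants.

Calibration is tested, not assumed: under data generated by the null's own
mechanism, betaNTI has mean near 0, standard deviation near 1, and
$|\beta\mathrm{NTI}| > 2$ fires at close to its nominal 5% rate.

## The synthetic-study generator

`scenario_config()` fixes the study conditions; the defaults emulate the
single-seed survey design the analyses target, and were chosen once, on
design grounds:

| parameter | default | reading |
|---|---|---|
| `n_plants` | 5 | plants sampled per species in the emulated design |
| `seeds_per_plant` | 32 | seeds per plant and stage (~96 per plant over 3 stages) |
| `stage_days` | 26, 37, 65 | seed filling to maturity |
| `S` | 20 | plant-level pool size (well above per-seed richness medians of 3–9) |
| `R` | 0.05 | replacement-dominated regime (dispersal less important than local processes) |
| `N_range` | 500–2000 | small per-seed bacterial population sizes |
| `q` | 0.6 | per-seed detection probability, inside the observed 30–84% per-stage range |
| `depth` | 4000 | reads per detected seed, the rarefaction convention |
| `theta_drift` | 0.3 | monodominance regime for the drift scenario |
| `pool_overlap` | 0.2 | shared fraction of plant pools — strong plant-to-plant variation |

Scenarios: **neutral** draws each seed from the Dirichlet-multinomial with
$\theta_c = R(N_c-1)$; **drift** fixes $\theta_c \le 0.5$, reproducing the
observed dominance regime (mean rank-1 share above 70%, median richness
below 10) *through* the model family rather than by hard-coding a rank-1
abundance; **selection** concentrates 90% of each plant's pool mass on one
clade shared across the study. The clade is chosen as the most
phylogenetically *compact* clade of adequate size (at least $0.75\,S$ tips,
at most half the tree), and each plant hosts its own roughly $S/2$-taxon
subset of it. Both choices are deliberate: selection means filtering for a
coherent clade, and taxa shared identically between two communities carry
no nearest-taxon signal — with near-total taxon overlap the betaNTI
contrast vanishes even though the communities are "selected".

The observation model (`apply_observation_model()`) detects each seed with
probability $q$ and multinomially resamples detected seeds to `depth`
reads. It does **not** simulate sequencing error, chimeras, taxonomic
misassignment, compositional bias of library preparation, or
culture-enrichment bias; passing tests on synthetic data therefore
demonstrate correctness of the estimators under the stated model, not
robustness to those artifacts. Stages are independent draws — the emulated
design is destructive, so no within-seed time series exists to mimic.

## Numerical choices and degenerate inputs

* Rarefaction (`rarefy_counts()`) is hypergeometric (without replacement),
  seeded, and drops samples below depth with a report; it is applied to
  diversity-style summaries (richness, Faith PD) but **not** to the neutral
  fit, which consumes raw counts — rarefaction would overwrite the per-seed
  totals that proxy $N_c$. This is switchable by simply fitting a rarefied
  table.
* The abundance filter uses a strict inequality, so taxa at exactly the
  threshold are excluded.
* Dominance ties are broken lexicographically and flagged, keeping every
  ranking deterministic.
* Beta-binomial probabilities are computed in log space; the GMM objective
  clamps parameters to the search box with a quadratic penalty, and
  reports `at_bound` when the optimum touches it (as it legitimately does
  for monodominant data, where $\hat R \to 0$).
* betaNTI is returned as `NA` with a flag when the null spread is zero
  (e.g. a single shared taxon, or `n_null = 1`).
* Degenerate quantile ranges ($N_{\min} = N_{\max}$) and single-ASV samples
  are handled throughout; empty samples are retained for detection
  summaries and excluded from proportion and null-model computations.

## Problem sizes

The test suite and the acceptance script run the exact Moran oracle on
state spaces up to $N = 8, S = 4$; Monte-Carlo moment checks at $10^5$
(tests) and $5\times10^4$ (script) draws per parameter point; GMM recovery
at 20 replicates for $M \in \{10, 50, 200\}$; betaNTI calibration on 200
community pairs at 199 null replicates; and pipeline determinism on a
3-plant, 2-stage study at 99 null replicates. These sizes were chosen so
that each property is resolved well inside its statistical tolerance while
the whole suite stays interactive; all of them scale up by changing a
single argument.

## Known limitations

* Only $R$ is identifiable, never $\mu$ and $C$ separately; likelihood or
  Bayesian fitting (e.g. via the Etienne sampling formula) is out of scope.
* The uniform $[N_{\min}, N_{\max}]$ size distribution is a modeling
  convenience; heavy-tailed size distributions would perturb the mixed
  moments.
* The Raup–Crick null-model variant (occurrence-weighted draws,
  abundance-weighted filling) is one standard choice among several; it is
  config-free here but isolated behind its own function.
* Source-habitat attribution is presence/absence co-occurrence, not a
  quantitative source-tracking model.
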