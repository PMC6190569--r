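# rvpedsim

Simulation of pedigrees **ascertained to contain multiple disease-affected
relatives**, for planning and interpreting family-based studies of rare
disease variants.

Family studies recruit a pedigree when a proband's disease onset falls in a
recruitment window and enough relatives are already affected. That
ascertainment process — together with right-censoring at the study stop
year and the proband's imperfect recall of distant relatives — shapes the
sample at least as much as the genetics does. `rvpedsim` simulates the
whole pipeline and provides the statistics used to analyse such samples.

## Model

Each individual's life is a competing-risks process of three
non-homogeneous Poisson events with piecewise-constant age-specific
hazards:

- **onset**: population hazard λ_onset(t) decomposed by the carrier mixture
  λ_onset(t) = (1 − p_c) λ_o(t) + κ p_c λ_o(t), so non-carriers experience
  the baseline λ_o(t) = λ_onset(t)/(1 + p_c(κ − 1)) and carriers κ λ_o(t),
  with κ the genetic relative-risk and p_c the carrier probability;
- **death**: hazard λ_u(t) while unaffected, λ_a(t) after onset;
- **reproduction**: a Poisson–Gamma (negative-binomial, size 2) offspring
  model — lifetime rate γ ~ Gamma(2, 4/3) spread over a personal
  reproductive span [a1, a2), a1 ~ U(16, 27), a2 − a1 ~ U(10, 18).

Waiting times are drawn by exact inversion of the cumulative hazard; the
shortest wait becomes the next event. Pedigrees grow recursively from a
founder who may introduce a causal variant (always, or with probability
p_c), transmitted by Mendel's laws. Ascertainment selects a proband (onset
in span, at least the `num_affected`-th onset), trims relatives by recall
probability (default: four times the kinship coefficient) while keeping
unavailable connectors, and discards-and-retries until the criteria hold.

Statistics: recursive kinship coefficients, the familial-clustering
statistic A_IBD (mean pairwise 2φ among affecteds), generation assignment
anchored at the affecteds' most recent common ancestor (for
apparent-anticipation analysis, with an unaffected death-age negative
control), per-family/per-affected summary tables, and the proportion of
ascertained families segregating a causal variant.

## Worked example

```r
library(rvpedsim)
h   <- synthetic_hazards()            # bundled registry-shaped curves
cfg <- study_config(kappa = 20, num_affected = 2,
                    ascertain_span = c(2000, 2015), stop_year = 2017)
set.seed(11)
pair <- ascertain_pedigree(cfg, h, famid = 1)
pair
#> <rv_ped_pair> ascertained after 2 attempt(s)
#> full pedigree: 12 members; ascertained: 11 members, 2 affected
summarize_family(pair)$family_info
#>   FamID totalRelatives numAffected aveOnsetAge aveIBD ascertainYear segRV
#> 1     1             11           2        37.5    0.5          2012  TRUE
```

Here the second simulated pedigree met the criteria: an 11-member
ascertained family (one relative was not recalled) whose proband had onset
in 2012; its two affecteds are first-degree relatives (mean pairwise IBD
0.5), average onset age 37.5, and the family segregates the causal variant
(`segRV`). A whole study sample is one call
(`simulate_study(cfg, h, n_families = 200, seed = 1)`), and
`proportion_segregating()`, `anticipation_tables()` and
`summarize_study()` reduce it to the quantities above.

A command-line wrapper is included (`inst/cli/rvpedsim`) with subcommands
`simulate`, `summarize` and `hazards`; see `?run_cli`.

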