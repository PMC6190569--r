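---
title: "Simulating pedigrees ascertained for multiple disease-affected relatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pedigrees ascertained for multiple disease-affected relatives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvpedsim)
```

Family-based studies recruit pedigrees that contain several relatives
affected by the same disease, because such families are enriched for rare
causal variants. The recruitment process itself, however, distorts what the
sample looks like: families enter the study only when enough members have
already developed disease during a fixed calendar window, younger members
are right-censored at the study stop year, and the proband cannot always
recall distant relatives. `rvpedsim` simulates this whole pipeline — life
events, variant transmission, ascertainment, and trimming — so that the
within-family patterns seen in real studies (clustering of affecteds,
apparent anticipation, the fraction of families that truly segregate a
variant) can be studied under a known generating model.

## The life-event model

Each individual is simulated from birth as a competing-risks process with
three event types, each a non-homogeneous Poisson process with
piecewise-constant, age-specific intensity:

* **Disease onset.** The population onset hazard
  $\lambda_{onset}(t)$ is supplied per yearly age bin. It is decomposed
  into a baseline (sporadic) hazard $\lambda_o(t)$ and a carrier hazard
  $\kappa\,\lambda_o(t)$ through the mixture identity
  $$\lambda_{onset}(t) = (1-p_c)\,\lambda_o(t) + \kappa\,p_c\,\lambda_o(t),
  \qquad \lambda_o(t) = \frac{\lambda_{onset}(t)}{1 + p_c(\kappa-1)},$$
  where $\kappa \ge 1$ is the genetic relative-risk and $p_c$ the carrier
  probability of all causal variants as a group. Onset can occur at most
  once; remission is not modelled.
* **Death.** Two hazard columns, $\lambda_u(t)$ for the unaffected and
  $\lambda_a(t)$ for the affected population; onset switches an individual
  from the first to the second. Anyone who outlives the final partition
  boundary (100 years by default) is recorded as dying there, so nobody is
  immortal.
* **Reproduction.** At birth each individual draws a lifetime birth rate
  $\gamma \sim \mathrm{Gamma}(2,\,4/3)$, a reproductive-span start
  $a_1 \sim U(16, 27)$ and length $a_2 - a_1 \sim U(10, 18)$. Waits are
  exponential with rate $\gamma f^{\delta}/(a_2-a_1)$ ($\delta$ the disease
  status, $f \in [0,1]$ the post-onset rescaling, default 1), conditioned
  on the current age: before $a_1$ the event lands at $a_1 + w$; inside the
  span the residual wait applies; beyond $a_2$ no reproduction occurs. For
  a survivor of the full span this yields Poisson($\gamma$) offspring, and
  mixing over $\gamma$ gives the negative-binomial offspring distribution
  with size 2 used for human family sizes. (A negative-binomial success
  probability of about $4/7$ is sometimes quoted alongside these gamma
  parameters; the standard Poisson–Gamma identity instead implies $3/7$,
  and this package follows the explicit Gamma(2, 4/3) draw, which is the
  operational definition.)

Waiting times are sampled by exact inversion of the piecewise-constant
cumulative hazard at an Exp(1) target rather than by thinning: integration
is closed-form, inversion round-trips to machine precision, and every draw
is reproducible from the seed. The three waits compete; the shortest one
becomes the next event, the age advances, and the process repeats until
death or until the next event's calendar year would pass the study stop
year, at which point the individual is censored. Ties (probability zero)
break deterministically as death, then onset, then reproduction. Event
calendar years are recorded as $\lfloor \text{birth year} + \text{age}
\rfloor$, matching the integer years reported in study tables.

One printed form of the conditional reproduction wait gives `t' + w` for an
individual already inside the reproductive span; that expression is an age,
not a wait, and is inconsistent with the first branch, so the residual wait
`w` is used — by memorylessness of the exponential this leaves the
offspring-count distribution unchanged, which the test suite verifies
against direct Poisson counts.

## Pedigree growth and variant transmission

A pedigree grows recursively from a starting founder whose birth year is
uniform over a configurable range (1900–1980 by default). The causal
variant enters by at most one founder, either deterministically
(`eldest_founder`) or with probability $p_c$ (`bernoulli`, which admits
fully sporadic families), and is transmitted to each offspring
independently with probability 1/2. Each reproduction event creates an
offspring (sex a fair coin) whose own life is then simulated; a single
married-in co-parent per individual is created at first reproduction, as a
non-carrier with no simulated life history. This "one union per member"
simplification keeps the blood pedigree a tree, which the kinship,
trimming, and generation-assignment machinery exploits; half-sibships,
inbreeding loops and de novo variants are out of scope.

## Ascertainment

A simulated family enters the study if it contains a *proband*: an affected
member whose onset year falls inside the ascertainment span and whose onset
is at least the `num_affected`-th in the family (onset-order ties break by
onset age, then ID). An eligible member is chosen uniformly. Eligibility is
assessed at onset; whether the member later died does not disqualify them,
since contact is presumed at the time of onset.

The proband then "recalls" each blood relative independently: by default
with probability four times the kinship coefficient (1, 0.5, 0.25 for
first, second, third degree), or with a user vector $(p_1, \dots, p_q)$
applied by degree, $p_q$ covering degree $\ge q$. Un-recalled individuals
needed to connect the recalled members — the paths to their most recent
common ancestor in the blood tree — are retained as *connectors*, marked
unavailable with disease status, carrier status, relative risk and event
years all missing. Carrier status is treated as unobservable for
un-recalled relatives (they are never genotyped), so it is masked along
with the rest. Married-in co-parents are kept exactly when one of their
offspring is present together with the blood co-parent, so parent links
always resolve in pairs. If trimming drops the affected count below
`num_affected`, the entire pedigree is discarded and a new one simulated;
the attempt count is reported, and a configurable ceiling (10,000) makes
impossible configurations fail loudly.

## Pedigree statistics

* **Kinship** is computed by the classic recursion over a
  parents-before-offspring ordering; founders are non-inbred and mutually
  unrelated.
* **Familial clustering** is summarised by the mean pairwise IBD
  probability among affecteds, $2\phi$ averaged over affected pairs
  (0.5 for an affected parent–child or sibling pair, 0.25 for avuncular or
  grandparent–grandchild pairs).
* **Generation assignment** anchors generation 1 at the most recent common
  ancestor from whom all affecteds could have inherited a variant
  identically by descent, allowing an affected to be their own ancestor; a
  founder couple counts as one generation (chains from a parentless spouse
  are collapsed onto the blood co-parent). Unaffected relatives in the
  same descent get the analogous depth-based number — a convention, since
  only affecteds define the anchor — which supports the death-age
  negative-control table used to diagnose right-censoring.
* **Proportion segregating**: among ascertained families with at least
  $n_A$ affecteds, the fraction carrying the variant, meaningful under the
  `bernoulli` introduction mode.

## The synthetic hazard generator

`synthetic_hazards()` builds the study conditions used throughout the
tests: yearly bins from 0 to 100; a disease hazard that is negligible in
childhood and rises logistically around age 50 to a plateau, integrating
to a lifetime risk of roughly 10% (the common-cancer end of registry
rates — deliberately higher than rates for rarer cancers so that
desk-scale simulations ascertain families in seconds rather than hours);
Gompertz death hazards ($4\times10^{-5} e^{0.085\,t}$, under which ~90% of
a cohort dies by 100); and an affected death hazard at a constant
excess multiple (2) of the unaffected one. These curves emulate the
*shape* of registry data, not any particular disease's level. Consequences
to keep in mind when reading test results: sporadic multiplex families are
more common here than for a rare cancer, so contrasts across $\kappa$ are
conservative relative to a rare-disease setting, and absolute quantities
(affecteds per family, proportion segregating) should not be read as
estimates for any real disease. What the passing suite does show is the
qualitative machinery: more and more-closely-related affecteds at higher
$\kappa$, and apparent anticipation at $\kappa = 1$ arising purely from
ascertainment plus right-censoring.

The simulation scale of the checks — two samples of 200 ascertained
families at $\kappa \in \{1, 20\}$, plus $10^4$–$10^5$-draw sampler
checks — was chosen so the full suite runs on a laptop in minutes while
keeping Monte Carlo error well inside the margins being asserted.

## Worked example

```{r example, eval = FALSE}
h <- synthetic_hazards()
cfg <- study_config(kappa = 20, num_affected = 2,
                    ascertain_span = c(2000, 2015), stop_year = 2017)
pair <- ascertain_pedigree(cfg, h, famid = 1)
pair$ascertained_ped
summarize_family(pair)
```

## Known limitations

Married-in co-parents have no simulated life history (no death year), so
they never appear in the death-age negative control; the blood pedigree is
a tree (no loops); recall is independent across relatives, whereas real
probands recall whole branches; and hazards are constant within yearly
bins with no calendar-time trends. The headline quantities of
registry-scale studies (counts from 1000-family samples under real
registry hazards) require those external hazard curves and hours of
compute, and are deliberately out of scope for the bundled synthetic
conditions.
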