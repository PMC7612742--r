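---
title: "Modelling UPF purchasing policies with upfsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling UPF purchasing policies with upfsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upfsim)
```

`upfsim` simulates weekly household purchasing of ultra-processed foods
(UPF) among adult female food purchasers and the response of that purchasing
to taxes, front-of-package warning labels and advertising changes. This
vignette documents the model, its assumptions, the tunable parameters, the
numerical choices made where the design was genuinely open, and what the
synthetic population does and does not capture about real data.

## The model

### Population

Each agent is a household food purchaser with three fixed characteristics
and one mutable state:

| field | values | default distribution |
|---|---|---|
| `age_group` | younger / middle / older | 25% / 50% / 25%, exact counts |
| `education` | low / high | 73% / 27%, exact counts |
| `income` | pesos/week | log-normal; low-ed mean 889, SD 911; high-ed 2044, 2225 |
| `income_category` | low / high | high iff income > 1890 pesos/week |
| `upf_kcal_week` | kcal/week | log-normal around the income-group baseline mean, CV 0.30 |

Category counts use deterministic largest-remainder apportionment rather
than independent Bernoulli draws: the population margins are specified
quantities, and fixing the counts removes a nuisance source of
between-replicate variance (a 1000-agent population always has exactly 270
high-education agents). Incomes are drawn from log-normals whose parameters
are solved analytically from the natural-scale mean and SD, so the
configured moments are reproduced exactly in expectation. The income
boundary is read strictly — an income exactly at the threshold is classed
low — so the rule is testable without ambiguity.

Two baseline scenarios encode stages of the social transition in UPF
purchasing: `pre_transition` starts high-income agents at a mean of 3446
kcal/week and low-income agents at 2966 (the Mexico-like pattern);
`post_transition` reverses the ordering (2620 high / 3100 low, the
Chile-like pattern).

The shape of the within-group baseline distribution is not identified by
group means alone, so it is a design choice: purchasing is non-negative and
right-skewed, hence a log-normal with a coefficient of variation of 0.30,
truncated at zero and exposed as `baseline_dispersion`. The CV matters
mainly for how long the social dynamics take to settle and for the spread of
replicate means; the headline policy contrasts are insensitive to it because
they are ratios of means.

### Social network

Friendships form a static, undirected small-world graph with target mean
degree 5.47 and hard per-node bounds of 3 and 50 ties. Construction:

1. a ring lattice of degree 4 over a **random** agent ordering;
2. extra edges added until the edge count equals
   `round(5.47 · n / 2)` (so the realised mean degree equals the target
   exactly, every seed);
3. a fraction `rewire_probability` (default 0.1) of lattice edges rewired to
   long-range contacts;
4. repair passes that restore any degree pushed outside the bounds while
   keeping the edge count fixed.

Steps 2 and 3 sample their endpoints with probability proportional to
`exp(homophily_weight × similarity)`, where similarity is the mean of three
indicator matches (same age group, same income category, same education).
This is the simplest symmetric multi-attribute homophily rule, and it
concentrates *all* homophily in the sampled edges: at `homophily_weight = 0`
the graph is a plain random small-world network with attribute assortativity
statistically indistinguishable from zero. An alternative — ordering the
ring lattice itself by a similarity embedding — was rejected because the
lattice ties would then stay assortative even with the weight at zero,
which would make the weight an untestable dial. Mean path length is
computed on the largest connected component, since rewiring can (rarely)
disconnect the graph; this is documented rather than hidden.

The network is static after construction: the model describes no tie churn,
and a fixed network keeps replicate differences attributable to the
population draw and graph draw alone.

### Weekly dynamics

Every week each agent makes two sub-updates, both against references
computed from the start-of-week snapshot of everyone's purchasing:

1. **social signal** — the mean purchasing of her network neighbours;
2. **social norm** — the mean purchasing of all agents sharing her age
   group, income category and education.

For each reference in turn, if `|x − ref|` exceeds the 50 kcal/week
perception threshold she moves `adjustment_fraction ×
conformity_resistance` of the difference towards it (defaults 0.10 × 1.0);
otherwise she does not move. The second sub-update starts from the
post-signal value but still compares against the snapshot norm, so the
update is synchronous and independent of agent iteration order — replicates
are reproducible without specifying a shuffle.

The threshold creates a deadband: once every agent is within 50 kcal of
both references the system freezes, which is what lets distinct
income-group purchasing levels persist at equilibrium instead of collapsing
to consensus. With the threshold at zero the dynamics are linear
(`x ← M x` for a row-stochastic M), which the test suite exploits with
matrix-power oracles on 10-agent instances.

`conformity_resistance` is kept separate from the stated 10% fraction
because resistance-to-conforming is a calibrated quantity while the 10% is
a stated one; the default of 1.0 recovers the literal 10% rule, and
calibration may scale it down.

### Policies

A scenario is a `(tax_rate, label_active, advertising_change)` triple
applied once at the activation week (default 52) as a per-agent
multiplicative level shift:

* tax: `1 + price_elasticity × tax_rate`, with the point elasticity −1.2 —
  the linear form, because 1 − 1.2 × 0.5 = 0.40 matches a 60% reduction
  under a 50% tax where the constant-elasticity power form (≈ 0.61) does
  not;
* label: `0.78` for low-education and `0.71` for high-education agents;
* advertising: `1 + 0.113 × advertising_change`.

Combined policies multiply the three factors. The discriminating evidence
is the combined scenarios themselves: a 50% tax + label + 50% advertising
cut yields a factor near 0.287 (a ≈72% reduction) multiplicatively, whereas
adding the proportional changes would predict ≈90% — only the product is
consistent with the reductions the model family is known to produce. An
`effect_parameters(composition = "additive")` switch preserves the additive
reading for sensitivity analysis.

The shift is applied once, not weekly: a weekly reapplication would compound
the factor and decay purchasing towards zero rather than moving it to a new
stable level. After the shift the social dynamics continue on the shifted
values; because a uniform tax rescales every agent and the deadband scales
with nothing, post-tax trajectories are nearly flat, while the
education-differential label induces a small amount of post-policy social
re-mixing.

### Calibration

Free parameters: `homophily_weight`, `conformity_resistance` and the
income-group baseline means. Targets: the no-policy equilibrium population
mean within 5 kcal of 3033 kcal/week; the configured income-group ordering
holding at every reported week; and a persistent income-group gap (final
gap ≥ 25 kcal/week), operationalising the requirement that the group
distributions not fully converge.

`calibrate()` evaluates a coarse grid over
`(homophily_weight, conformity_resistance)` — default `{2, 5, 8} × {0.5,
1.0}` — with all candidates sharing the same derived replicate seeds, keeps
the admissible candidate with the largest persistent gap (the most robustly
non-converged), and then rescales both baseline means by a common factor
towards the mean target. The rescaling converges in one or two iterations
because the dynamics are almost scale-equivariant (the only absolute scale
in the update is the 50 kcal threshold), so the equilibrium mean is nearly
proportional to the baseline means. The stated baseline means are trusted
first and only rescaled if the target is missed; the common factor
preserves the configured ordering and approximate gap.

"Equilibrium mean" is defined as the average over the last 26 weeks of a
burn-in-plus-52-week no-policy window, averaged over replicates — the model
typically freezes well before that, and the 26-week tail smooths
Monte-Carlo noise. Calibration uses 20 replicates per evaluation;
production scenario runs use more.

### Experiments

`run_scenario()` runs `n_replicates` independent replicates. Each replicate
regenerates the population and network from seeds derived deterministically
from the master seed, burns in 100 weeks (not recorded), records weeks
1–208, and applies the policy immediately after week 52 is recorded.
Per-week population means are averaged across replicates (with their SD);
stratum means are pooled (total kcal over total agents), so size-weighted
stratum means rebuild the population mean exactly. Scenarios sharing a
master seed have identical pre-policy trajectories, so scenario contrasts
are paired. Percentage effects are reported as
`100 × (mean₅₂ − mean₂₀₈)/mean₅₂` — the change relative to the same run's
pre-policy level; under the stable no-policy equilibrium this almost
coincides with the contrast against the paired no-policy scenario.

Equity is summarised by the absolute income-strata gap `|low − high|` and
the relative gap against the **larger** stratum mean (so a 138 kcal gap on
a 3000 kcal base reads as 4.6%); `equity_report()` tabulates both stages of
the transition side by side.

## Problem sizes and reproducibility

Shipped defaults follow the study design: 1000 agents, 100-week burn-in,
208 recorded weeks, policy at week 52, 200 replicates. The packaged checks
and the acceptance script run the same design at 25 replicates (20 per
calibration evaluation), which keeps the full scenario battery around a
minute of CPU while leaving replicate standard errors of the percentage
effects an order of magnitude below the tolerances being checked. All
randomness flows from one master seed through a deterministic seed ladder
(master → replicate → population/network streams); the weekly dynamics are
themselves deterministic, so replicate variation is structural (population
and network draws), and identical seeds give bit-identical results.

## What the generator does and does not emulate

The synthetic population reproduces the marginal age, education and income
structure and the income-group purchasing means of the study population —
not joint structure beyond education→income (age is independent of both),
not household composition, and not any real friendship network. Passing
tests therefore demonstrate that the *mechanisms* behave as specified
(elasticity arithmetic, homophily, deadband dynamics, calibration,
paired-seed experimentation), not that the model is validated against
observed purchasing trajectories. The policy effect sizes are imported
elasticities and evaluation estimates, so population-level reductions are
close to analytic predictions by construction; the simulator's added value
is the joint, stratified, networked behaviour — who moves, how gaps evolve,
and how policies interact.

## Known limitations

* One gender, adults only, one purchaser per household; no children or
  intra-household bargaining.
* No product reformulation, cross-price substitution, spatial food access
  or pass-through below 100%.
* Advertising effects use a television-advertising elasticity; other
  advertising forms may differ.
* The emergent post-transition gap statistics depend on calibrated
  parameters that are not pinned by published values, so they are checked
  qualitatively (direction of gap changes), not numerically.
* Relative income prices per agent (continuous income modulating the tax
  burden) are not modelled; the tax acts uniformly across incomes.
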