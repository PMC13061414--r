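---
title: "An individual-based model of helper task specialization in cooperative breeders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of helper task specialization in cooperative breeders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`dolsim` simulates the evolution of alloparental care and task
specialization in a cooperatively breeding population with totipotent
helpers. A fixed habitat of `N_b` breeding territories is occupied by
groups of a single asexually reproducing breeder (complete reproductive
skew) and a variable number of subordinate helpers; dispersed individuals
without a territory are floaters. Each individual carries seven haploid
loci: a helping effort allele (`alpha`), a dispersal allele (`beta`), the
intercept and dominance slope of an optional dispersal reaction norm
(`beta_0`, `beta_R`), the intercept and dominance slope of the task-choice
reaction norm (`gamma_0`, `gamma_R`), and a neutral marker used only to
measure relatedness.

Each breeding cycle executes five steps:

1. **Reproduction.** Every breeder produces `Poisson(K)` offspring, with
   `K = k_0 + k_h * S / (1 + S)` and `S` the group's *effective* cumulative
   help from the previous cycle. Offspring inherit the breeder's genome
   with per-locus mutation probability `mu` and Gaussian step `sigma_mu`,
   and join the natal group as age-1 subordinates.
2. **Dispersal.** Every subordinate (newborns included) becomes a floater
   with probability equal to its dispersal phenotype `D`; the floater pool
   (old floaters first, then fresh dispersers) is then processed in order,
   each member joining a uniformly random territory as a subordinate with
   probability `1 - D`. In the group-augmentation-only scenario,
   philopatric newborns are then cross-fostered by randomly permuting
   their territory labels, which removes kin structure while leaving
   demography untouched.
3. **Task choice and help.** Every subordinate chooses the defensive task
   with probability `T = 1 / (1 + exp(gamma_R * R - gamma_0))`, evaluated
   at its current dominance `R` (its age, the work cost not yet being
   paid), and otherwise works. Its full help `H = max(0, alpha)` accrues
   to the group's cumulative sum for the chosen task; those sums feed the
   *next* cycle's reproduction.
4. **Survival.** Logistic role-specific survival with ceiling `1 - m`:
   breeders `S_B = (1-m)/(1+exp(-x_0 - x_n N))`, subordinates
   `S_H = (1-m)/(1+exp(-x_0 + x_h H_def - x_n N))` where `H_def` is the
   help expressed in defense this cycle, floaters
   `S_F = (1-m)/(1+exp(-x_0))`. Group size `N` counts the breeder plus
   subordinates, frozen at the start of the step and shared by all group
   members; newborns are not exempt.
5. **Breeder replacement.** Each vacant territory is contested by its
   surviving subordinates plus a sampled set of floater bidders; the
   number of bidders per vacancy is `Poisson(f N_f / N_b)`, drawn without
   replacement so a floater bids at most once per cycle. The winner is
   drawn with probability proportional to dominance
   `R = max(0, t - y_h H_work)`, i.e. age minus the current cycle's work
   cost (work costs are not cumulative). Survivors then ascend one age
   class.

Help is costly in two distinct currencies: defensive tasks reduce
immediate survival (scale `x_h`), work tasks reduce the dominance value
and hence the chance of inheriting a breeding position (scale `y_h`).
Under the `DOL` fecundity mode the breeder's productivity saturates unless
the two task sums are balanced: each sum is truncated at
`H_max = (sum_def + sum_work)/2 + k_m`, so a group that only works (or
only defends) wastes effort above the cap, and division of labour is
required for full productivity; the `NO_DOL` benchmark removes the cap.

Three benefit scenarios separate the evolutionary forces. `KS_GA` (the
default) has both kin structure and group-size survival benefits.
`KS_ONLY` removes the direct benefit by forcing `x_n = 0` while leaving
kin structure intact. `GA_ONLY` keeps `x_n` but destroys kin structure by
cross-fostering philopatric newborns.

## Parameters

All parameters are dimensionless scalings except where noted.

| name | default | meaning |
|------|---------|---------|
| `y_h` | 0.1 | work cost on dominance per unit help |
| `x_h` | 5 (3/7 for sweeps) | defense cost on survival per unit help |
| `x_n` | 3 (0 in `KS_ONLY`) | group-size survival benefit |
| `x_0` | 1.5 | survival intercept |
| `m`  | 0.1–0.3 | baseline mortality; the environmental-harshness axis |
| `f`  | 2 | mean groups a floater samples per vacancy cycle |
| `k_m` | 0.1 | slack on the balanced-task requirement |
| `k_h` | 1 | fecundity gain of cumulative help (saturating) |
| `k_0` | 1 | baseline fecundity (offspring/cycle) |
| `mu` | 0.05 | per-locus mutation rate |
| `sigma_mu` | 0.04 | mutation step SD (allelic units) |
| `N_b` | 5000 | breeding territories |

The ancestral state is no care and absolute dispersal: `alpha = 0`,
`beta = 1`, `beta_0 = 1`, `beta_R = 0`, `gamma_0 = gamma_R = 0` (either
task with probability one half). The population is initialized with one
age-1 breeder per territory carrying these alleles, no subordinates and no
floaters; the neutral locus is drawn i.i.d. standard normal so the
relatedness regression is estimable from the first generations.

## Design choices

Several aspects of the dynamics are open to interpretation; the choices
made here are part of the engine contract and are tested as such.

* **Gene bounds.** Allelic values are unbounded and bounds are applied at
  phenotype expression, with one deliberate exception: the dispersal
  allele, whose phenotype is the identity map onto the closed interval
  `[0, 1]`, is truncated into that interval at mutation. Under
  expression-only clamping both of its boundaries are absorbing — once the
  population mean drifts past a boundary, selection can no longer see
  genetic variation and the trait is frozen at the extreme forever — which
  contradicts the persistent low-level philopatry the model is meant to
  exhibit. The helping allele is *not* truncated: its boundary is
  one-sided, evolution across it is the object of study, and gene-level
  truncation would inject a spurious upward mutational bias producing
  nonzero helping even where help is counter-selected (it would also break
  the zero-help demographic equilibrium of the benign
  group-augmentation-only scenario).
* **Dispersal-norm variant.** The optional reaction norm of dispersal to
  dominance uses the same logistic shape as the task norm,
  `D = 1/(1+exp(beta_R R - beta_0))`; the scalar clamped allele is the
  default (`SCALAR`).
* **Relatedness estimator.** The OLS slope of the helpers' neutral values
  regressed on their breeders' (one observation per helper), recomputed at
  every recorded cycle; helpers outnumber breeders, giving the
  better-conditioned design. Fewer than two pairs, or zero breeder-side
  variance, yield a missing value rather than an error.
* **Fresh dispersers may immigrate the same cycle.** A subordinate that
  disperses joins the floater pool and is processed with it in the join
  phase of the same cycle, so it may immediately enter a random group with
  probability `1 - D`.
* **Bidder counts.** The nominal bidders-per-vacancy `f N_f / N_b` is
  generally fractional; it is realized as a Poisson draw capped by the
  remaining pool, preserving the stated mean with integer counts.
* **Vacant territories** do not reproduce, still receive immigrants, and
  are re-contested every cycle.
* **Tie-breaks.** When every replacement candidate has dominance zero the
  lottery is uniform. Breeders never disperse, never help and pay no task
  costs.
* **Equilibrium summary.** Each run's equilibrium statistics are means
  over the final 10% of recorded cycles. The optional equilibrium
  detector (off by default; fixed run length is the primary stopping rule)
  fires when every allele mean has OLS slope below `tol` over the last
  window of records and the window mean moved by less than `tol` against
  the previous window.

## Determinism and the two engines

All stochastic decisions follow a fixed draw order (territories in index
order, individuals in stable queue order, loci in genome order), so runs
are exactly reproducible from `(parameters, scenario, seed)`. The package
ships two implementations of the cycle: a compiled production engine and a
deliberately unoptimized per-individual reference written in R. Both
consume random numbers from R's RNG in the same order; the test suite
verifies that they produce bit-identical populations over multiple cycles
in every scenario, which protects the production engine against silent
divergence from the documented dynamics.

## What the simulator emulates — and what it does not

The simulator is its own data generator; there is no external input. It
emulates the demographic consequences of helping, dispersal and queue
inheritance under overlapping generations: emergent group sizes, floater
loads, age structure, and kin structure measured at a neutral locus. It
does not model sexual or diploid genetics, explicit space, within-group
reproductive sharing, enforcement of help by dominants, age- or
condition-dependent task ability, or plastic adjustment of help to
relatedness. Passing tests therefore show that the *mechanisms as
specified* produce the expected equilibria; they say nothing about
parameter ranges outside those studied, and quantitative equilibrium
values at reduced scale can differ from full-scale runs because drift is
stronger in smaller populations and slow co-evolutionary transients
(helping together with philopatry) may not complete within shorter runs.

## Problem sizes

Full-scale runs (`N_b = 5000`, 200,000 cycles, 20 replicates per cell) are
an overnight batch. The package's own verification uses scaled designs
chosen to fit an interactive workflow: structural test runs use
`N_b` 400–1000 for 15,000–20,000 cycles, and the reproduction script
(`scripts/acceptance.R`) uses `N_b = 1000` with 60,000-cycle
kin-selection runs and 30,000-cycle group-augmentation runs, five
replicates per cell, recording every 100 cycles. At these sizes the
kin-selection scenario has typically not finished its slow co-evolutionary
drift toward the full-scale equilibrium (dispersal keeps creeping down for
over 100,000 cycles), which is the main known source of quantitative
disagreement at reduced scale; the group-augmentation scenario converges
within a few thousand cycles.

## Known limitations

* The neutral-locus relatedness slope is a haploid parent-offspring
  regression; analyses using the diploid convention (relatedness as twice
  the parent-offspring regression) will read systematically higher values
  on the same populations.
* Per-record relatedness estimates are noisy when helpers are rare (the
  kin-selection scenario keeps group sizes barely above 1); equilibrium
  relatedness should always be read as a window average, never from a
  single record.
* The equilibrium detector is a pragmatic flatness test on allele means,
  not a stationarity test of the full state.
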