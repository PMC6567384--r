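---
title: "Estimating poaching mortality with multievent capture-mark-recapture"
author: "poachCMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating poaching mortality with multievent capture-mark-recapture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poachCMR)
```

## The problem

Poaching removes animals from a population without leaving obvious evidence:
carcasses are found haphazardly, causes of death often cannot be assigned,
and the marked animals that would carry the information wear different mark
types with very different detection properties. This package estimates the
annual probability that an animal alive at the start of a year is poached
during it — separately from mortality by all other causes, by sex and age
class — from exactly this kind of messy field data: annual encounter
histories of individually marked deer carrying ear tags, optical collars or
GPS collars, with live resightings, incomplete dead recoveries and a
fraction of recoveries whose cause remains unknown.

## The multievent model

The data for one individual are a string of *event codes*, one per annual
occasion: 0 (not seen), 1–4 (seen alive, by mark status), 5–10 (recovered
dead, by mark group x cause: 5/6 poached, 7/8 other, 9/10 unknown). Events
are imperfect reflections of a *latent state*. The hidden process has nine
states: four alive states distinguished by mark status (working GPS,
inactive GPS collar, optical collar, ear tags only), four newly-dead states
(poached/other cause x working-GPS/other marks), and an absorbing
long-dead state. Dead recoveries of optical-collar, inactive-GPS and
ear-tag animals are pooled into a single non-GPS mark group: the dead codes
do not distinguish them, so the state space does not need to either.

Each annual transition factorizes into a **mark kernel** followed by
**survival/mortality**:

* a working GPS loses its signal with probability `lambda[d]`, where `d` is
  the deployment-year class (first year vs later — collars age, so loss
  concentrates after the first year), and the collar drops off with
  probability `D`, reverting the animal to ear tags only;
* the animal then survives with probability `phi[a] = 1 - mPoach[a] -
  mOther[a]`, is poached with probability `mPoach[a]`, or dies of another
  cause with probability `mOther[a]`, where `a` is its age class; a death
  enters the newly-dead state of the post-kernel mark group.

The event matrix ties states to codes: working-GPS animals are detected
with certainty (hourly fixes), collar-like animals are resighted with
probability `p[t, collar]`, ear-tag animals with `p[t, tag]`; a newly-dead
animal is recovered with probability `r` (non-GPS) or `rGps` (working GPS,
fixed at 1 by default — a telemetered death is always detected), and a
recovered carcass has its cause determined with probability `delta`,
otherwise it is reported with an unknown-cause code. Because `delta` enters
the likelihood, unknown-cause recoveries are redistributed between poaching
and other causes by the model itself rather than being discarded or
assigned ad hoc. Identifiability forces one `delta` shared across causes
and mark groups.

The likelihood of a history is the standard scaled forward recursion over
the latent states, conditioned on the release; initial mark-type
proportions are estimated as two free multinomial-logit parameters by
default (they decouple from every other parameter, but keep the deviance
and parameter counts directly comparable with analyses that estimate them;
`estimateInit = FALSE` conditions on the release instead).

### Parameterization and candidate structures

All probabilities live on link scales: binomial parameters on the logit,
each age class's (poach, other, survive) triple on a multinomial logit with
survival as the reference, which enforces `mPoach + mOther <= 1` for any
finite parameter vector. Three mortality structures formalize the
biological hypotheses:

* **interactive** — a free parameter per age class x cause (2A parameters);
* **additive** — the two causes share the age profile up to a constant
  cause offset on the multinomial-logit scale (A + 1 parameters). The scale
  of "parallel" variation is a genuine choice; the multinomial logit is the
  convention of multievent software and preserves the simplex constraint,
  so it is the one implemented;
* **constant_poach** — poaching constant over age on its own logit,
  other-cause mortality free (1 + A parameters).

Resighting can be constant, mark-dependent, time-dependent, or both
(additively on the logit, or fully interacted); recovery constant or
time-dependent; time effects are occasion-indexed factors over occasions
2..T. GPS signal loss always has the two deployment-year classes and
drop-off is constant, matching how collar hardware actually behaves.

### Process-order convention

The decomposition "mark dynamics, then mortality" within an interval is a
convention: the data cannot distinguish whether a collar dropped before or
after its carrier died within the same year. The choice is isolated in
`buildTransition()`, so the alternative order is a one-line variant; all
conservation and oracle tests would apply unchanged.

## Estimation, selection, averaging

`fitModel()` maximizes the likelihood by BFGS from a null start plus
seeded random starts (multievent likelihoods can be multimodal; 10 random
starts is the default, simulation studies start at the generating values).
Standard errors come from the inverse observed information on the link
scale, delta-transformed; confidence intervals are logit-scale Wald, hence
asymmetric and inside [0, 1]. Parameters within 1e-4 of a boundary are
reported as boundary estimates without SE — with these data that regularly
happens to first-year GPS loss and female drop-off, which sit at 0.

The number of *identifiable* parameters `np` is the numerical rank of the
Hessian (singular values above 1e-6 of the largest, configurable), not the
nominal count: sparse recovery data routinely confounds parameters, and an
AICc computed with the nominal count would over-penalize such models. AICc
uses `deviance + 2 np + 2 np (np+1) / (ess - np - 1)` with the effective
sample size `ess` defined as the total number of non-zero event codes
(releases, resightings, recoveries) per sex. No consensus definition of
`ess` exists for joint live-dead data; this one is consistent with the
AICc corrections in published analyses of this design at both male and
female sample sizes, and it is configurable.

Akaike weights are normalized over the three hypothesis-driven candidates
only — structural models fitted on the way (age partition, recovery and
resighting structure) guide the ladder but take no part in averaging.
Averaging happens on the probability scale with the Burnham–Anderson
unconditional SE, `sum w_j sqrt(var_j + (est_j - avg)^2)`; link-scale
averaging was the alternative, but probability-scale averages are what get
compared across age classes and plotted, and the candidate estimates are
close enough that the difference is far below the reported precision.
Mortality estimates are always expanded per age class before averaging, so
an age-constant poaching model contributes its single value to every class.

## Goodness of fit

No omnibus test exists for multievent models, so adequacy is checked on the
time-dependent Cormack–Jolly–Seber model fitted to the live resightings
only: codes 2, 3, 4 become 1, everything else 0 — working-GPS detections
are excluded because perfect detection would violate the CJS detection
model, and recoveries because dead-recovery time dependence is too sparse.
`overallGof()` computes the classical contingency-table components per sex
and pools them: TEST3.SR and TEST3.SM contrast newly against previously
marked animals (transience), TEST2.CT and TEST2.CL contrast animals
captured and not captured at an occasion (trap-dependence), each built as
sequential splits of the conditional multinomial so the chi-squares pool
additively. Columns are pooled outermost-inward until every expected count
reaches 2; tables that cannot support a test contribute zero df. Exact
pooling conventions differ between implementations, so on a given dataset
the pooled chi-square can differ by a few units from other software while
the df tally is the sturdier reference; the package's own calibration
check is simulation-based (below).

## The simulator and what passing tests mean

`simulateHistories()` draws each individual's yearly mark transition,
survival/death and observation from exactly the matrices the likelihood
uses, and records the latent truth. Its defaults describe a decade-long
protected-area Alpine red deer program: 10 annual occasions; 56 males and
85 females in
staggered cohorts over occasions 1–9 with initial marks 13/22/21 (male
GPS/collar/tag) and 16/67/2 (female); ages at marking from a geometric-like
distribution with mean about 4 years (the age distribution of darted deer
is not published; this choice spreads individuals over all age classes and
is stated here once, not tuned). The generating rates (`presetParameters`)
are realistic averaged sex- and age-specific survival and poaching
mortalities for such a population, with `lambda = (0, 0.27/0.39)`
(signal loss begins in the second deployment year), `D = 0.15/0` (male /
female), `r = 0.38/0.47`, male resighting by mark (0.47 collar, 0.23 tag),
female resighting mark-independent at its published mean 0.75 (the ten
yearly values are not published, so the female preset is time-constant and
the female refit structure is resight-constant), and `delta = 41/50` — the
empirically determined fraction of recoveries with known cause, a stand-in
because the fitted value is not published.

Two things the simulator deliberately does not emulate: the 3-year timer
on real drop-off devices (drop-off is annual-Bernoulli so simulator and
likelihood share one process; a timer variant would create model
misspecification experiments, not validation), and any spatial or
density-dependent structure. Passing recovery tests therefore demonstrate
that the estimator inverts its own generative process without bias at
realistic rates and sample sizes — they do not certify the model against
misspecifications real data might carry.

## Numerical choices

* Forward recursion with per-step scaling; compiled (RcppArmadillo) over
  aggregated unique histories, with a plain-R reference implementation
  cross-checked in the tests, and both checked against exhaustive
  latent-path enumeration on short histories.
* BFGS with `reltol 1e-10`, `maxit 500`; degenerate likelihoods (histories
  impossible under the parameters) return a large finite penalty to the
  optimizer and are reported with the offending individuals.
* Boundary tolerance 1e-4 on the probability scale; rank threshold 1e-6;
  probabilities clamped at 1e-6 before linking in `deflate()`.
* Problem sizes in the validation suite: the exhaustive oracle enumerates
  9^3 paths on 4-occasion histories; conservation is checked over 1000
  random parameter sets; parameter recovery runs 50 replicates at n = 2000
  per sex; goodness-of-fit calibration uses 200 replicates of a
  time-dependent CJS simulation with 500 released animals over 8 occasions,
  where the pooled test's rejection rate at the 5% level is verified to sit
  at its nominal value.

## Known limitations

* Cause assignment is modelled as *determined or not* (`delta`), never as
  *wrong*: a carcass labelled poached is taken at face value.
* Wald intervals only; profile or bootstrap intervals are out of scope, and
  intervals for parameters at boundaries are not reported. Simulation at the
  study's rates shows the usual Wald shortfall: coverage of the 95%
  intervals for individual mortality probabilities sits near 0.90–0.94
  rather than exactly 0.95, with the young-male poaching class the most
  affected.
* The CJS goodness-of-fit is necessary, not sufficient, for the multievent
  model: it checks the live-resighting backbone only.
* `ess` and the rank threshold are conventions; analyses comparing AICc
  across software should fix both explicitly.
* The 9-state/11-event structure reproduces the identifiable-parameter
  counts of reference analyses of this design for every male model
  structure exactly; for female models with time-dependent resighting the
  count here is one lower (occasions 2..T give T-1 resighting levels),
  a discrepancy that cannot be settled without the original data and is
  left open.

## A worked run

```{r example, eval = FALSE}
sim <- simulateHistories(defaultStudyDesign(),
                         list(M = presetParameters("M"),
                              F = presetParameters("F")), seed = 1)
summarizeDataset(sim)
overallGof(sim)

out <- runFullAnalysis(sim, list(
  nStarts = 5L, seed = 1L,
  M = list(ages = "1:3,4:7,8+", resight = "by_mark", recovery = "constant"),
  F = list(ages = "1,2:7,8+", resight = "constant", recovery = "constant")))
out$M$table
out$M$averaged
plotMortality(list(M = out$M$relative, F = out$F$relative))
```
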