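# poachCMR

Multievent capture–mark–recapture estimation of sex- and age-specific
poaching mortality.

## What this solves, and for whom

Wildlife managers and population ecologists who monitor individually marked
animals often need to know *which* segment of a population illegal killing
removes — not just how many die. The raw material is unforgiving: annual
encounter histories of animals wearing mixed marks (ear tags only, optical
collars, GPS collars), where detection probability depends on the mark, GPS
collars fail or drop off, most carcasses are never found, and some of the
found ones cannot be assigned a cause of death.

`poachCMR` fits a hidden-Markov ("multievent") capture–recapture model to
such data. The latent process has 9 states — four alive states by mark
status, four newly-dead states by cause (poached vs other) × mark group
(working GPS vs other), and an absorbing dead state — observed through 11
event codes (0 = not seen, 1–4 = resighted alive by mark, 5–10 = recovered
dead by mark group × cause, including unknown-cause codes). Each annual
transition decomposes into mark dynamics (GPS signal loss λ by deployment
year, drop-off D) followed by survival: an animal in age class *a* survives
with φ\[a\] = 1 − m_poach\[a\] − m_other\[a\]. Observations bring resighting
probabilities p (by mark and/or year), recovery probabilities r (with
working-GPS deaths always detected), and a cause-determination probability
δ that lets the likelihood redistribute unknown-cause recoveries between
poaching and other causes instead of discarding them.

On top of the likelihood the package provides: AICc model selection
(identifiable-parameter counts by numerical rank, effective sample size =
total non-zero events), Akaike weights and model averaging with
unconditional SEs across the three standard mortality hypotheses
(interactive, additive/parallel, age-constant poaching),
Cormack–Jolly–Seber goodness-of-fit components (TEST3.SR, TEST3.SM,
TEST2.CT, TEST2.CL) on the live resightings, and a generative simulator of
the whole marking–mortality–observation process with recorded ground truth.

## Worked example

Simulate a decade-long study mirroring a protected-area red deer program
(56 males, 85 females, staggered marking, three mark types), then run the
full pipeline — goodness of fit, the three mortality-hypothesis fits per
sex, selection and averaging:

```r
library(poachCMR)

sim <- simulateHistories(defaultStudyDesign(),
                         list(M = presetParameters("M"),
                              F = presetParameters("F")), seed = 1)
summarizeDataset(sim)$nRecoveriesByCause
#> poached   other unknown
#>      11      24       5

overallGof(sim)
#> CJS goodness-of-fit: chi2 = 0.26, df = 5, p = 0.998

out <- runFullAnalysis(sim, list(nStarts = 5L, seed = 1L, gof = FALSE,
  M = list(ages = "1:3,4:7,8+", resight = "by_mark", recovery = "constant"),
  F = list(ages = "1,2:7,8+", resight = "constant", recovery = "constant")))
out$M$table
#> ModelTable (weights over: interactive, additive, constant_poach )
#>           model      mortality resight recovery np deviance   aicc dAicc weight
#>  constant_poach constant_poach by_mark constant 12   465.17 491.98  0.00  0.805
#>        additive       additive by_mark constant 12   468.87 495.68  3.70  0.127
#>     interactive    interactive by_mark constant 14   465.08 496.93  4.95  0.068
out$M$relative
#>   ageClass     mPoach     mOther  relPoach
#> 1      1-3 0.09198988 0.19264096 0.3231901
#> 2      4-7 0.10371709 0.04890697 0.6795593
#> 3       8+ 0.08275508 0.36356448 0.1854167
```

The `relative` table is the headline output: absolute annual poaching and
other-cause mortality per age class, and poaching's share of total
mortality. `plotMortality(list(M = out$M$relative, F = out$F$relative))`
draws the stacked-bar chart with the relative-poaching line.

With only 56 males, 50 recoveries and partial cause determination, a single
run at the study's own scale is noisy — here the male relative-poaching
profile (32/68/19%) scatters widely around the generating truth
(52/67/56%), and selection prefers the most parsimonious mortality
structure. The simulator exists precisely to quantify that:
`recoveryExperiment()` refits the generating structure across replicates
and reports per-parameter bias, empirical SE and CI coverage — at n = 2000
per sex every mortality probability is recovered with |bias| below 0.02.

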