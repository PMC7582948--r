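# threatcode

Analysis pipeline for single-unit recordings collected during Pavlovian
fear discrimination over a baseline of rewarded nose poking, built for
experiments in which three auditory cues predict distinct foot-shock
probabilities — danger (p = 1.00), uncertainty (p = 0.375) and safety
(p = 0.00) — and the question is whether a neuron's trial-by-trial firing
tracks the animal's *fear output* or the cue's *threat probability*.

It is aimed at behavioral/systems neuroscientists analyzing peri-event
spike and nose-poke event data (midbrain vlPAG/DR recordings being the
motivating case), and at anyone who wants a tested, seeded reference
implementation of this analysis family.

## What it computes

**Conditioned suppression.** Per trial,

    ratio = (baseline poke rate − cue poke rate) / (baseline poke rate + cue poke rate)

with the baseline from the 20 s before cue onset, the cue rate over the
10 s cue, and each trial using only its own baseline. 1 = high fear,
0 = none.

**Peri-event normalization.** Firing in 250 ms bins from −20 s to +30 s
around onset (200 bins); per-trial-type mean traces differenced against the
type's 2 s pre-onset baseline; one (μ, σ) per unit over all types'
concatenated differential traces, giving Z traces with mean 0, SD 1.

**Cue-responsiveness screening.** Paired t tests of raw epoch rates vs the
10 s pre-cue baseline, three cues × two epochs at the Bonferroni threshold
0.05/6, labeling each unit cue-excited, cue-inhibited, or outside selection
criteria (osc), with mutual exclusion of the opposite direction.

**Trial-by-trial encoding.** For each 1 s cue interval, OLS of normalized
single-trial firing on (constant, fear output, threat probability), where
fear output is the trial's 10 s suppression ratio and threat probability is
the cue's shock probability with the uncertainty assignment u. Sweeping
u = 0…1 in 0.125 steps and averaging the threat beta over intervals gives
the nine-point **threat-tuning curve**, whose population peak locates the
probability the units' firing assigns to the uncertainty cue.

**Population statistics.** 2×2 Pearson chi-square for responsive
proportions, mixed-design ANOVA with partial eta squared, Bonferroni t
tests, Pearson firing/signaling coupling, and Fisher r-to-z comparison of
correlations between groups.

**Synthetic sessions.** A seeded generator (Poisson nose poking with
per-trial fear levels; inhomogeneous-Poisson units with threat/fear gains
and an internal uncertainty weight) reproduces the task's 32-trial
structure so every stage can be validated against ground truth. See the
methods vignette (`vignettes/threat-coding-methods.Rmd`) for the model,
parameter meanings and design choices.

## Worked example

```r
library(threatcode)

# one synthetic session: trained-rat behavior, one cue-excited unit
b <- simulateSession(units = list(u01 = unitSpec(threat_gain = 8)), seed = 11)
b
#> SessionBundle: rat r01 (Con) session s01
#>   32 trials: danger=6, safety=10, uncertainty_omission=10, uncertainty_shock=6
#>   1576 pokes, 1 unit(s): u01

sup <- sessionSuppression(b)
round(tapply(sup$ratio, sup$cue, mean, na.rm = TRUE), 3)
#>      danger      safety uncertainty
#>       0.951       0.119       0.661
```

Suppression is high to danger, intermediate-but-disproportionate to
uncertainty and low to safety — the behavioral pattern that makes fear
output and threat probability dissociable regressors.

```r
classifyUnit(spikeTimes(b, "u01"), trials(b))$label
#> [1] "excited"

tr <- znormUnit(trialTypeMeanTraces(spikeTimes(b, "u01"), trials(b)), "u01")
tr
#> UnitTraces for unit 'u01': 3 trial types x 200 bins (0.25 s)
#>   mu = 1.3688 Hz, sigma = 2.6472 Hz

tc <- tuningCurve(tr, spikeTimes(b, "u01"), trials(b), sup)
round(setNames(tc$mean_beta_threat, tc$u), 3)
#>     0 0.125  0.25 0.375   0.5 0.625  0.75 0.875     1
#> 1.815 2.171 2.544 2.808 2.769 2.348 1.725 1.143 0.706
```

This unit was simulated with an internal uncertainty weight of 0.375 and
its tuning curve indeed peaks at the 0.375 assignment: the regression
recovers where the unit's firing places the uncertainty cue on the
probability axis.

```r
chi <- chiSquare2x2(matrix(c(80, 71, 133, 70), 2, byrow = TRUE))
sprintf("chi2 = %.2f, p = %.3f", chi$chi2, chi$p)
#> [1] "chi2 = 5.68, p = 0.017"
```

Whole cohorts run through `runSimulate()` → `runAnalyze()` →
`runReport()`, or the equivalent `inst/scripts/threatcode
simulate|validate|analyze|report` command-line wrapper; `runAnalyze()`
writes one CSV per stage plus `stats_report.json` and a `run.log` of every
exclusion.

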