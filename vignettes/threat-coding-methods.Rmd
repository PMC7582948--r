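---
title: "Measuring threat-probability and fear-output coding in single units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring threat-probability and fear-output coding in single units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threatcode)
```

## The scientific problem

In Pavlovian fear discrimination over a baseline of rewarded nose poking,
three auditory cues predict distinct foot-shock probabilities: danger
(p = 1.00), uncertainty (p = 0.375) and safety (p = 0.00). A 10 s cue is
followed, on shocked trials, by a foot shock 2 s after cue offset. A session
contains 32 trials in randomized order: 6 danger, 6 uncertainty-shock, 10
uncertainty-omission and 10 safety. Because the animal cannot know the
outcome of an uncertainty trial during the cue, the two uncertainty subtypes
are collapsed for cue-period analyses.

Fear on each trial is read out as conditioned suppression of nose poking,

$$\mathrm{ratio} = \frac{r_\mathrm{baseline} - r_\mathrm{cue}}
                        {r_\mathrm{baseline} + r_\mathrm{cue}},$$

with the baseline rate from the 20 s before cue onset and the cue rate over
the 10 s cue, each trial using only its own baseline. A ratio of 1 means
complete suppression (high fear), 0 none.

Crucially, trained animals show *disproportionate* fear to uncertainty:
suppression to the uncertainty cue is far above 0.375 times the suppression
to danger. This non-linearity between shock probability and fear output is
what lets a trial-by-trial regression dissociate the two as explanations of
single-unit firing: a neuron may track how afraid the animal is (fear
output) or the objective shock probability of the cue (threat probability).

## The pipeline

### Suppression (`sessionSuppression`)

One record per trial with half-open counting windows. When a trial has no
pokes in either window the ratio is 0/0: the package records `NA` and the
trial drops out of means and of the fear-output regressor (the regression
then runs on the remaining trials). The alternative policy `ratio = 0` is
available via `zero_policy = "zero"`. There is no unbiased choice here —
which is why the zero-baseline case is surfaced in `run.log` rather than
silently imputed. At low baseline poke rates the measured ratio is also a
noisy, slightly biased estimate of the underlying fear level (counts are
small and the ratio is a non-linear function of them); with a 1 Hz baseline
(about 20 baseline pokes) the trial-level measurement noise on the ratio is
roughly 0.1–0.15 and the bias is small relative to it. Parameter-recovery
checks that need a nearly noiseless fear regressor therefore simulate
higher poke rates (see below).

### Peri-event binning and Z-normalization (`binTrial`, `znormUnit`)

Firing is counted in 250 ms half-open bins spanning −20 s to +30 s around
cue onset — 200 bins covering 20 s of baseline, the 10 s cue and 20 s after
offset. Per trial type, trials are averaged elementwise; each type's mean
trace is differenced against that type's own 2 s pre-onset baseline mean;
and a single (mu, sigma) per unit is computed over the concatenation of all
trial types' differential traces, each type contributing its 200 bins once
regardless of trial count. Normalizing over the whole epoch (rather than
baseline only) keeps nearly-silent-baseline units usable, at the cost that
normalized baseline activity need not be zero. A unit whose differential
traces never vary (sigma = 0) is flagged degenerate and excluded from all
normalized analyses.

Two distinct baselines are deliberately held apart: the 2 s window for
differencing traces, and the 10 s window used by the responsiveness screen.

For *single-trial* normalized firing, used by the encoding regression, the
construction at the mean-trace level does not pin down a unique recipe. The
package's default differs each trial's interval rate against the trial's
*own* 2 s pre-onset baseline and then applies the unit-level (mu, sigma).
This keeps single-trial values exactly consistent with the mean z traces
(a trial identical to its type mean reproduces the plotted trace value) and
removes slow drift trial-by-trial. The alternative — differencing against
the trial-type mean baseline instead — is available via
`baseline_mode = "type"`, and the choice is exposed end to end because the
two modes can matter for low-rate units.

### Cue-responsiveness screening (`classifyUnit`)

Per cue (danger, uncertainty collapsed, safety), per-trial raw rates (Hz)
in defined cue epochs are compared against the 10 s pre-cue baseline with
two-tailed paired t tests at the Bonferroni-corrected threshold 0.05/6 —
kept as the exact fraction, not the rounded 0.0083. A unit is *cue-excited*
if at least one screened epoch shows a significant increase and none a
significant decrease, *cue-inhibited* for the converse, and *outside
selection criteria* (osc) otherwise, including when both directions fire.

The epochs screened differ by direction in the default `"classwise"`
scheme: excitation looks at the first 1 s and last 5 s of the cue (phasic
onset responses and sustained late responses), inhibition at the first 5 s
and last 5 s (suppression builds more slowly than phasic excitation). A
`"uniform"` scheme (first 1 s / last 5 s for both) is provided because the
choice is defensible either way. Zero-variance paired differences admit no
t statistic; they are flagged and treated as non-significant rather than
dropped, which is conservative for the responsiveness call.

Under the default scheme a stationary Poisson unit is called responsive at
a rate of about 5% (union of six correlated tests per direction at 0.05/6);
the test suite verifies the rate stays at or below 0.06 over 2,000
simulated null units, and that effects of size d = 1.5 on epoch rates are
labeled correctly in at least 95% of simulations.

### Encoding regression and the threat-tuning curve (`unitBetaSeries`, `tuningCurve`)

For each 1 s interval of the cue ([k, k+1) s, k = 0..9), the unit's
normalized single-trial firing is regressed on a constant, the trial's fear
output (its 10 s suppression ratio) and the trial's threat probability
(danger 1.00, safety 0.00, uncertainty u). Regressors stay on their raw
scales — betas are per unit probability and per unit suppression ratio —
so beta magnitudes are comparable across units only because the response is
Z-normalized. Trials with missing suppression drop out; fewer than 8 usable
trials excludes the unit-session (logged); a rank-deficient design (e.g., a
constant fear column) yields a flagged minimum-norm solution.

The tuning curve repeats the whole per-interval analysis nine times with
u swept from 0 to 1 in 0.125 steps, averaging the threat beta over the ten
intervals at each u. For a population of cue-excited units the curve peaks
where the assignment best matches the probability the units' firing
actually assigns to the uncertainty cue.

One property of this statistic deserves emphasis. The fear and threat
columns are correlated (that is the point of the design), and the strength
and shape of that correlation depend on the behavioral suppression profile.
When suppression to uncertainty is disproportionately high relative to its
shock probability — exactly the profile trained animals show — the
population tuning curve's peak is pulled toward assignments *above* the
programmed probability. The package's tests demonstrate both regimes: with
behaviorally realistic suppression and a population internally weighted at
0.5, the peak is recovered at 0.500; with cleanly dissociable regressors
(precise fear measurement, wide within-cue fear variability) a population
weighted at the programmed 0.375 peaks at 0.375. Peak location should
therefore be interpreted jointly with the behavioral profile, not as a
pure readout of neural tuning.

### Population statistics (`chiSquare2x2`, `mixedAnova`, `bonferroniT`, `pearsonCoupling`, `fisherRtoZ`)

Responsive proportions between groups are compared with the uncorrected
Pearson chi-square on one degree of freedom. Group-by-condition firing and
beta analyses use the standard univariate mixed-design ANOVA: the
between-group effect is tested against subjects-within-groups, each within
effect against its effect-by-subjects stratum, with partial eta squared
(SS\_effect / (SS\_effect + SS\_error)) as the effect size and no
sphericity correction. With unequal group sizes the standard unweighted
decomposition applies — the balanced-design behavior is exact (verified
against a hand-worked decomposition), the unbalanced case is a documented
approximation. Observed power, an artifact of a particular software
tradition, is deliberately not reported. Firing/signaling coupling is the
Pearson correlation (with least-squares line) between per-unit normalized
epoch firing and per-unit betas, compared across groups with the Fisher
r-to-z statistic.

## The synthetic session generator

No public recordings accompany the analyses, so the generator is the
package's ground truth, and its defaults are the study conditions:

* **Task** (`taskConfig`): 10 s cues, shock 2 s after offset, 32 trials
  (6/6/10/10), shock probabilities 1.00/0.375/0.00. Inter-onset gaps are
  compressed to `pre + cue + post` plus a 5 s margin (55 s): the behavioral
  task spaces trials by minutes, but every analysis lives in the
  [−20, +30] s peri-onset window, so longer intervals only add dead time.
  Shock responses are not simulated — all analyses target the cue period.
* **Behavior** (`behaviorParams`): nose poking is piecewise-homogeneous
  Poisson at 1 Hz baseline. During a cue the rate is thinned by
  (1 − s)/(1 + s), where s = clamp(target + N(0, 0.15), 0, 1) is the
  trial's true fear level drawn once per trial. The thinning inverts the
  suppression-ratio formula, so s lives on the ratio scale and targets are
  directly comparable to measured ratios — and a simulated "fear-output
  coder" codes the same quantity the regression later uses. Default targets
  (danger 0.9, uncertainty 0.6, safety 0.1) reproduce the trained-rat
  pattern of high, disproportionate-to-probability, and low suppression.
* **Units** (`unitSpec`): inhomogeneous Poisson. Within the cue, each
  250 ms bin fires at max(0, baseline + profile × (threat\_gain × p +
  fear\_gain × s + eps)), with p the unit's internally assigned probability
  (danger 1, safety 0, uncertainty = its internal weight), s the trial's
  fear level and eps a once-per-trial rate offset — noise enters per trial,
  not per bin, matching the trial-by-trial structure the regression
  targets. Defaults: 5 Hz baseline, 8 Hz threat gain, a flat cue profile
  with a 1.5× first-second onset boost, 1 Hz trial noise. Inhibited units
  use negative gains; rates clamp at zero.
* **Cohort** (`cohortConfig`): 8 Con and 12 EAA rats by default, with
  per-group distributions over unit parameters. All randomness derives from
  one master seed through stable string-keyed sub-streams (group, rat,
  session, unit), so any subset of a cohort is individually reproducible
  and two runs are byte-identical. Before simulating, the generator asserts
  that the suppression targets keep the fear and threat regressor columns
  dissociable (|r| < 0.95 over the trial multiset) and refuses otherwise.

What the generator does *not* emulate: learning across sessions, reward
schedule microstructure, shock-evoked firing, bursting/refractory spike
statistics, waveform information, or electrode drift. Passing tests
therefore show the *analysis* is correct and well-calibrated under Poisson
assumptions with trial-level noise — not that real vlPAG/DR data meet those
assumptions.

## Numerical choices

* All counting windows and bins are half-open [a, b); events on a boundary
  belong to the right-hand bin. Epoch rates computed from raw spikes and
  from bins tiling the epoch agree exactly for grid-aligned epochs.
* OLS is solved by QR (`lm.fit`); rank deficiency falls back to the
  flagged minimum-norm (pseudoinverse) solution.
* Z-normalization uses the sample SD (n − 1) over the 600 concatenated
  bins (3 collapsed types × 200); the normalization identity (mean 0,
  SD 1) is enforced to 1e−9 by a validity method on the traces object.
* Suppression 0/0 → `NA` (default) with a configurable 0; zero-variance
  paired t → p = 1 with a flag; degenerate units → excluded and logged.
* Output CSVs round floats to 6 significant digits deterministically, so
  identical inputs re-produce byte-identical files.

## Problem sizes in the test suite

The suite simulates at desk scale: 2,000 stationary null units for the
classifier's false-positive rate, 150 units per direction for its power,
50 units per coder class for beta recovery, 48 units for the tuning-peak
experiment, 200 datasets for ANOVA null calibration, and 1,000 random
problems for the OLS oracle. These sizes give Monte-Carlo standard errors
comfortably inside each assertion's tolerance; re-running with larger
populations only tightens them. Recovery tests use deliberately favorable
measurement conditions (20 Hz poke baseline, within-cue fear SD 0.3): with
realistic 1 Hz poking, measurement error in the fear regressor leaks into
the correlated threat column and per-unit betas become individually noisy —
a real limitation of the trial-by-trial design worth keeping in mind when
interpreting single-unit betas from modest sessions.

## Known limitations

* The single-trial normalized firing construction is a package choice
  among several consistent with the mean-trace definition; both modes are
  exposed and the default is the one consistent with the plotted traces.
* The mixed ANOVA's unbalanced-group behavior follows the standard
  unweighted decomposition; software traditions differ here and no exact
  target behavior is defined.
* The tuning-curve peak is a population statistic whose location is
  biased toward higher assignments under strongly non-linear fear
  profiles (see above); single-unit peak locations are far noisier than
  the population peak.
* Suppression ratios from low poke rates are noisy and slightly biased;
  the package quantifies but does not correct this.
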