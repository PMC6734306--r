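---
title: "Diagnosing menstrually related migraine from headache diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing menstrually related migraine from headache diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmdiary)
```

## The attack model

`mmdiary` treats a woman's migraine history as a two-state Markov chain
observed once per day. From the *susceptible* state an attack starts with
per-day probability $\mu$; an ongoing attack continues with probability
$\delta$ and otherwise ends, returning the subject to susceptibility the
next day. Attack durations are therefore geometric with mean
$1/(1-\delta)$ days. Menstrually related migraine is expressed as a split
of the onset probability: $\mu^{M}$ on the five perimenstrual days
(bleeding day $1 \pm 2$) and $\mu^{NM}$ elsewhere, with association
meaning $\Delta\mu = \mu^{M} - \mu^{NM} > 0$.

The parameters and their units:

| parameter | meaning | default in simulations |
|---|---|---|
| $\mu^{NM}$ | onset probability / day, outside windows | 0.045 |
| $\mu^{M}$ | onset probability / day, inside windows | 0.244 |
| $\mu$ | flat onset probability for null subjects | 0.083 |
| $\delta$ | continuation probability / day | 0.444 (mean duration 1.8 d) |
| $\alpha$ | sMM significance cut-off, $0<\alpha<0.5$ | 0.1 |

The simulation defaults are empirical subgroup means from a clinical
diary cohort: the onset probabilities of women receiving both diagnoses
(for the association arm) and of women receiving neither (for the null
arm), and the pooled mean attack duration. Published summary values are
percentages per day; they are used here as probabilities (divided by
100), since per-day transition probabilities above 1 are meaningless.

## Why days cannot be counted directly

An exact conditional test on *migraine days* assumes each day is an
independent draw, but attacks make migraine days cluster (about half of
attacks span more than one day at $\delta \approx 0.44$). The test then
rejects too often. The remedy is to test only the days that inform
$\mu$:

1. **Locked-day imputation.** A non-migraine day sandwiched between two
   migraine days is part of one attack under the 48-hour relapse rule and
   is imputed as migraine, iteratively to a fixed point.
2. **Trimming.** Days on which an attack is ongoing are removed, as are
   the two days after each attack's end (an onset recorded there would be
   a relapse, and such runs are merged back into the preceding attack);
   attacks whose first day is the first retained diary day have no
   observable onset and are removed wholesale.

Every retained day is classified `SUSCEPTIBLE` or `ATTACK_START`; these
are the $N$ classifiable days. With $K$ of them inside menstrual windows,
$n$ onsets, $k$ of those in windows, the one-sided mid-p value is

$$p = \sum_{i=k}^{\min(n,K)} f_{\mathrm{HG}}(i;K,n,N) -
      \tfrac12 f_{\mathrm{HG}}(k;K,n,N),$$

the upper hypergeometric tail minus half the point mass. The mid-p
correction is justified because $n$ is itself random before the diary is
observed; the plain tail probability is exposed only for diagnostics and
never drives a diagnosis. The test is one-sided because only an elevated
in-window onset rate is clinically interesting. A diary where every
classifiable day, or none, lies in a window ($K=0$ or $K=N$) carries no
contrast and is flagged non-evaluable rather than scored.

**sMM($\alpha$)** declares a subject positive when $p < \alpha$. On
subjects with no true association the positive rate is $\alpha$ by
construction, for any attack-clustering behaviour — this is the
criterion's central guarantee, and the test suite verifies it by
simulation.

The ICHD-style **2/3 criterion** is implemented as: an attack *onset*
inside at least two thirds of *all* recorded windows (not a sliding
two-of-three-consecutive rule — the fraction form is what the published
formulation states, and it extends naturally past three cycles). Overlap
of an ongoing attack with a window does not count; at least three windows
are required for the verdict.

## Preprocessing of clinic diaries

Raw diaries pass through a fixed pipeline before diagnosis
(`preprocess_diary()`):

* cycle lengths are onset-to-onset day differences;
* cycles longer than twice the subject's mean cycle length (one pass,
  mean over all her cycles) indicate missing data; the longest remaining
  run of at least three consecutive typical cycles is kept, ties broken
  toward the earliest. A diary without such a run is excluded
  (`too_few_cycles` / `atypical_unsalvageable`);
* the diary is truncated 15 days before the first and 15 days after the
  last registered bleeding day and re-anchored at day 1;
* locked days are imputed.

The pipeline is idempotent. Two points were genuinely open and decided
here: when a salvageable run is cut out, a 15-day margin is kept on each
side so truncation behaves as for an untouched diary; and a bleeding day
on diary day 1 counts as an onset but its window is flagged partial,
since the true onset may precede observation.

## The simulator

`simulate_diary()` draws the chain day by day: onset with $\mu^{M}$ or
$\mu^{NM}$ (flat $\mu$ for null subjects) from susceptibility,
continuation with $\delta$ during attacks, menstrual state ignored while
an attack runs. Layouts place each cycle as 23 windowless days followed
by the 5 window days (28-day cycles), bleeding on the window's middle
three days so that window detection recovers the layout exactly, plus a
10-day windowless tail after the last cycle. Cycle length within a
subject is fixed; between-cycle variability, treatment effects and aura
are not modelled. Parameter distributions are point masses at the
defaults above (an optional log-normal spread is available), so
population-level results are deterministic up to Monte-Carlo error under
a fixed seed; each diary gets a sub-seed derived from the population seed
and its index, making results independent of evaluation order.

What passing simulation tests shows, and what it does not: the simulator
reproduces the *statistical* structure the criteria assume (geometric
attacks, window-modulated onsets, exact 28-day cycles). Real diaries add
irregular cycles, missed entries, reporting errors and day-boundary
ambiguities that are not emulated, so simulation results quantify the
criteria's behaviour under the model, not their field performance.

## The criteria-comparison study

`roc_study()` simulates, for each cycle count from 3 to 9, an
association arm and a null arm (default 2 000 diaries each in the
acceptance runs; 10 000 reproduces the original study scale), diagnoses
every diary label-free, and traces ROC curves: sMM by sweeping $\alpha$
over $(0, 0.5)$, the 2/3 rule by sweeping its window-fraction threshold
over $[0,1]$ with the canonical 2/3 point reported separately (the rule
is intrinsically binary; the sweep makes an AUC well defined). AUC is
trapezoidal over the swept staircase with corner augmentation. Every
sensitivity/specificity carries a binomial Monte-Carlo standard error and
comparisons in tests use 3-SE tolerances (Hanley–McNeil for AUCs).

Across the sweep the sMM criterion dominates: its AUC exceeds the 2/3
rule's at every cycle count and increases monotonically with more cycles,
while the 2/3 rule is most sensitive at exactly three cycles and trades
sensitivity for specificity as cycles accumulate — the discreteness of
"two of three" cannot convert extra information into sensitivity. These
statements are exactly what the acceptance test suite asserts; no numeric
AUC value is promised beyond them.

## Numerical and design notes

* The hypergeometric pmf is evaluated in log space via `stats::dhyper`;
  diaries of several hundred days stay exact to floating precision. An
  exhaustive-enumeration oracle validates the mid-p tail for all tables
  with $N \le 12$ in the test suite.
* $\hat\mu = n/N$, $\hat\mu^{M} = k/K$, $\hat\mu^{NM} = (n-k)/(N-K)$ from
  the trimmed counts; empty denominators yield `NA`, never 0.
  $\hat\delta$ is continuation days over attack days in maximal recorded
  migraine runs with an observed start. On raw simulated diaries these
  estimators recover the generating values with bias vanishing in diary
  length; after locked-day imputation of real diaries $\hat\delta$
  describes the merged 48-hour-rule attacks, which is the clinically
  intended object but sits above the raw chain value.
* A migraine day falling on a refractory day is merged into the previous
  attack rather than counted as a new onset; the original formulation is
  silent here and the 48-hour relapse definition motivates the merge.
* Attacks truncated by the diary's end still count as onsets (the onset
  is observed; only missing starts disqualify).
* Window membership of a trimmed day uses the original day index —
  trimming removes days from the count, it never renumbers.
* Non-evaluable diaries score $p = 1$ in ROC sweeps (never positive) so
  arms keep their full denominator.

## Problem sizes

The shipped tests run the size check on 2 000 null diaries of four cycles
and the comparison study at 2 000 diaries per arm for cycle counts 3–9
(28 000 diaries total), chosen to put three Monte-Carlo standard errors
near two percentage points on any rate; parameter-recovery checks use
300–400 diaries of 6–9 cycles. The whole suite completes in about two
minutes on one core.

## Limitations

The temporal unit is the day; sub-daily timing, severity, aura and
hormonal-contraception effects are out of scope, as is the distinction
between pure and menstrually related migraine (a strong association is
detected either way). The sMM criterion certifies association, not
attack burden or regularity; studies needing both should conjoin it with
the 2/3 rule.
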