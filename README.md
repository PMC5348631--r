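# tagdisc

Behavioural analysis toolkit for delay-discounting experiments in which
delayed rewards can carry an **episodic tag** — a concrete imagined future
event (e.g. meeting a named person in a café on the delivery date).
`tagdisc` is written for cognitive-neuroscience and decision-science
researchers who run (or simulate) such paradigms and want a tested,
reproducible pipeline from trial-level CSVs to group-level statistics.

## What it computes

The core is the hyperbolic-discounting choice model with softmax action
selection. The subjective value of an amount *A* delayed by *D* days under
discount rate *k* is Mazur's hyperbola

    SV = A / (1 + k·D)

and the probability of choosing the delayed option over a fixed immediate
reference *R* (20 €) is

    P(delayed) = 1 / (1 + exp(−(SV − R)/β))

with β a decision-noise *temperature* in euros (larger β = noisier
choice; the inverse-temperature convention is τ = 1/β). Per condition,
(k, β) are fitted by multi-start bounded maximum likelihood
(`fit_mle()`); group statistics use √k.

Around the model the package provides:

* **Adaptive design** (`build_session()`): the participant-specific
  schedule that pairs six delay pairs (1–190 days) with six amounts
  bracketing each indifference point `A* = R(1 + kD)`, 36 trials per
  block, six blocks with paired condition ordering, amounts on a 0.5 €
  grid inside [20.5, 79.5] €.
* **Synthetic cohorts** (`simulate_cohort()`): generative truths plus all
  three data streams (choices, visual-search trials, paired-rater
  interview tallies) with a controllable correlation between attentional
  control and the per-subject tag effect.
* **Behavioural scores**: the singleton attentional-control index
  (`singleton_score()`: flexible-condition distractor cost minus
  strategic-condition cost, higher = poorer flexible control),
  autobiographical-interview detail tallies (`tally_details()`) and
  two-rater reliability (`cronbach_alpha()`).
* **Group statistics** (`fit_all_subjects()`, `rm_anova()`, `paired_t()`,
  `covariate_adjusted_correlation()`, `analyze_cohort()`): per-condition
  and pooled-tag fits, the within-subject condition ANOVA on √k, and
  gender-adjusted partial correlations linking the singleton score to the
  tag effect.
* **I/O and pipeline**: typed CSV readers/writers for all three table
  schemas, a YAML/JSON run config, stage functions
  (`run_simulate()` … `run_analyze()`), and a thin CLI at
  `inst/cli/tagdisc.R` (exit codes 0/1/2).

Fits are plain R objects with `tidy()`/`glance()` methods and an
`autoplot()`; most functions take a data frame first and return tibbles,
so stages chain with the pipe.

## Worked example

```r
library(tagdisc)
library(dplyr)

# A participant-specific schedule from a pretest discount rate
sched <- build_session(k = 0.085, seed = 1)
head(sched, 4)
#>   block_index trial_index condition partner_slot delay_days amount_eur
#> 1           1           1 control              1        190       77.5
#> 2           1           2 control              2         13       52.5
#> 3           1           3 control              1          2       20.5
#> 4           1           4 control              2          7       40

# Simulate a chooser on it and fit one condition
trials <- simulate_choices(sched, k = 0.085, beta = 2, seed = 2)
fit <- fit_mle(filter(trials, condition == "control"))
fit
#> Hyperbolic-softmax discounting fit (control)
#>   k = 0.0951 per day   sqrt(k) = 0.3084   beta = 1.782 EUR
#>   nll = 17.300 over 72 trials (22 delayed), converged: TRUE
```

The fitted `k = 0.095` recovers the generating rate 0.085 from 72 trials
(the residual gap is sampling noise at this trial count), and `beta`
recovers the injected noise temperature 2 €. A full synthetic cohort runs
through the group pipeline the same way:

```r
coh    <- simulate_cohort(cohort_spec(n_subjects = 8, seed = 42))
fits   <- suppressWarnings(fit_all_subjects(coh$choices))
scores <- score_attention(coh$attention) |>
  inner_join(coh$subjects[, c("subject_id", "gender")], by = "subject_id")
analyze_cohort(fits, scores)
#> Condition RM-ANOVA: F(2, 14) = 0.321, p = 0.73
#> Singleton score vs tag effect (gender-adjusted): r = -0.833, p = 0.0199
```

With the default generator (no *mean* tag effect, but a strong negative
coupling ρ = −0.67 between attentional control and the per-subject tag
effect) the condition ANOVA is null while the singleton-score correlation
is large and negative — poorer flexible attentional control goes with a
smaller episodic reduction of discounting. At n = 8 the correlation
estimate is noisy; calibration at realistic sizes is what the test suite
checks.

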