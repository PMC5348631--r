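---
title: "Modelling episodic-tag effects on delay discounting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling episodic-tag effects on delay discounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdisc)
library(dplyr)
```

## The scientific problem

People devalue rewards that are delayed. In intertemporal-choice
experiments a participant repeatedly chooses between a fixed immediate
amount (here 20 €) and a larger delayed amount, and the steepness of the
devaluation — the *discount rate* — indexes impulsivity. Pairing the
delayed option with a concrete imagined future episode (an "episodic tag",
e.g. meeting a named person in a café on the delivery date) can reduce
discounting; whether it does so may depend on a person's ability to
flexibly control attention, measured independently with a visual-search
task. `tagdisc` implements the full behavioural analysis chain for such
experiments: the choice model and its maximum-likelihood fit, the adaptive
trial-schedule construction, the attentional-control and interview scores,
the group statistics, and a synthetic-cohort generator so that every stage
can be validated without human data.

## The choice model

Subjective value follows Mazur's hyperbola,

$$SV = \frac{A}{1 + kD},$$

with $A$ the delayed amount in euros, $D$ the delay in days and $k \ge 0$
the discount rate per day. Choices are probabilistic via a softmax
(logistic) rule on the value difference to the immediate reference $R$:

$$P(\text{delayed}) = \frac{1}{1 + e^{-(SV - R)/\beta}}.$$

**The noise parameter is a temperature.** $\beta$ is in euros: it is the
value gap at which a chooser moves from indifference to choosing the
better option with probability `plogis(1)` $\approx 0.73$. Larger $\beta$
means *noisier* choice, and $\beta \to 0$ a deterministic maximiser. Some
toolboxes instead multiply the value gap by an inverse temperature
$\tau$; the two conventions are related by $\tau = 1/\beta$, and absolute
noise-parameter values are not comparable across them. We adopt the
temperature convention so that "greater $\beta$ = more decision noise"
reads correctly.

Per condition, $(k, \beta)$ are estimated by maximum likelihood
(`fit_mle()`). Numerical choices:

* **Bounds**: $k \in [10^{-6}, 2]$ per day and $\beta \in [10^{-3},
  10^{3}]$ € — generous boxes around plausible adult values (group medians
  sit near $k \approx 0.08$, $\beta \approx 2\!-\!3$).
* **Optimiser**: L-BFGS-B on $(\log k, \log \beta)$ with an analytic
  gradient, restarted from every node of an $8 \times 8$ log-spaced grid
  spanning the bounds; the best start wins. The log parameterisation keeps
  the box well conditioned across three orders of magnitude.
* **Clipping**: per-trial probabilities are clipped to $[10^{-9},
  1-10^{-9}]$ before the log so the objective stays finite at extreme
  parameters; clipped trials are counted and reported on the fit object.
* **Degenerate data**: a subject who always chooses the same option
  cannot identify the parameters. `fit_mle()` returns the relevant $k$
  bound (lower for all-delayed, upper for all-immediate) with
  `converged = FALSE` and a warning instead of erroring, mirroring how
  such subjects would otherwise silently pin the optimiser to its box.
* **Ties**: at $SV = R$ the rule gives $P = 0.5$; no tie-breaking is
  needed under a probabilistic model.

Group statistics operate on $\sqrt{k}$ (`transform_k()`) because $k$ is
strongly right-skewed across subjects.

```{r fit-demo}
sched <- build_session(k = 0.085, seed = 1)
trials <- simulate_choices(sched, k = 0.085, beta = 2, seed = 2)
fit <- fit_mle(filter(trials, condition == "control"))
fit
tidy(fit)
```

## The adaptive schedule

The session builder reproduces the titration logic of the task: a pretest
discount rate determines, for each delay, the *indifference amount*
$A^* = R\,(1 + kD)$ at which the delayed and immediate rewards are
subjectively equal; each delay is then paired with six amounts bracketing
$A^*$. Concretely:

* **Delays**: six positions, each drawing its concrete delay uniformly
  from a fixed pair — [1, 2], [6, 7], [13, 15], [28, 32], [85, 95],
  [170, 190] days.
* **Ladder**: symmetric offsets of ±10 %, ±25 % and ±45 % around $A^*$.
  The source design specifies only that amounts lie "equally above and
  below" the indifference point between roughly half-euro extremes; these
  three offsets span close to the extremes while keeping symmetry, and
  are configurable. Amounts are rounded to 0.5 € and clamped into
  [20.5, 79.5] €; collisions created by clamping are nudged apart on the
  0.5 € grid, so symmetry is guaranteed before clamping, not after.
* **Crossing**: each block crosses the six delay positions with their
  six-amount ladders (36 trials); we fix six trials per delay pair as the
  only reading consistent with a full 6 × 6 amount-by-delay crossing. The
  partner slot (which of the two named persons, or placeholder strings in
  the control condition, accompanies a trial) alternates
  deterministically; no balancing rule beyond alternation is imposed.
* **Session**: six blocks — two consecutive blocks per condition with the
  condition order randomised (AABBCC over a random permutation of
  control / familiar / unfamiliar), 216 trials in total.

Everything is a pure function of `(k, seed)`: the same inputs reproduce a
byte-identical schedule CSV.

### How balanced are choices under this design?

When the indifference amount is representable — i.e. $A^* \le 79.5$,
equivalently $kD \le 2.975$ — a chooser whose $k$ matches the
construction rate picks the delayed option on half the trials of that
delay, because the ladder is symmetric and the softmax is symmetric
around $A^*$. At 180 days this requires $k \lesssim 0.0165$ per day.
For steeper discounters the two long-delay pairs fall outside the
admissible amount range: every allowed amount is then clearly worse than
the immediate reward and those trials are near-deterministically
immediate. At $k = 0.085$ (a typical older-adult median) the overall
delayed-choice proportion of a matched simulated chooser is therefore
about 34 %, not 50 % — the 50 % balance holds per bracketable delay, not
globally, whenever the participant discounts too steeply for the printed
amount cap. This is a property of the published design parameters
themselves, not of the implementation, and the acceptance checks report
the honestly simulated value.

## The synthetic cohort generator

`simulate_cohort()` produces cohorts with the covariance structure the
analysis is designed to detect, so that recovery and calibration can be
tested end to end. Per subject it draws generative truths and then all
three data streams (choice trials on the subject's own adaptive schedule,
singleton visual-search trials, paired-rater interview tallies). Defaults
describe an older-adult sample and were fixed once, from published
summary statistics, before any downstream checks:

| parameter | default | why |
|---|---|---|
| `n_subjects` | 22 | typical single-group sample (condition df 2, error df 42) |
| `sqrt_k_mean` | $\sqrt{0.085} \approx 0.2915$ | square root of a typical control-condition median rate |
| `sqrt_k_sd` | 0.15 | reproduces an inter-quartile range of $k$ near 0.2 |
| `tag_effect_mean` | 0 | older adults show no mean tag effect |
| `tag_effect_sd` | 0.10 | between-subject spread needed for individual-differences analyses |
| `cond_noise_sd` | 0.02 | session-level variability; small because discount rates are trait-like |
| `rho` | −0.67 | target coupling between attentional control and the tag effect |
| `beta_meanlog`, `beta_sdlog` | log 2.5, 0.8 | lognormal noise temperatures with medians 2–3 € |
| `singleton_mean`, `singleton_sd` | 71.34, 89.29 ms | published singleton-score moments |
| `base_rt_ms`, `strategic_cost_ms`, `rt_noise_sd` | 900, 30, 150 ms | plausible search RTs; strategic distractor cost small and ability-independent |
| `error_rate` | 0.0452 | reproduces the reported ~4.5 % exclusion rate |
| `interview_rates` | per-category Poisson rates | published per-event category means (the `time` category carries ~0 details and defaults to rate 0) |
| `rater_noise_sd` | 1.1 per cell | puts simulated inter-rater alpha near the reported 0.81 |
| `memory_mean`, `memory_sd` | 47.5, 10.34 | verbal-learning sum-score moments |

The tag effect $\delta_i$ (in $\sqrt{k}$ units) and the true singleton
score are drawn jointly bivariate-normal with correlation `rho`; both tag
conditions share $\delta_i$, and each condition additionally receives an
iid $N(0, \texttt{cond\_noise\_sd})$ deviation so that a zero-effect null
cohort is non-degenerate for the repeated-measures ANOVA. Simulated
$\sqrt{k}$ values are truncated into the fitting bounds.

Distributional forms (normal $\sqrt{k}$, lognormal $\beta$ and RTs,
Gaussian RT noise, Poisson tallies) are modelling conveniences centred on
published summaries — the source reports summaries, not distributions.
The generator deliberately does **not** emulate several features of real
data: choice RTs are independent of the value gap, there is no
within-session drift or fatigue, search errors are independent of RT, and
interview counts have no subject-level random effect. Passing recovery
tests therefore shows the pipeline is correct and well calibrated under
the assumed structure, not that real data meet those assumptions.

## Behavioural scores

* **Singleton score** (`singleton_score()`): distractor cost (mean RT
  distractor-present minus distractor-absent, over valid trials) in the
  flexible condition minus the same cost in the strategic condition;
  higher = poorer flexible control. Error trials, missing responses and
  responses beyond the 3000 ms window are excluded
  (`filter_singleton_trials()`), with the exclusion percentage pooled
  over conditions. Flexible-condition trials on which the singleton is
  itself the target are excluded from the cost means: the cost is defined
  for the coloured *distractor*, and target-singleton trials contain no
  such distractor. RT central tendency is the arithmetic mean by default
  (`center = median` is available).
* **Interview details** (`tally_details()`): counts per category — time,
  place, perceptual, emotion/thought, event (internal = their sum) and a
  pooled external score — summarised per familiarity over events.
  Inter-rater reliability (`cronbach_alpha()`) treats the two raters as a
  two-item scale over per-event internal (separately, external) totals;
  the item unit is configurable via `rater_totals()` since the level at
  which reliability is computed is a genuine free choice.

## Group statistics

* `fit_all_subjects()` fits each condition separately plus a pooled
  **tag** parameter refit on the concatenated familiar + unfamiliar
  trials — a single likelihood over all tagged trials rather than an
  average of two fits, so all 144 trials inform one estimate.
* `rm_anova()` is the one-way within-subject F-test
  (`aov(value ~ condition + Error(subject))`); no sphericity correction
  is applied by default, with Greenhouse–Geisser available as an option
  (`correction = "greenhouse-geisser"`, epsilon from the condition
  covariance matrix).
* `covariate_adjusted_correlation()` residualises both variables on the
  covariates (gender, coded as a binary indicator) and correlates the
  residuals, with $df = n - 2 - \#\text{covariates}$. Gender enters the
  correlations by residualisation; it is not modelled inside the
  repeated-measures ANOVA, where the available information does not
  support a specific mixed-model formulation.

```{r group-demo}
coh <- simulate_cohort(cohort_spec(n_subjects = 6, seed = 42))
fits <- suppressWarnings(fit_all_subjects(coh$choices))
discount_summary_table(fits, coh$choices)
```

## Validation strategy and problem sizes

The package's checks are design-property and recovery based, at sizes
chosen to give stable Monte-Carlo estimates on a single core:

* likelihood optimum vs a 200 × 200 $(k, \beta)$ grid on 50 random
  72-trial fixtures (the grid is recomputed with independent inline
  arithmetic);
* $\sqrt{k}$ recovery over 100 simulated subjects with full 216-trial
  sessions (correlation with truth ≥ 0.9; median signed bias within
  ±0.02);
* repeated-measures ANOVA type-I calibration over 1000 null cohorts and
  correlation recovery at $\rho = -0.67$ over 500 cohorts, both run on
  the generator's subject-level truths (`include = character(0)`), which
  is what those two checks are about — the calibration of the statistics
  and the generator's covariance structure;
* exact closure tests: a noiseless singleton simulation returns the
  injected cost difference identically, and identical raters give
  $\alpha = 1$.

## Known limitations

* Only the Mazur hyperbola is implemented; exponential or
  quasi-hyperbolic discounting, hierarchical/Bayesian estimation and RT
  modelling of choices are out of scope.
* The 50 % choice-balance property of the adaptive design fails for
  steep discounters (see above); analyses of such participants rest
  mostly on the four short-delay pairs.
* The pooled-tag refit assumes the two episodic conditions share one
  $(k, \beta)$; per-condition fits are always available alongside.
* `cronbach_alpha()` with two raters is algebraically close to a
  consistency-type intraclass correlation; absolute-agreement variants
  are not provided.
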