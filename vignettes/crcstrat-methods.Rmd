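---
title: "Model and methods behind crcstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind crcstrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`crcstrat` simulates colorectal cancer (CRC) natural history and fecal
immunochemical test (FIT) screening at the individual level, to compare
screening strategies that differ in start age by sex while holding the mean
number of offered screening episodes per person fixed. This vignette is the
package's own account of the model, its parameters, the synthetic inputs,
the numerical choices, and the design decisions that were genuinely open.

## The disease model

Every simulated person enters at age 30 with normal colorectal epithelium
and is advanced in annual cycles to age 100 or death. Undiagnosed disease
follows the strictly sequential chain

> normal → low-risk adenoma → high-risk adenoma → CRC A → B → C → D

with at most one step per year; there is no regression and no direct
normal→CRC shortcut (a missed-adenoma pathway would be an additional
assumption, deliberately not introduced). Death from other causes can occur
from any state; undiagnosed CRC can present symptomatically with a
stage-specific annual probability, which freezes the underlying stage and
switches the person onto CRC survival indexed by stage at diagnosis and
year from diagnosis (bands 0, 1, 2, 3, 4, 5+). The two death states are
absorbing.

**Within-cycle event order** (the model contract; any fixed order is
defensible, but one must be fixed for reproducibility):

1. other-cause death,
2. natural-history progression (one chain step),
3. the screening episode, if any, plus due surveillance colonoscopies,
4. symptomatic presentation of undiagnosed CRC,
5. CRC death among the diagnosed,
6. cost and QALY accrual at cycle end.

Screening sits between progression and presentation so that screen
detection pre-empts symptomatic presentation within the same year; a person
detected at screening is diagnosed at the current underlying stage, with no
additional stage-shift benefit. There is no half-cycle correction: costs
and QALYs accrue at cycle end and are discounted by `(1 + r)^-t` with `t`
the cycle index anchored at model start (age 30). Anchoring at model start
rather than screening start was an open choice; model start is the exposed
default because it makes the discounting of the whole life course
independent of the strategy being evaluated.

## The parametric natural-history family

The probability tables are generated from seven parameters (see
`theta_template()`):

| parameter     | meaning                                                        | default |
|---------------|----------------------------------------------------------------|---------|
| `log_onset`   | log annual onset hazard (normal → low-risk adenoma) at age 50, men | solved (≈ −5.37) |
| `onset_slope` | log-hazard slope per year of age, plateau at age 85            | 0.07 |
| `sex_shift`   | years by which the female onset hazard lags the male           | solved (≈ 4.9) |
| `p_lr_hr`     | annual probability low- → high-risk adenoma                    | 0.05 |
| `p_hr_crc`    | annual probability high-risk adenoma → CRC A                   | 0.04 |
| `p_prog`      | annual probability of each CRC stage transition                | 0.35 |
| `pres_scale`  | multiplier on stage-specific presentation (0.08/0.18/0.35/0.60 for A–D) | 1 |

The slope 0.07/year doubles incidence roughly every decade, the standard
shape of registry CRC incidence below the plateau; the dwell times implied
by the adenoma rates (mean ~20 years in the low-risk state) match the
usual order of magnitude quoted for the adenoma–carcinoma sequence. The
two "solved" entries are root-found internally (`default_theta()`) so that
the deterministic cohort model reproduces the anchoring constraint: male
ten-year cumulative incidence of diagnosed CRC from age 56 equals the
configured value (0.85% by default), and the female value from age 60
matches it. The solved female shift (≈ 4.9 years) exceeds the naive 4-year
gap because women face lower competing mortality, which raises cumulative
incidence at equal rates. A `sex_effect` switch scales the shift: 0 removes
every sex difference from the disease process (including, for exact
symmetry, the life-table gap), and raising it can only raise the
male-to-female incidence ratio, by construction.

CRC survival after diagnosis uses annual death probabilities
0.02/0.06/0.18/0.45 for stages A–D scaled by a declining year-from-diagnosis
multiplier (1.2, 1.0, 0.75, 0.55, 0.4, 0.25); other-cause mortality is a
Gompertz table with female probabilities 0.75 of male. Both are synthetic
placeholders with realistic shape, not estimates.

## Calibration

`calibrate()` matches model **outputs** — age/sex incidence rates, adenoma
prevalence, undiagnosed CRC prevalence in 5-year bands 40–84, plus the two
cumulative-incidence constraint rows (weight 10 versus 1) — not latent
rates: identifiability of individual transition probabilities is not
claimed, and recovered parameter vectors routinely trade off `p_lr_hr`
against `p_hr_crc` while reproducing every target curve.

The loss is a weighted sum of squared relative errors. Because every event
probability in the unscreened model depends only on (state, age, sex), the
expected summaries are computed exactly by deterministic cohort
propagation (`cohort_occupancy()`), which is what the default loss
evaluates — noiseless and roughly a thousandfold faster than a
microsimulated loss. `method = "microsim"` retains a simulated evaluator
(default 20,000 individuals per evaluation) whose loss at the generating
values sits at its Monte-Carlo noise floor; the cohort default is the exact
expectation of that evaluator, not an approximation to it.

The search is Latin-hypercube screening over box priors followed by
Nelder–Mead refinement of the best draw (free parameters optimised on a
logit-transformed unit box). Two bookkeeping rules make the search's
contract testable:

* LHS points are generated in fixed-size seeded blocks, so a larger budget
  evaluates a strict superset of a smaller one and the best loss can only
  improve with budget;
* any refinement budget left after convergence is spent on further LHS
  points, so the number of evaluated parameter sets always equals the
  budget exactly.

A parameter set is *accepted* when its largest absolute relative error
within each target class is at most the class tolerance (5% by default).
Zero acceptances produce a classed warning and a result object carrying the
best loss. Acceptance is verified in the test suite by re-simulating
accepted sets forward, not by trusting the search's bookkeeping.

## The synthetic inputs

The generator (`synth_inputs()`) emulates the *structure* and the stated
qualitative conditions of the English data this kind of analysis is built
on — an all-age-30 disease-free cohort with a 50/50 sex split; rising
incidence with a male excess anchored by the 0.85% constraint; FIT
sensitivity higher and specificity lower in men at every threshold, with
sensitivity rising and specificity falling as the threshold drops from 120
to 20 µg/g; screening uptake lower in men (0.52–0.59 versus 0.60–0.66 by
age band) — with all remaining magnitudes chosen once at plausible values.
It does **not** emulate baseline comorbidity, deprivation or ethnicity
structure, anatomical lesion site, serrated pathways, multiple synchronous
lesions, or real English unit costs and utilities; passing tests therefore
demonstrate correctness of the machinery and reproduction of the *stated*
structural conditions, not quantitative transferability to England.

Uptake is a persistent per-person propensity (one uniform draw at cohort
generation, compared to the sex/age uptake threshold at each invitation),
reproducing the never-attender correlation that independent per-episode
draws destroy; `per_episode_bernoulli` remains available as a config
option. Follow-up colonoscopy attendance uses the same table scaled by
0.85, drawn fresh per episode — a single propensity governing both would
make follow-up attendance a deterministic function of the kit-return
threshold.

Post-polypectomy surveillance maps the model's two adenoma classes onto a
configurable policy table: low-risk removals return to routine screening;
high-risk removals are re-examined at 1 year and then 3-yearly until two
consecutive clear examinations. Endoscopy complications (perforation
6×10⁻⁴, major bleed 1.2×10⁻³, death 6×10⁻⁵ per colonoscopy) are drawn
independently; a procedural death is attributed to other-cause mortality so
the CRC-mortality outcome stays interpretable.

## Strategies and resource parity

Schedules are biennial. The episode-parity end rule is encoded exactly as
stated for the programme being modelled: strategies starting at even ages
end at 74 for everyone; strategies starting at odd ages end at 73 in men
and 75 in women. An offered episode counts toward programme size whether or
not the kit is returned — parity is about the size of the offered
programme, and kit counts are reported separately. The whole scenario grid
(thresholds 20/80/120; mean starts 58/54/50; sex gaps 2/4/6/8) is
constructible from configuration, and every member passes
`assert_resource_parity()` (tolerance 0.1 episodes) against the uniform
strategy at its mean start age.

## Economics

Costs: FIT kit £6, colonoscopy £550, polypectomy £160, perforation £3,500,
major bleed £2,200; CRC treatment by age band, stage and year-from-diagnosis
band (e.g. stage-A year-0 £11,000 falling to £600/year from year 5).
Utilities: age-band baselines (0.94 at 30–39 declining to 0.75 at 90+) with
additive decrements for a CRC diagnosis (0.05/0.10/0.17/0.28 for stages A–D,
applied every year lived after diagnosis) and 0.10 in the year of an
endoscopy complication, floored at zero. "Late stage" means C/D (exposed as
config). Discounting is 3.5%/year for both costs and QALYs (scenario values
1.5% and 5%); the willingness-to-pay threshold is £20,000/QALY.

Strategies are always simulated with common random numbers: event draws are
indexed by (cycle, stream, individual position), so two strategies diverge
only where the strategies themselves act. This makes paired increments
nearly noise-free — a strategy whose schedule leaves one sex untouched has
*exactly* zero increments in that sex — and the probabilistic sensitivity
analysis shares the event seed across strategies within each parameter
sample. PSA draws perturb their base inputs through the ratio of the draw
to its distribution mean, so the distributions are centred on the
deterministic point estimates and an all-`fixed` PSA collapses exactly to
the deterministic comparison.

## Problem sizes

Point-estimate comparisons use cohorts of 100,000 per arm (a lifetime
simulation takes a few seconds); calibration uses a budget of 2,000 loss
evaluations (~40 s with the cohort evaluator); the PSA defaults are 200
samples of 20,000 individuals; unit tests use 500–50,000 individuals
depending on the precision the assertion needs.

## Known limitations and one honest divergence

* Stage at screen detection equals the current underlying stage; any
  additional stage-shift benefit of screen detection is not modelled.
* CRC survival after diagnosis is sex-invariant in the synthetic inputs
  (the table is indexed by sex, but the generator fills both sexes
  identically).
* Calibration targets are generated by the same parametric family the
  search explores, so calibration-recovery results demonstrate machinery,
  not robustness to model misspecification.
* On these synthetic inputs, the *overall* net-monetary-benefit advantage
  of sex-stratified (56/60) over uniform-58 screening is approximately
  zero: the ~20–25% extra detectable disease reached by screening men two
  years earlier is offset by men's lower uptake and shorter life
  expectancy, which raise the QALY value of screening women. The
  qualitative findings that are robust here are: starting at 58 beats the
  age-60 comparator; all incremental health benefits of stratification
  versus the comparator accrue to men; random stratification captures less
  benefit than sex stratification; and the stratification effect shrinks
  as the mean start age falls to 50. A positive overall advantage of
  stratification additionally requires input magnitudes (relative risk,
  uptake and survival sex gaps) that the synthetic placeholders do not
  pin down — with real calibrated inputs this balance can tip either way,
  which is precisely why the package exposes every one of these inputs as
  data rather than code.
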