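---
title: "Modelling disability transitions and state-specific life expectancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disability transitions and state-specific life expectancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mshale)
```

## The model

`mshale` analyses ageing-cohort panel data in which adults aged 50 and over
are interviewed every couple of years about limitations in basic activities
of daily living (BADL: dressing, bathing, eating, transferring, continence)
and instrumental activities (IADL: housework, cooking, shopping, managing
medication and money). Each interview is classified into one of four
states:

1. **robust** — no BADL or IADL limitation;
2. **iadl** — at least one IADL limitation but no BADL limitation;
3. **badl** — at least one BADL limitation, whether or not IADL
   limitations are also present;
4. **dead** — absorbing.

Classification depends only on limitation *counts*, never on which items
are limited, because item batteries differ across surveys while "one or
more limitations" is comparable everywhere.

Health trajectories are modelled as a continuous-time Markov chain: the
next transition depends only on the current state. Transition intensities
follow a proportional-hazards form,

$$q_{rs}(z) = q^{(0)}_{rs} \, \exp(\beta_{rs}^\top z),$$

with baseline intensities \(q^{(0)}_{rs}\) (units 1/year) and per-transition
log-hazard-ratio coefficients \(\beta_{rs}\) for covariates \(z\) (by
default gender alone, coded 0 for men and 1 for women, so
\(\exp(\beta_{rs})\) is the women-vs-men hazard ratio for transition
\(r \to s\)). All six transitions among the live states plus death from
each live state are allowed — nine free intensities. Transition
probabilities over a horizon \(t\) are \(P(t) = e^{Qt}\).

The model is deliberately time-homogeneous with gender as the sole default
intensity covariate: multi-year transition-probability tables are then a
single matrix exponential per population, and age enters at the
life-expectancy stage (below), where the next-state models are explicitly
age-adjusted. An optional age-at-interval-start covariate
(centred at 70, scaled by 10) can be added to the intensities, but it is
off by default.

### Likelihood

States are observed only at interviews (interval censoring), while death
times are known to the day (recorded or imputed). A subject contributes,
for each pair of consecutive observations:

* live target: \(\log P(\Delta t)[r, s]\);
* death target: the exact-death-time density
  \(\log \sum_{r'} P(\Delta t)[r, r'] \, q_{r' \to \text{dead}}\), a sum
  over the unknown state just before death.

The likelihood conditions on each subject's first observed state; no
initial-state term is included. Subjects whose interviews simply stop
contribute nothing after their last interview, which is correct when
attrition is non-informative.

`fit_mle()` maximises this likelihood over \((\log q^{(0)}, \beta)\) —
unconstrained on the log scale, so intensities stay positive by
construction — with BFGS. Gradients are analytic: each Q is
eigendecomposed once per evaluation and the derivative of a row of
\(e^{Q\Delta t}\) along one transition's perturbation is a rank-one
Fréchet derivative, which is how the likelihood stays fast enough for
replicated simulation studies. The reported covariance is the inverse
observed information, obtained by central finite differences of the
analytic gradient (relative step \(10^{-5}\)) at the optimum. Confidence
intervals for hazard ratios assume normality of the log effect.

Numerical choices worth knowing:

* convergence: BFGS relative tolerance \(10^{-10}\), iteration budget
  500; the maximal absolute gradient at the optimum is stored in
  `gradient_max` so a flat or suspicious fit is visible. A fixed absolute
  gradient-norm cutoff is not used, because the attainable gradient norm
  scales with the likelihood's magnitude.
* the "crude" initialisation sets each baseline intensity to observed
  transitions divided by person-years in the origin state, floored at
  \(10^{-4}\)/year, with all betas zero.
* transitions never observed in the data are not identifiable from it;
  their parameters are fixed (intensity at the floor, beta 0), excluded
  from optimisation, and listed in the fit's `dropped` field.
* interview and death on the same date would give a zero-length interval;
  the interval is widened to half a day.
* an optimizer overshoot producing astronomically large intensities is
  treated as zero likelihood (a finite penalty), which makes the line
  search back off rather than abort.

### Death-date imputation

When a death is reported at a wave without a date, the date is placed at
the day-resolution midpoint of the interval between the last interview
alive and the reporting wave (odd spans floored). `build_panels()` can
instead place missing dates one day inside either interval edge
(`death_mode = "early"` / `"late"`), which is the sensitivity analysis:
the life-expectancy pipeline below is structurally almost insensitive to
the placement, because moving a death *within* its reporting interval
does not change the cycle in which the death event falls. The
continuous-time intensities, by contrast, do shift with placement (the
exposure changes), and on the default synthetic cohort the fitted-Q
occupancy route shows an early-vs-late spread of roughly a quarter of a
year for men; that spread is a property of the interval-censored
likelihood, not a defect, and it is why the sensitivity claim is stated
for the life-expectancy pipeline.

## Life expectancy by microsimulation

Life expectancy is estimated the way stochastic population analysis
programs do it, not from the fitted Q:

1. `fit_discrete_model()` estimates, for each live origin state, a
   multinomial logistic model of the destination state one cycle later
   (reference: staying put; death is a destination like any other), with
   covariates age at the interval start (centred at 70, scaled by 10), an
   optional quadratic age term (on by default — "age-adjusted" without a
   stated functional form suggests allowing curvature, and it can be
   switched off), and gender. Live-to-live pairs are used when they span
   one cycle within ±25%; live-to-dead pairs are used whenever the death
   falls within 1.25 cycles of the last interview, because deaths occur
   part-way through a cycle by construction — binning them to the nearest
   whole cycle would discard the first-half-of-interval deaths and bias
   mortality down.
2. `simulate_cohort()` draws 100 000 individual trajectories from age 50
   to 90 in two-year cycles (the modal inter-wave gap of these surveys;
   configurable), drawing each cycle's destination from the fitted model
   at the individual's current age and gender. Runs are fully determined
   by the configuration seed.
3. `life_expectancy()` averages person-years of occupancy. Occupancy uses
   a trapezoid convention: an alive-to-alive cycle credits half a cycle
   to the state at each endpoint, and the cycle in which death occurs
   credits half a cycle to the origin state. With cycle length \(h\) this
   makes the occupancy estimator a trapezoid-rule quadrature of the
   occupancy curves with \(O(h^2)\) discretisation error (about 0.03
   years at \(h = 2\)); a naive full-cycle credit to the origin state
   would be a left-endpoint rule with \(O(h)\) error near a full year.
   Total LE is exactly the sum of the three state-specific LEs.

LE here is *temporary* life expectancy on the simulated age span
(50–90 by default): the simulation stops at 90 and no open-ended tail is
added, because extrapolating beyond the modelled ages is not something
the fitted next-state models can support. Fitted age coefficients are
likewise extrapolated when simulating to ages beyond those observed in
the panel; with the default quadratic this is visible as extra variance
in old-age mortality, which is worth remembering when panels are small.

`conditional_le_by_age()` repeats the simulation from each starting age
and state (degenerate starting distribution) and `gender_gap()` differences
women's and men's tables; the disabled-years gap is defined so that
total gap = robust gap + disabled gap holds exactly.

## The synthetic cohort generator

Restricted survey microdata cannot ship with a package, so the generator
(`generate_panel_data()`) produces panels with the statistical structure
the analysis assumes, and a known truth to validate against:

* cohort composition: 55% women; baseline ages drawn from bands
  50–59/60–69/70–79/80–89/90+ with weights 0.32/0.33/0.25/0.09/0.01
  (uniform within band, the open band drawn on 90–95); baseline states
  robust/iadl/badl at 0.75/0.10/0.15 per gender — all typical of the
  published baseline tables of the harmonised ageing cohorts.
* true gender hazard ratios (`default_gender_hr()`): women progress to
  IADL disability more (1.392), to BADL slightly less (0.856), recover
  from BADL to robust less (0.692), move BADL→IADL more (1.356), and die
  less from every live state (0.232 / 0.285 / 0.692) — the canonical
  reported pattern, so the package's demo output is qualitatively the
  published story.
* true baseline intensities (`default_log_q0()`) are package-chosen (no
  baseline intensities are published): calibrated once, analytically on
  the truth model, so that the 10-year robust→dead probability lands
  inside the published 7–19% envelope for both genders, recorded deaths
  over four waves land inside a plausible 10–30% follow-up band, and
  women's total and disabled years both exceed men's. They were frozen
  before any test was run.
* observation design: four waves, two years apart with ±0.25-year
  uniform jitter; monotone non-informative attrition at 8% per wave from
  wave 2 (attrition censors later interviews *and* death reports, so the
  likelihood's ignorability assumption holds exactly); 30% of deaths
  have their date withheld to exercise midpoint imputation; item counts
  are synthesised consistently with the latent state.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: informative dropout, proxy responses,
misclassified states, item-battery differences between surveys, age- or
period-varying intensities, and survey design weights. The generator's
latent process is exactly the fitted model's; real cohorts are not.

## Validation design

The suite validates each layer against an independent route:

* matrix exponentials against a truncated-Taylor-series oracle written in
  the tests, plus Chapman–Kolmogorov consistency on random generators
  and closed-form two-state decay;
* the panel likelihood against a per-pair series-expansion oracle;
* the estimator by parameter recovery (every log-intensity and gender
  beta within three estimated standard errors of the generator truth at
  n = 2000) and by interval coverage for a null gender effect across 200
  refitted replicates at n = 1000;
* the microsimulation against Simpson-rule occupancy integrals
  \(\int_0^{40} e^{Qu}\,du\) of a fixed generator, within three
  Monte-Carlo standard errors at n = 100 000;
* the full pipeline for the qualitative gender pattern (women live
  longer, and longer with disability) and for determinism (identical
  seeds, byte-identical outputs).

Problem sizes (2000 subjects for the main fit, 1000 for coverage
replicates, 100 000 simulated individuals) were chosen as the smallest
that leave comfortable statistical margins for these checks.

## Limitations

* One Q per population stratum: no piecewise-constant age bands, random
  effects, or hidden-state misclassification.
* No confidence intervals for life expectancy (a bootstrap over the whole
  pipeline would be needed).
* The discrete-cycle LE estimator inherits the ±25% pair-span rule; data
  with very irregular wave spacing would discard many pairs.
* Temporary LE on 50–90 undercounts total remaining LE for populations
  with substantial survival past 90.
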