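# mshale

Multi-**s**tate **h**ealth transitions **a**nd disability-specific **l**ife
**e**xpectancy for ageing cohorts.

## The problem

Longitudinal ageing surveys interview adults aged 50+ every couple of
years about limitations in basic activities of daily living (BADL —
dressing, bathing, eating, transferring, continence) and instrumental
activities (IADL — housework, cooking, shopping, managing medication and
finances). Two questions drive policy: *how do people move between
robustness, IADL disability, BADL disability and death as they age*, and
*how many of the remaining years are lived in each state* — overall and by
gender. `mshale` is for epidemiologists and biostatisticians who want to
answer both from panel data in which states are only observed at
interviews (interval censoring) and death dates are sometimes missing.

## The model

Each interview is classified into one of four states — robust (no
limitation), `iadl` (≥1 IADL limitation, no BADL), `badl` (≥1 BADL
limitation, regardless of IADL), `dead` — and trajectories are modelled as
a continuous-time Markov chain with proportional transition intensities

    q_rs(z) = q0_rs * exp(beta_rs' z),

where `z` is the covariate vector (by default gender, 0 = man / 1 = woman)
so `exp(beta_rs)` is the per-transition hazard ratio. All six transitions
among live states plus death from each live state are allowed (nine
intensities). Transition probabilities over `t` years are `P(t) = expm(Qt)`.
The likelihood combines interval-censored contributions
`log P(dt)[r, s]` for live targets with exact-death-time densities
`log sum_r' P(dt)[r, r'] q_{r'd}` for deaths, and is maximised by BFGS
with analytic gradients; missing death dates are midpoint-imputed first.

Life expectancy is then estimated the way SPACE-style programs do it:
multinomial logistic next-state models (per origin state, in age and
gender, death as an ordinary destination) feed a microsimulation of
100 000 individuals from age 50 to 90 in two-year cycles, and person-years
of state occupancy are averaged into total and state-specific expectancies.

A synthetic cohort generator with a known Markov truth emulates the
structure of harmonised ageing-survey panels (biennial jittered waves,
dropout, partially missing death dates), so the whole pipeline is testable
without access-restricted survey microdata.

## Worked example

```r
library(mshale)
ds     <- generate_panel_data(generator_config(n_subjects = 2000, seed = 4156))
panels <- build_panels(ds$rows)
panels
#> Health-state panels: 1840 subjects, 6720 observations
#>   deaths observed: 200 (64 with imputed dates)
#>   excluded: entry age <50: 0 | <2 usable waves: 160 | waves with missing items: 0

fit <- fit_mle(panels)
fit
#> Multi-state Markov model fit
#>   1840 subjects, 4880 observation intervals, log-likelihood -3694.699
#>   converged: TRUE (max |grad| 3.46e-04)
#>    transition intensity HR[gender]
#>  robust->iadl    0.0549      1.386
#>  robust->badl    0.0222      1.055
#>  robust->dead    0.0048      0.463
#>  iadl->robust    0.1850      0.874
#>    iadl->badl    0.1761      1.294
#>    iadl->dead    0.0413      0.215
#>  badl->robust    0.1146      0.780
#>    badl->iadl    0.0754      2.216
#>    badl->dead    0.1372      0.551
```

The fitted intensities are per-year rates; `HR[gender]` is the
women-vs-men hazard ratio per transition. On this synthetic cohort the
generator's truth has women progressing to IADL disability more
(true HR 1.392; fitted 1.386, 95% CI 1.060–1.812 from `wald_hr(fit)`) and
dying less from every live state — the fitted pattern reproduces it.

Life expectancy between ages 50 and 90, via the microsimulation pipeline:

```r
dtm <- fit_discrete_model(panels)
mix <- baseline_state_mix(panels)
le  <- lapply(0:1, function(g) {
  cfg <- sim_config(n_individuals = 100000, start_state_distribution = mix[g + 1, ],
                    gender = c("man", "woman")[g + 1], seed = 2718 + g)
  life_expectancy(simulate_cohort(dtm, cfg))
})
rbind(le[[1]], le[[2]])
#>   gender start_age start_state le_total le_robust le_iadl le_badl n_effective
#> 1    man        50         mix    23.63     17.43   3.025   3.174      100000
#> 2  woman        50         mix    28.60     17.88   5.504   5.214      100000

gender_gap(le[[2]], le[[1]])
#>   start_age start_state gap_total gap_robust gap_disabled
#> 1        50         mix      4.96      0.446         4.52
```

Women live 4.96 more of the years between 50 and 90, but 4.52 of those
extra years are lived with disability — longer lives, disproportionately
disabled ones, which is the headline pattern these models exist to
quantify. `horizon_probability_table(fit, covariates = 1)` gives the
10/20/30-year transition-probability tables, `conditional_le_by_age()`
the expectancies by starting age (50/60/70/80) and state, and
`baseline_summary(panels)` the baseline characteristics table.

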