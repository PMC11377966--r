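# zero-mortality generator: moves among live states, never dies
Q_no_death <- local({
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- 0.2; Q[2, 1] <- 0.15; Q[2, 3] <- 0.1; Q[3, 2] <- 0.1
  diag(Q) <- -rowSums(Q)
  Q
})

test_that("discrete next-state probabilities form a distribution everywhere", {
  p <- gen_panels(1500, seed = 402)
  dtm <- fit_discrete_model(p)
  for (s in 1:3) {
    pr <- mshale:::dtm_probs(dtm, s, c(52, 67, 88), c(0, 1, 1))
    expect_true(all(pr >= 0 & pr <= 1))
    expect_equal(rowSums(pr), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("scarce origin states are refused with a named error", {
  p <- gen_panels(25, seed = 403)
  expect_error(fit_discrete_model(p), "fewer than 30")
})

test_that("age and gender coefficients recover zero effects", {
  # truth: no gender effect, and intensities never depend on age
  p <- gen_panels(4000, seed = 404, true_beta = rep(0, 9))
  dtm <- fit_discrete_model(p)
  for (s in 1:3) {
    b <- dtm$blocks[[s]]
    expect_false(is.null(b$se))
    z_age <- abs(b$coef[, "ac"]) / b$se[, "ac"]
    z_gen <- abs(b$coef[, "gender"]) / b$se[, "gender"]
    expect_true(all(z_age < 3))
    expect_true(all(z_gen < 3))
  }
})

test_that("discrete model fitted on CTMC data matches expm(2Q) rows", {
  p <- gen_panels(6000, seed = 405, dropout_per_wave = 0,
                  death_date_missing_prob = 0)
  dtm <- fit_discrete_model(p)
  m <- truth_model()
  pr <- mshale:::panel_pairs(p, "gender")
  for (g in 0:1) {
    Ptrue <- expm_oracle(build_Q(m, g), 2)
    for (s in 1:3) {
      n_sg <- sum(pr$from == s & pr$Z[, "gender"] == g)
      est <- mshale:::dtm_probs(dtm, s, 67, g)
      for (d in 1:4) {
        se <- sqrt(Ptrue[s, d] * (1 - Ptrue[s, d]) / n_sg)
        expect_lt(abs(est[d] - Ptrue[s, d]), 3 * se + 1e-3)
      }
    }
  }
})

test_that("zero-mortality cohorts live the full horizon", {
  cfg <- sim_config(n_individuals = 2000, start_state_distribution = c(1, 0, 0),
                    gender = "both", seed = 5)
  occ <- simulate_cohort(Q_no_death, cfg)
  expect_true(all(occ$states != 4))
  le <- life_expectancy(occ)
  expect_equal(le$le_total, rep(40, nrow(le)), tolerance = 1e-12)
})

test_that("a frozen cohort accrues all person-time in its start state", {
  cfg <- sim_config(n_individuals = 500, start_state_distribution = c(0, 0, 1),
                    gender = "man", seed = 6)
  occ <- simulate_cohort(matrix(0, 4, 4), cfg) # all live states absorbing
  le <- life_expectancy(occ)
  expect_equal(le$le_badl, 40, tolerance = 1e-12)
  expect_equal(le$le_total, 40, tolerance = 1e-12)
  expect_identical(le$start_state, "badl")
})

test_that("simulation is deterministic given the configuration seed", {
  cfg <- sim_config(n_individuals = 3000, start_state_distribution = c(0.7, 0.1, 0.2),
                    gender = "both", seed = 99)
  Q <- build_Q(truth_model(), 1)
  occ1 <- simulate_cohort(Q, cfg)
  occ2 <- simulate_cohort(Q, cfg)
  expect_identical(occ1$states, occ2$states)
  expect_identical(life_expectancy(occ1), life_expectancy(occ2))
})

test_that("state-specific expectancies partition total life expectancy", {
  cfg <- sim_config(n_individuals = 5000, start_state_distribution = c(0.75, 0.10, 0.15),
                    gender = "both", seed = 17)
  occ <- simulate_cohort(build_Q(truth_model(), 0), cfg)
  le <- life_expectancy(occ)
  expect_equal(le$le_total, le$le_robust + le$le_iadl + le$le_badl,
               tolerance = 1e-9)
  expect_true(all(le$le_total >= 0 & le$le_total <= 40))
})

test_that("conditional life expectancy declines with starting age", {
  model_fun <- function(g) build_Q(truth_model(), g)
  cfg <- sim_config(n_individuals = 4000, gender = "both", seed = 23)
  le <- conditional_le_by_age(model_fun, cfg, ages = c(50, 80), states = c(1, 3))
  for (g in c("man", "woman")) {
    for (s in c("robust", "badl")) {
      le50 <- le$le_total[le$gender == g & le$start_state == s & le$start_age == 50]
      le80 <- le$le_total[le$gender == g & le$start_state == s & le$start_age == 80]
      expect_lt(le80, le50)
    }
  }
  expect_error(conditional_le_by_age(model_fun, cfg, states = 4), "dead")
})

test_that("conditional run reproduces an unconditional degenerate run", {
  cfg <- sim_config(n_individuals = 2000, gender = "woman", seed = 31)
  Q <- build_Q(truth_model(), 1)
  cond <- conditional_le_by_age(Q, cfg, ages = 50, states = 1)
  direct_cfg <- sim_config(n_individuals = 2000, start_age = 50,
                           start_state_distribution = c(1, 0, 0),
                           gender = "woman",
                           seed = (cfg$seed + 7919L) %% .Machine$integer.max)
  direct <- life_expectancy(simulate_cohort(Q, direct_cfg),
                            start_state_label = "robust")
  expect_equal(cond$le_total, direct$le_total)
  expect_equal(cond$le_badl, direct$le_badl)
})

test_that("gender gaps reproduce transcribed cohort values and their identity", {
  mk <- function(gender, tot, rob, iadl, badl) {
    d <- data.frame(gender = gender, start_age = 50, start_state = "mix",
                    le_total = tot, le_robust = rob, le_iadl = iadl,
                    le_badl = badl, n_effective = 1e5)
    class(d) <- c("le_table", "data.frame")
    d
  }
  # transcribed China values: women 35.49 vs men 31.34 at age 50
  gap <- gender_gap(mk("woman", 35.49, 18.0, 9.0, 8.49), mk("man", 31.34, 20.0, 6.0, 5.34))
  expect_equal(gap$gap_total, 4.15, tolerance = 1e-9)
  expect_equal(gap$gap_total, gap$gap_robust + gap$gap_disabled, tolerance = 1e-12)

  same <- mk("woman", 30, 20, 5, 5)
  m <- same; m$gender <- "man"
  gap0 <- gender_gap(same, m)
  expect_equal(unlist(gap0[, c("gap_total", "gap_robust", "gap_disabled")]),
               c(gap_total = 0, gap_robust = 0, gap_disabled = 0))

  mm <- mk("man", 31, 20, 6, 5)
  mm$start_age <- 60
  expect_error(gender_gap(mk("woman", 35, 18, 9, 8), mm), "grid")
})
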