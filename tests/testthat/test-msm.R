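# shared small fit used by the table tests below
fit_small <- local({
  p <- gen_panels(500, seed = 8101)
  fit_mle(p)
})

test_that("transition structure validates its shape", {
  s <- transition_structure()
  expect_identical(nrow(s), 9L)
  expect_false(any(s$from == 4))
  expect_true(all(1:3 %in% s$from))
  expect_error(transition_structure(cbind(4, 1)), "source")
  expect_error(transition_structure(cbind(c(1, 1), c(2, 2))), "duplicate")
  expect_error(transition_structure(cbind(1, 2)), "outgoing")
})

test_that("build_Q applies proportional covariate effects", {
  lq <- log(c(0.05, 0.03, 0.01, 0.18, 0.20, 0.03, 0.12, 0.11, 0.14))
  m0 <- intensity_model(lq, rep(0, 9))
  Q <- build_Q(m0, 1)
  expect_equal(Q[cbind(transition_structure()$from, transition_structure()$to)],
               exp(lq), tolerance = 1e-12)

  # a gender hazard ratio of 1.392 scales the robust->iadl intensity
  b <- rep(0, 9); b[1] <- log(1.392)
  m1 <- intensity_model(lq, b)
  expect_equal(build_Q(m1, 1)[1, 2], 1.392 * exp(lq[1]), tolerance = 1e-12)
  expect_equal(build_Q(m1, 0)[1, 2], exp(lq[1]), tolerance = 1e-12)

  expect_true(all(abs(rowSums(Q)) < 1e-12))
  expect_true(all(Q[4, ] == 0))
  expect_error(build_Q(m0, c(1, 2)), "length")
})

test_that("transition probabilities are matrix exponentials", {
  Q <- build_Q(truth_model(), 0)
  expect_equal(transition_probability(Q, 0), diag(4), ignore_attr = TRUE)

  # two-state collapse: only robust -> dead at rate 0.1/yr
  Q2 <- matrix(0, 4, 4)
  Q2[1, 4] <- 0.1; Q2[1, 1] <- -0.1
  expect_equal(transition_probability(Q2, 10)[1, 1], exp(-1), tolerance = 1e-12)
  expect_equal(transition_probability(Q2, 10)[1, 4], 1 - exp(-1), tolerance = 1e-12)

  # generic Q against the series oracle
  expect_lt(max(abs(transition_probability(Q, 2) - expm_series(Q * 2))), 1e-9)
  expect_error(transition_probability(Q, -1), ">= 0")
})

test_that("interval and exact-death contributions match closed forms and oracles", {
  Q <- build_Q(truth_model(), 1)
  # continuity at the identity
  expect_equal(interval_loglik(1, 1, 1e-9, Q), 0, tolerance = 1e-6)
  # interval pair against the series oracle
  expect_equal(interval_loglik(1, 2, 2, Q), log(expm_series(Q * 2)[1, 2]),
               tolerance = 1e-9)

  # exponential-density closed form in the two-state collapse
  lam <- 0.07
  Q2 <- matrix(0, 4, 4); Q2[1, 4] <- lam; Q2[1, 1] <- -lam
  expect_equal(exact_death_loglik(1, 1.3, Q2), log(lam * exp(-lam * 1.3)),
               tolerance = 1e-12)

  # four-state death density against the series oracle
  P <- expm_series(Q * 1.5)
  expect_equal(exact_death_loglik(1, 1.5, Q), log(sum(P[1, 1:3] * Q[1:3, 4])),
               tolerance = 1e-9)

  # scaling all death intensities up increases the density at small dt
  m <- truth_model()
  Qup <- build_Q(intensity_model(m$log_q0 + log(1.5) * (transition_structure()$to == 4),
                                 m$beta), 1)
  expect_gt(exact_death_loglik(1, 0.2, Qup), exact_death_loglik(1, 0.2, Q))

  # no path into death
  Q0 <- matrix(0, 4, 4); Q0[1, 2] <- 0.1; Q0[1, 1] <- -0.1
  expect_warning(v <- exact_death_loglik(1, 1, Q0), "death")
  expect_identical(v, -Inf)
  expect_error(interval_loglik(1, 2, 0, Q), "positive")
})

test_that("panel likelihood reduces to single-pair contributions", {
  m <- truth_model()
  Q <- build_Q(m, 0)
  p1 <- mini_panel(c(0, 2), c(1, 2))
  expect_equal(panel_loglik(p1, m), interval_loglik(1, 2, 2, Q), tolerance = 1e-10)
  p2 <- mini_panel(c(0, 1.3), c(1, 4))
  expect_equal(panel_loglik(p2, m), exact_death_loglik(1, 1.3, Q), tolerance = 1e-10)
  # women use their own Q
  p3 <- mini_panel(c(0, 2), c(1, 3), gender = 1)
  expect_equal(panel_loglik(p3, m), interval_loglik(1, 3, 2, build_Q(m, 1)),
               tolerance = 1e-10)
})

test_that("panel likelihood equals the per-pair series oracle on simulated panels", {
  p <- gen_panels(50, seed = 301, n_waves = 3)
  m <- truth_model()
  expect_equal(panel_loglik(p, m), loglik_oracle(p, m), tolerance = 1e-8)
})

test_that("the fitted optimum improves on the crude initialisation", {
  expect_true(fit_small$converged)
  K <- 9
  init_model <- intensity_model(fit_small$init[1:K],
                                matrix(fit_small$init[-(1:K)], K))
  p <- gen_panels(500, seed = 8101)
  expect_gte(fit_small$loglik, panel_loglik(p, init_model))
  # covariance is symmetric with non-negative diagonal on the free block
  vc <- fit_small$covariance[fit_small$free, fit_small$free]
  expect_equal(vc, t(vc), tolerance = 1e-8)
  expect_true(all(diag(vc) >= 0))
})

test_that("Wald hazard-ratio intervals match the closed form", {
  mk_fit <- function(b, se) {
    K <- 9
    est <- c(log(rep(0.1, K)), rep(0, K))
    est[K + 1] <- b
    names(est) <- paste0("p", seq_along(est))
    vc <- diag(c(rep(0.01, K), rep(1e-4, K)))
    vc[K + 1, K + 1] <- se^2
    dimnames(vc) <- list(names(est), names(est))
    f <- list(estimates = est, covariance = vc, converged = TRUE,
              structure = transition_structure(), covariate_names = "gender",
              free = rep(TRUE, 2 * K))
    class(f) <- "msm_fit"
    f
  }
  hr <- wald_hr(mk_fit(0, 0.1))
  expect_equal(hr$hr[1], 1, tolerance = 1e-12)
  expect_equal(hr$ci_low[1], exp(-qnorm(0.975) * 0.1), tolerance = 1e-12)
  expect_equal(hr$ci_high[1], exp(qnorm(0.975) * 0.1), tolerance = 1e-12)
  expect_equal(round(hr$ci_low[1], 3), 0.822)
  expect_equal(round(hr$ci_high[1], 3), 1.217)

  # round-trip of a reported interval: HR 1.392 (1.321-1.467) implies
  # a log-scale SE of about 0.0267
  se <- (log(1.467) - log(1.321)) / (2 * qnorm(0.975))
  expect_equal(se, 0.0267, tolerance = 5e-3)
  hr2 <- wald_hr(mk_fit(log(1.392), se))
  expect_equal(hr2$ci_low[1], 1.321, tolerance = 1e-3)
  expect_equal(hr2$ci_high[1], 1.467, tolerance = 1e-3)

  # degenerate SE collapses the interval
  hr3 <- wald_hr(mk_fit(log(2), 0))
  expect_equal(hr3$ci_low[1], hr3$hr[1])
  expect_equal(hr3$ci_high[1], hr3$hr[1])
})

test_that("horizon tables are stochastic and match the expm oracle", {
  tab <- horizon_probability_table(fit_small, covariates = 1)
  sums <- aggregate(probability ~ start_state + horizon, tab, sum)
  expect_true(all(abs(sums$probability - 1) < 1e-10))

  # death probability is non-decreasing in the horizon
  dead <- tab[tab$end_state == "dead", ]
  for (s in unique(dead$start_state)) {
    ps <- dead$probability[dead$start_state == s][order(dead$horizon[dead$start_state == s])]
    expect_true(all(diff(ps) >= 0))
  }

  # table equals direct oracle rows for the fitted Q
  Q <- build_Q(mshale:::as_intensity_model(fit_small), 1)
  for (t in c(10, 20, 30)) {
    P <- expm_oracle(Q, t)
    sub <- tab[tab$horizon == t, ]
    for (s in 1:3) {
      expect_equal(sub$probability[sub$start_state == names(health_states())[s]],
                   unname(P[s, ]), tolerance = 1e-8)
    }
  }
})

test_that("Chapman-Kolmogorov holds for random intensity matrices", {
  set.seed(77)
  for (i in 1:25) {
    Q <- random_Q()
    s <- runif(1, 0.1, 15)
    t <- runif(1, 0.1, 15)
    err <- max(abs(transition_probability(Q, s + t) -
                     transition_probability(Q, s) %*% transition_probability(Q, t)))
    expect_lt(err, 1e-8)
  }
})
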