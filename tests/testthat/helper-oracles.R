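# Independent numerical oracles, deliberately kept apart from the package's
# compiled implementation: plain truncated-Taylor matrix exponentials and a
# Simpson-rule occupancy integral built on them.

# truncated Taylor series sum_{k<=nterm} A^k / k!
expm_series <- function(A, nterm = 60) {
  A <- unname(A)
  S <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(nterm)) {
    term <- term %*% A / k
    S <- S + term
  }
  S
}

# series oracle with scaling and squaring, reliable for large Q*t
expm_oracle <- function(Q, t) {
  A <- Q * t
  m <- max(0, ceiling(log2(max(1, norm(A, "I")))))
  P <- expm_series(A / 2^m)
  for (i in seq_len(m)) P <- P %*% P
  P
}

# temporary occupancy integrals int_0^T expm(Qu) du by Simpson's rule,
# stepping P along the grid with the series oracle
occupancy_quadrature <- function(Q, T = 40, h = 0.05) {
  n <- round(T / h)
  stopifnot(n %% 2 == 0)
  Ph <- expm_oracle(Q, h)
  P <- diag(nrow(Q))
  w <- c(1, rep(c(4, 2), n / 2 - 1), 4, 1)
  acc <- w[1] * P
  for (j in 2:(n + 1)) {
    P <- P %*% Ph
    acc <- acc + w[j] * P
  }
  acc * h / 3
}

# per-pair panel log-likelihood oracle using the series expm
loglik_oracle <- function(panels, model) {
  df <- as.data.frame(panels)
  df <- df[order(df$subject_id, df$time), ]
  total <- 0
  for (id in unique(df$subject_id)) {
    s <- df[df$subject_id == id, ]
    Q <- build_Q(model, s$gender[1])
    for (i in seq_len(nrow(s) - 1)) {
      dt <- s$time[i + 1] - s$time[i]
      if (dt <= 0) dt <- 0.5 / 365.25
      P <- expm_series(Q * dt)
      total <- total + if (s$state[i + 1] == 4) {
        log(sum(P[s$state[i], 1:3] * Q[1:3, 4]))
      } else {
        log(P[s$state[i], s$state[i + 1]])
      }
    }
  }
  total
}

# the generator's truth as an intensity model
truth_model <- function() {
  intensity_model(default_log_q0(), log(default_gender_hr()))
}

# random valid intensity matrix on the default 9-transition structure
random_Q <- function() {
  m <- intensity_model(log(runif(9, 0.01, 0.5)), rep(0, 9))
  build_Q(m, 0)
}

# minimal panel data frame for hand-built likelihood cases
mini_panel <- function(times, states, gender = 0, id = "x1") {
  df <- data.frame(
    subject_id = id, gender = gender, time = times, state = states,
    age_years = 60 + times
  )
  class(df) <- c("health_panels", "data.frame")
  df
}

# generate + validate panels in one step
gen_panels <- function(n, seed, ...) {
  build_panels(generate_panel_data(generator_config(n_subjects = n, seed = seed, ...))$rows)
}
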