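#' Allowed-transition structure of the four-state model
#'
#' The default structure allows all six transitions among the live states
#' (robust, iadl, badl, in both directions) plus death from each live
#' state: nine directed transitions in all, in the canonical order
#' robust->iadl, robust->badl, robust->dead, iadl->robust, iadl->badl,
#' iadl->dead, badl->robust, badl->iadl, badl->dead. Dead is absorbing.
#'
#' @param allowed Optional two-column integer matrix of (from, to) state
#'   codes overriding the default; the dead state may not be a source and
#'   every live state needs at least one exit.
#' @return A data frame of class `"transition_structure"` with columns
#'   `from`, `to`, `label`.
#' @examples
#' transition_structure()
#' @export
transition_structure <- function(allowed = NULL) {
  if (is.null(allowed)) {
    allowed <- cbind(
      from = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
      to   = c(2L, 3L, 4L, 1L, 3L, 4L, 1L, 2L, 4L)
    )
  }
  allowed <- matrix(as.integer(allowed), ncol = 2,
                    dimnames = list(NULL, c("from", "to")))
  if (any(allowed[, 1] == DEAD)) stop("the dead state cannot be a transition source")
  if (any(allowed < 1L) || any(allowed > 4L) || any(allowed[, 1] == allowed[, 2])) {
    stop("invalid transition pair")
  }
  if (anyDuplicated(allowed)) stop("duplicate transition pair")
  if (!all(1:3 %in% allowed[, 1])) stop("every live state needs an outgoing transition")
  out <- data.frame(
    from = allowed[, 1], to = allowed[, 2],
    label = paste(STATE_LABELS[allowed[, 1]], STATE_LABELS[allowed[, 2]], sep = "->")
  )
  class(out) <- c("transition_structure", "data.frame")
  out
}

#' Proportional-intensity model specification
#'
#' Bundles the transition structure with baseline log-intensities and
#' covariate log-hazard-ratio coefficients. The intensity of transition
#' r->s for covariate vector z is `exp(log_q0[r->s] + sum_j beta[r->s, j] * z[j])`,
#' so each covariate acts proportionally on each transition intensity and
#' `exp(beta)` is the per-transition hazard ratio.
#'
#' @param log_q0 Numeric vector of baseline log-intensities (units
#'   log(1/year)), one per allowed transition in structure order.
#' @param beta Numeric matrix of log-hazard-ratio coefficients, one row per
#'   transition and one column per covariate (a vector is taken as a
#'   single-covariate column).
#' @param structure A [transition_structure()].
#' @param covariate_names Character vector naming the covariates; the
#'   default single covariate is `"gender"` coded 0 man / 1 woman.
#' @return An object of class `"intensity_model"`.
#' @examples
#' m <- intensity_model(log(rep(0.1, 9)), rep(0, 9))
#' build_Q(m, covariates = 1)
#' @export
intensity_model <- function(log_q0, beta = NULL,
                            structure = transition_structure(),
                            covariate_names = "gender") {
  K <- nrow(structure)
  if (length(log_q0) != K) stop("log_q0 must have one entry per allowed transition")
  if (!all(is.finite(exp(log_q0)))) stop("exp(log_q0) must be finite")
  if (is.null(beta)) beta <- matrix(0, K, length(covariate_names))
  beta <- matrix(beta, nrow = K)
  if (ncol(beta) != length(covariate_names)) {
    stop("beta needs one column per covariate")
  }
  out <- list(structure = structure, log_q0 = as.numeric(log_q0), beta = beta,
              covariate_names = covariate_names)
  class(out) <- "intensity_model"
  out
}

#' Build the transition intensity matrix for a covariate vector
#'
#' Assembles the 4x4 generator matrix Q at covariate value z: off-diagonal
#' entries are `exp(log_q0 + beta %*% z)` on allowed transitions and zero
#' elsewhere, diagonals make rows sum to zero, and the dead row is all
#' zeros (absorbing).
#'
#' @param model An [intensity_model()].
#' @param covariates Numeric covariate vector matching the model's
#'   `covariate_names`.
#' @return A 4x4 intensity matrix (1/year) with state dimnames.
#' @export
build_Q <- function(model, covariates) {
  stopifnot(inherits(model, "intensity_model"))
  if (length(covariates) != length(model$covariate_names)) {
    stop("covariate vector length must match covariate_names")
  }
  tridx <- as.matrix(model$structure[, c("from", "to")])
  storage.mode(tridx) <- "integer"
  Q <- build_Q_cpp(model$log_q0, model$beta, tridx,
                   matrix(as.numeric(covariates), nrow = 1))
  dimnames(Q) <- list(STATE_LABELS, STATE_LABELS)
  Q
}

validate_Q <- function(Q) {
  if (!is.matrix(Q) || !all(dim(Q) == 4)) stop("Q must be a 4x4 matrix")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal intensities must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-10)) stop("rows of Q must sum to zero")
  if (any(Q[DEAD, ] != 0)) stop("the dead state must be absorbing")
  invisible(Q)
}

#' Transition probabilities over a horizon
#'
#' Computes `P(t) = expm(Q t)`, the matrix of probabilities of occupying
#' each state after `t` years given the current state, for a
#' time-homogeneous intensity matrix.
#'
#' @param Q A 4x4 intensity matrix, e.g. from [build_Q()].
#' @param t Horizon in years (>= 0).
#' @return A 4x4 stochastic matrix.
#' @examples
#' m <- intensity_model(log(rep(0.1, 9)), rep(0, 9))
#' transition_probability(build_Q(m, 0), 10)
#' @export
transition_probability <- function(Q, t) {
  validate_Q(Q)
  if (length(t) != 1 || !is.finite(t) || t < 0) stop("t must be a single year value >= 0")
  P <- expm_mat(Q * t)
  # clamp Pade roundoff at the boundary of [0, 1]
  P[P < 0 & P > -1e-12] <- 0
  P[P > 1 & P < 1 + 1e-12] <- 1
  dimnames(P) <- list(STATE_LABELS, STATE_LABELS)
  P
}

#' Log-likelihood of one interval-censored live-to-live observation pair
#'
#' The panel-data likelihood contribution for a subject seen in `from_state`
#' and then, `dt` years later, in live state `to_state`:
#' `log P(dt)[from, to]`. A zero probability for an observed transition
#' yields `-Inf` with a warning.
#'
#' @param from_state,to_state State codes (see [health_states()]).
#' @param dt Interval length in years (> 0).
#' @param Q A 4x4 intensity matrix.
#' @return The log-likelihood contribution.
#' @export
interval_loglik <- function(from_state, to_state, dt, Q) {
  validate_Q(Q)
  if (dt <= 0) stop("dt must be positive")
  if (from_state == DEAD) stop("from_state must be a live state")
  p <- expm_mat(Q * dt)[from_state, to_state]
  if (p <= 0) {
    warning("zero probability for an observed transition")
    return(-Inf)
  }
  log(p)
}

#' Log-likelihood of an exactly observed death time
#'
#' Contribution for a subject alive in `from_state` at the start of an
#' interval and dead exactly `dt` years later, with the penultimate live
#' state unknown: the log of the death-time density
#' `sum_r P(dt)[from, r] * q[r, dead]` over live states r.
#'
#' @inheritParams interval_loglik
#' @return The log-likelihood contribution.
#' @export
exact_death_loglik <- function(from_state, dt, Q) {
  validate_Q(Q)
  if (dt <= 0) stop("dt must be positive")
  if (from_state == DEAD) stop("from_state must be a live state")
  if (all(Q[1:3, DEAD] == 0)) {
    warning("no transition into death has positive intensity")
    return(-Inf)
  }
  P <- expm_mat(Q * dt)
  dens <- sum(P[from_state, 1:3] * Q[1:3, DEAD])
  if (dens <= 0) {
    warning("zero density for an observed death")
    return(-Inf)
  }
  log(dens)
}

# Consecutive observation pairs for the likelihood: one row per interval,
# with the subject's covariate values. Zero-length intervals (interview and
# death on the same date) get dt = half a day.
panel_pairs <- function(panels, covariate_names = "gender") {
  df <- as.data.frame(panels)
  df <- df[order(df$subject_id, df$time), ]
  n <- nrow(df)
  same <- df$subject_id[-1] == df$subject_id[-n]
  i1 <- which(same)
  i2 <- i1 + 1L
  dt <- df$time[i2] - df$time[i1]
  dt[dt <= 0] <- 0.5 / 365.25
  Z <- matrix(NA_real_, length(i1), length(covariate_names),
              dimnames = list(NULL, covariate_names))
  for (j in seq_along(covariate_names)) {
    Z[, j] <- switch(covariate_names[j],
      gender = df$gender[i1],
      age = (df$age_years[i1] - 70) / 10,
      stop("unknown covariate: ", covariate_names[j])
    )
  }
  list(
    subject_id = df$subject_id[i1],
    from = as.integer(df$state[i1]), to = as.integer(df$state[i2]),
    dt = dt, Z = Z
  )
}

ll_pairs <- function(log_q0, beta, tridx, pairs) {
  pat <- unique(pairs$Z)
  idx <- match(
    do.call(paste, c(as.data.frame(pairs$Z), sep = "\r")),
    do.call(paste, c(as.data.frame(pat), sep = "\r"))
  )
  panel_loglik_pairs_cpp(log_q0, beta, tridx, pat,
                         pairs$from, pairs$to, pairs$dt, idx)
}

#' Panel log-likelihood of an intensity model
#'
#' Sums, over subjects and consecutive observation pairs, the
#' interval-censored contribution ([interval_loglik()]) for live targets
#' and the exact-death-time contribution ([exact_death_loglik()]) for dead
#' targets, conditioning on each subject's first observed state. Q is built
#' per subject from that subject's covariates.
#'
#' @param panels A `"health_panels"` data frame (see [build_panels()]).
#' @param model An [intensity_model()].
#' @return The total log-likelihood. If any pair has probability zero the
#'   result is `-Inf` and the offending subject ids are attached as the
#'   `"offending_subjects"` attribute and reported in a warning.
#' @export
panel_loglik <- function(panels, model) {
  stopifnot(inherits(model, "intensity_model"))
  pairs <- panel_pairs(panels, model$covariate_names)
  tridx <- as.matrix(model$structure[, c("from", "to")])
  storage.mode(tridx) <- "integer"
  ll <- ll_pairs(model$log_q0, model$beta, tridx, pairs)
  bad <- !is.finite(ll)
  total <- sum(ll)
  if (any(bad)) {
    off <- unique(pairs$subject_id[bad])
    warning("non-finite likelihood contributions for subject(s): ",
            paste(head(off, 5), collapse = ", "))
    attr(total, "offending_subjects") <- off
  }
  total
}

# Crude initial intensities: observed r->s panel-transition count over
# person-years observed in r (interval lengths credited to the origin
# state), floored at 1e-4/yr.
crude_init <- function(pairs, structure) {
  K <- nrow(structure)
  q0 <- numeric(K)
  for (k in seq_len(K)) {
    cnt <- sum(pairs$from == structure$from[k] & pairs$to == structure$to[k])
    py <- sum(pairs$dt[pairs$from == structure$from[k]])
    q0[k] <- if (py > 0) cnt / py else 0
  }
  log(pmax(q0, 1e-4))
}

#' Fit the multi-state Markov model by maximum likelihood
#'
#' Maximises [panel_loglik()] over the baseline log-intensities and the
#' covariate log-hazard-ratio coefficients by quasi-Newton (BFGS)
#' iteration on the unconstrained log scale. The default `"crude"`
#' initialisation sets each baseline intensity to the observed
#' transition count divided by person-years in the origin state (floored
#' at 1e-4/yr) with all betas zero. Gradients are analytic (eigendecomposition
#' of Q with the rank-one Frechet derivative per transition); the covariance
#' of the estimates is the inverse of the observed information, obtained by
#' central finite differences of the analytic gradient at the optimum.
#' Transitions never observed in the data are not identifiable
#' from it; their parameters are fixed (intensity at the 1e-4/yr floor,
#' betas at 0), excluded from the optimisation, and listed in `dropped`.
#'
#' @param panels A `"health_panels"` data frame.
#' @param structure A [transition_structure()].
#' @param covariate_names Covariates entering the intensities; the default
#'   is gender alone. `"age"` (age at interval start, centred at 70 and
#'   scaled by 10) may be added.
#' @param init `"crude"` or a numeric parameter vector (log_q0 then beta,
#'   column-major by covariate) of full length.
#' @param tol Relative convergence tolerance passed to the optimiser.
#' @param max_iter Iteration budget.
#' @return An object of class `"msm_fit"`: `estimates` (named vector:
#'   log_q0 then beta), `covariance`, `loglik`, `converged`, `n_subjects`,
#'   `n_transitions`, `gradient_max` (finite-difference check at the
#'   optimum), `dropped`, plus the model metadata needed to rebuild Q.
#' @seealso [wald_hr()], [horizon_probability_table()]
#' @export
fit_mle <- function(panels, structure = transition_structure(),
                    covariate_names = "gender", init = "crude",
                    tol = 1e-10, max_iter = 500) {
  pairs <- panel_pairs(panels, covariate_names)
  if (length(pairs$from) == 0L) stop("no observation pairs in panels")
  K <- nrow(structure)
  C <- length(covariate_names)
  tridx <- as.matrix(structure[, c("from", "to")])
  storage.mode(tridx) <- "integer"

  par_names <- c(
    paste0("logq0[", structure$label, "]"),
    as.vector(outer(structure$label, covariate_names,
                    function(l, cn) paste0("beta[", cn, "][", l, "]")))
  )

  # identifiability: a transition never observed in the panel data has its
  # parameters fixed, not estimated
  obs_count <- vapply(seq_len(K), function(k) {
    sum(pairs$from == structure$from[k] & pairs$to == structure$to[k])
  }, integer(1))
  free_q <- obs_count > 0L
  free <- c(free_q, rep(free_q, C))
  dropped <- structure$label[!free_q]

  full0 <- if (identical(init, "crude")) {
    c(crude_init(pairs, structure), rep(0, K * C))
  } else {
    if (length(init) != K * (1 + C)) stop("init has wrong length")
    as.numeric(init)
  }
  full0[seq_len(K)][!free_q] <- log(1e-4)

  pat <- unique(pairs$Z)
  pat_idx <- match(
    do.call(paste, c(as.data.frame(pairs$Z), sep = "\r")),
    do.call(paste, c(as.data.frame(pat), sep = "\r"))
  )
  unpack <- function(theta) {
    full <- full0
    full[free] <- theta
    list(log_q0 = full[seq_len(K)],
         beta = matrix(full[-seq_len(K)], K, C))
  }
  # loglik and analytic gradient share one evaluation via a small cache
  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) return(cache$res)
    p <- unpack(theta)
    res <- panel_loglik_grad_cpp(p$log_q0, p$beta, tridx, pat,
                                 pairs$from, pairs$to, pairs$dt, pat_idx)
    cache$theta <- theta
    cache$res <- res
    res
  }
  negll <- function(theta) {
    v <- evaluate(theta)$loglik
    if (!is.finite(v)) return(1e10)
    -v
  }
  neggr <- function(theta) {
    r <- evaluate(theta)
    if (!is.finite(r$loglik)) return(rep(0, length(theta)))
    -r$gradient[free]
  }

  opt <- optim(full0[free], negll, neggr, method = "BFGS",
               control = list(maxit = max_iter, reltol = tol))
  est <- unpack(opt$par)
  full_est <- c(est$log_q0, as.vector(est$beta))
  names(full_est) <- par_names

  # observed information: central differences of the analytic gradient
  hstep <- 1e-5
  pfree <- length(opt$par)
  H <- matrix(0, pfree, pfree)
  for (i in seq_len(pfree)) {
    hi <- hstep * max(1, abs(opt$par[i]))
    xp <- opt$par; xp[i] <- xp[i] + hi
    xm <- opt$par; xm[i] <- xm[i] - hi
    H[i, ] <- (neggr(xp) - neggr(xm)) / (2 * hi)
  }
  H <- (H + t(H)) / 2
  cov_free <- tryCatch(solve(H), error = function(e) {
    warning("observed information singular; using pseudo-inverse")
    eg <- eigen(H, symmetric = TRUE)
    pos <- eg$values > 1e-10 * max(abs(eg$values))
    eg$vectors[, pos, drop = FALSE] %*%
      diag(1 / eg$values[pos], sum(pos)) %*% t(eg$vectors[, pos, drop = FALSE])
  })
  covariance <- matrix(NA_real_, K * (1 + C), K * (1 + C),
                       dimnames = list(par_names, par_names))
  covariance[free, free] <- (cov_free + t(cov_free)) / 2

  grad <- neggr(opt$par)

  out <- list(
    estimates = full_est,
    covariance = covariance,
    loglik = -opt$value,
    converged = opt$convergence == 0L,
    n_subjects = length(unique(pairs$subject_id)),
    n_transitions = length(pairs$from),
    gradient_max = max(abs(grad)),
    dropped = dropped,
    free = free,
    structure = structure,
    covariate_names = covariate_names,
    init = full0,
    settings = list(tol = tol, max_iter = max_iter, hessian_step = 1e-5)
  )
  class(out) <- "msm_fit"
  out
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Multi-state Markov model fit\n")
  cat(sprintf("  %d subjects, %d observation intervals, log-likelihood %.3f\n",
              x$n_subjects, x$n_transitions, x$loglik))
  cat("  converged:", x$converged,
      sprintf("(max |grad| %.2e)\n", x$gradient_max))
  if (length(x$dropped)) cat("  dropped (unobserved):", paste(x$dropped, collapse = ", "), "\n")
  K <- nrow(x$structure)
  q <- exp(x$estimates[seq_len(K)])
  tab <- data.frame(transition = x$structure$label, intensity = round(q, 4))
  if (length(x$covariate_names)) {
    hr <- exp(matrix(x$estimates[-seq_len(K)], K))
    colnames(hr) <- paste0("HR[", x$covariate_names, "]")
    tab <- cbind(tab, round(hr, 3))
  }
  print(tab, row.names = FALSE)
  invisible(x)
}

# Rebuild the intensity model at the fitted estimates.
as_intensity_model <- function(fit) {
  K <- nrow(fit$structure)
  intensity_model(fit$estimates[seq_len(K)],
                  matrix(fit$estimates[-seq_len(K)], K),
                  fit$structure, fit$covariate_names)
}

#' Wald hazard-ratio table
#'
#' Per transition and covariate: the hazard ratio `exp(beta)` with a
#' normal-theory confidence interval on the log scale,
#' `exp(beta +/- z * SE)`, using standard errors from the fitted
#' covariance diagonal.
#'
#' @param fit An `"msm_fit"` from [fit_mle()] (must have converged).
#' @param level Confidence level (default 0.95).
#' @return A data frame of class `"hr_table"` with columns `transition`,
#'   `covariate`, `hr`, `ci_low`, `ci_high`, `se_log`.
#' @export
wald_hr <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "msm_fit"))
  if (!fit$converged) stop("fit did not converge; refit before computing hazard ratios")
  K <- nrow(fit$structure)
  C <- length(fit$covariate_names)
  if (C == 0L) stop("fit has no covariates")
  vc <- fit$covariance
  dv <- diag(vc)[-seq_len(K)]
  if (any(dv < -1e-8, na.rm = TRUE)) {
    stop("covariance is not positive semi-definite; refit the model")
  }
  z <- qnorm((1 + level) / 2)
  b <- fit$estimates[-seq_len(K)]
  se <- sqrt(pmax(dv, 0))
  out <- data.frame(
    transition = rep(fit$structure$label, C),
    covariate = rep(fit$covariate_names, each = K),
    hr = exp(b),
    ci_low = exp(b - z * se),
    ci_high = exp(b + z * se),
    se_log = se,
    row.names = NULL
  )
  class(out) <- c("hr_table", "data.frame")
  out
}

#' Multi-year transition-probability table
#'
#' For each start state and horizon, the probability of occupying each of
#' the four states after the horizon has elapsed, from the fitted model at
#' a given covariate value. This is the long-format equivalent of the
#' 10/20/30-year heat-map layout.
#'
#' @param fit An `"msm_fit"` (must have converged).
#' @param covariates Covariate vector at which to evaluate Q (e.g. gender
#'   0 or 1).
#' @param horizons Horizons in years.
#' @param start_states Live start states.
#' @return A data frame keyed (start_state, horizon, end_state) with a
#'   `probability` column.
#' @export
horizon_probability_table <- function(fit, covariates,
                                      horizons = c(10, 20, 30),
                                      start_states = 1:3) {
  stopifnot(inherits(fit, "msm_fit"))
  if (!fit$converged) stop("fit did not converge")
  if (any(start_states == DEAD)) stop("start states must be live states")
  Q <- build_Q(as_intensity_model(fit), covariates)
  out <- do.call(rbind, lapply(horizons, function(t) {
    P <- transition_probability(Q, t)
    do.call(rbind, lapply(start_states, function(s) {
      data.frame(start_state = STATE_LABELS[s], horizon = t,
                 end_state = STATE_LABELS, probability = unname(P[s, ]))
    }))
  }))
  rownames(out) <- NULL
  out
}
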