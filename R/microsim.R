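#' Microsimulation configuration
#'
#' Settings for the stochastic cohort microsimulation: cohort size, age
#' span, cycle length, starting-state mix and random seed. The default
#' cohort of 100 000 individuals is aged from 50 to 90 in two-year cycles,
#' matching the modal inter-wave gap of biennial ageing surveys.
#'
#' @param n_individuals Cohort size (default 100 000).
#' @param start_age,max_age Age span in years (default 50 to 90);
#'   `max_age - start_age` must be a whole number of cycles.
#' @param cycle_years Cycle length in years (default 2).
#' @param start_state_distribution Probability vector over the three live
#'   states (robust, iadl, badl), or a 2x3 matrix with rows (man, woman)
#'   for gender-specific mixes. See [baseline_state_mix()] to derive it
#'   from a panel.
#' @param gender `"man"`, `"woman"`, or `"both"`.
#' @param prop_women Fraction of women when `gender = "both"`.
#' @param seed Integer random seed; the simulation is fully determined by
#'   the configuration plus this seed.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals = 100000L, start_age = 50, max_age = 90,
                       cycle_years = 2, start_state_distribution = c(1, 0, 0),
                       gender = c("both", "man", "woman"),
                       prop_women = 0.55, seed = 1L) {
  gender <- match.arg(gender)
  if (start_age >= max_age) stop("start_age must be below max_age")
  ncyc <- (max_age - start_age) / cycle_years
  if (abs(ncyc - round(ncyc)) > 1e-9) {
    stop("(max_age - start_age) must be divisible by cycle_years")
  }
  d <- start_state_distribution
  if (is.matrix(d)) {
    if (!all(dim(d) == c(2, 3))) stop("start_state_distribution matrix must be 2x3")
  } else {
    if (length(d) != 3) stop("start_state_distribution must cover the three live states")
    d <- rbind(man = d, woman = d)
  }
  if (any(d < 0) || any(abs(rowSums(d) - 1) > 1e-8)) {
    stop("start_state_distribution rows must be probability vectors")
  }
  out <- list(n_individuals = as.integer(n_individuals), start_age = start_age,
              max_age = max_age, cycle_years = cycle_years,
              start_state_distribution = d, gender = gender,
              prop_women = prop_women, seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

#' Gender-specific baseline state mix of a panel
#'
#' The distribution of first-interview states by gender, used as the
#' default starting-state mix for cohort simulation.
#'
#' @param panels A `"health_panels"` data frame.
#' @return A 2x3 matrix (rows man, woman; columns robust, iadl, badl).
#' @export
baseline_state_mix <- function(panels) {
  df <- as.data.frame(panels)
  first <- df[!duplicated(df$subject_id), ]
  out <- matrix(0, 2, 3, dimnames = list(c("man", "woman"), STATE_LABELS[1:3]))
  for (g in 0:1) {
    s <- first$state[first$gender == g]
    out[g + 1, ] <- tabulate(s, nbins = 3) / length(s)
  }
  out
}

#' Fit discrete-time next-state models for the microsimulation
#'
#' Estimates, for each live origin state, a multinomial logistic model of
#' the destination state one cycle later (staying in the origin state is
#' the reference destination, and death is a destination like any other)
#' with covariates age at the interval start (centred at 70, scaled by 10),
#' optionally age squared, and gender. Live-to-live observation pairs are
#' used when they span one cycle within +/-25%; live-to-dead pairs are used
#' whenever the death falls within 1.25 cycles of the last interview, since
#' deaths occur part-way through the cycle by construction. Excluded pairs
#' are counted in the result.
#'
#' @param panels A `"health_panels"` data frame.
#' @param cycle_years Cycle length in years (default 2).
#' @param quadratic_age Include an age-squared term (default `TRUE`).
#' @return An object of class `"discrete_transition_model"` with one
#'   coefficient block per origin state, fitted by [nnet::multinom()].
#' @export
fit_discrete_model <- function(panels, cycle_years = 2, quadratic_age = TRUE) {
  pairs <- panel_pairs(panels, "gender")
  df <- as.data.frame(panels)
  df <- df[order(df$subject_id, df$time), ]
  n <- nrow(df)
  same <- df$subject_id[-1] == df$subject_id[-n]
  i1 <- which(same)
  age <- df$age_years[i1]

  is_death <- pairs$to == DEAD
  rel <- pairs$dt / cycle_years
  keep <- (!is_death & rel >= 0.75 & rel <= 1.25) | (is_death & rel <= 1.25)
  n_excluded <- sum(!keep)

  dat <- data.frame(
    from = pairs$from[keep], to = pairs$to[keep],
    ac = (age[keep] - 70) / 10, gender = pairs$Z[keep, "gender"]
  )
  dat$ac2 <- dat$ac^2

  blocks <- vector("list", 3)
  for (s in 1:3) {
    d <- dat[dat$from == s, ]
    if (nrow(d) < 30) {
      stop("origin state '", STATE_LABELS[s], "' has fewer than 30 usable pairs (",
           nrow(d), "); enlarge the data")
    }
    lev <- c(s, setdiff(1:4, s))
    lev <- lev[lev %in% unique(c(s, d$to))] # drop never-seen destinations
    d$dest <- factor(d$to, levels = lev)
    form <- if (quadratic_age) dest ~ ac + ac2 + gender else dest ~ ac + gender
    fit <- nnet::multinom(form, data = d, trace = FALSE, Hess = TRUE, maxit = 500)
    cf <- stats::coef(fit)
    if (is.null(dim(cf))) { # binary destination set collapses to a vector
      cf <- matrix(cf, nrow = 1, dimnames = list(as.character(lev[2]), names(cf)))
    }
    se <- tryCatch({
      vc <- stats::vcov(fit)
      matrix(sqrt(pmax(diag(vc), 0)), nrow = nrow(cf), byrow = TRUE,
             dimnames = dimnames(cf))
    }, error = function(e) NULL)
    blocks[[s]] <- list(coef = cf, se = se, destinations = lev, n_pairs = nrow(d))
  }

  out <- list(cycle_years = cycle_years, quadratic_age = quadratic_age,
              blocks = blocks, age_center = 70, age_scale = 10,
              n_pairs_excluded = n_excluded)
  class(out) <- "discrete_transition_model"
  out
}

#' @export
print.discrete_transition_model <- function(x, ...) {
  cat("Discrete next-state model (", x$cycle_years, "-year cycles)\n", sep = "")
  for (s in 1:3) {
    b <- x$blocks[[s]]
    cat("  origin ", STATE_LABELS[s], ": ", b$n_pairs, " pairs, destinations ",
        paste(STATE_LABELS[b$destinations], collapse = ", "), "\n", sep = "")
  }
  cat("  pairs excluded by cycle-span rule:", x$n_pairs_excluded, "\n")
  invisible(x)
}

# Destination probabilities over the four states for individuals in a given
# origin state at (age, gender). Returns an n x 4 matrix.
dtm_probs <- function(model, origin, age, gender) {
  b <- model$blocks[[origin]]
  ac <- (age - model$age_center) / model$age_scale
  X <- if (model$quadratic_age) cbind(1, ac, ac^2, gender) else cbind(1, ac, gender)
  eta <- X %*% t(b$coef) # n x (ndest - 1)
  ex <- exp(eta)
  denom <- 1 + rowSums(ex)
  probs <- matrix(0, length(age), 4)
  probs[, b$destinations[1]] <- 1 / denom
  for (j in seq_len(ncol(ex))) {
    probs[, b$destinations[j + 1]] <- ex[, j] / denom
  }
  probs
}

# Per-cycle destination probabilities from a time-homogeneous intensity
# matrix: rows of expm(Q * cycle).
q_cycle_probs <- function(Q, cycle_years) {
  P <- expm_mat(Q * cycle_years)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate a cohort of individual health trajectories
#'
#' Simulates `n_individuals` trajectories on the discrete cycle grid from
#' `start_age` to `max_age`. Initial states are drawn from the configured
#' starting-state mix; at each cycle the destination state is drawn from
#' the transition model at the individual's current age and gender; death
#' is absorbing. The run is fully determined by the configuration seed
#' (the caller's RNG state is left untouched).
#'
#' @param model Either a `"discrete_transition_model"` from
#'   [fit_discrete_model()], or a 4x4 intensity matrix Q (e.g. from
#'   [build_Q()]), in which case per-cycle probabilities are the rows of
#'   `expm(Q * cycle_years)` for all ages and both genders.
#' @param config A [sim_config()].
#' @return An object of class `"cohort_occupancy"`: an integer state
#'   matrix (individuals x cycle grid points), the gender vector, and the
#'   configuration.
#' @export
simulate_cohort <- function(model, config) {
  stopifnot(inherits(config, "sim_config"))
  is_q <- is.matrix(model)
  if (is_q) validate_Q(model)
  n <- config$n_individuals
  h <- config$cycle_years
  ncyc <- as.integer(round((config$max_age - config$start_age) / h))

  seed_keep <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(seed_keep)) assign(".Random.seed", seed_keep, envir = globalenv())
  })
  set.seed(config$seed)

  gender <- switch(config$gender,
    man = rep.int(0L, n),
    woman = rep.int(1L, n),
    both = rbinom(n, 1L, config$prop_women)
  )
  states <- matrix(0L, n, ncyc + 1L)
  for (g in 0:1) {
    idx <- gender == g
    if (!any(idx)) next
    pr <- config$start_state_distribution[g + 1L, ]
    states[idx, 1L] <- sample.int(3L, sum(idx), replace = TRUE, prob = pr)
  }

  if (is_q) pq <- q_cycle_probs(model, h)

  for (k in seq_len(ncyc)) {
    cur <- states[, k]
    age <- config$start_age + (k - 1L) * h
    nxt <- cur # dead stays dead
    for (s in 1:3) {
      for (g in 0:1) {
        idx <- which(cur == s & gender == g)
        if (!length(idx)) next
        if (is_q) {
          probs <- matrix(pq[s, ], length(idx), 4, byrow = TRUE)
        } else {
          probs <- dtm_probs(model, s, rep.int(age, length(idx)), rep.int(g, length(idx)))
        }
        cp <- probs %*% upper.tri(diag(4), diag = TRUE)
        u <- runif(length(idx))
        nxt[idx] <- 1L + as.integer(rowSums(u > cp[, 1:3, drop = FALSE]))
      }
    }
    states[, k + 1L] <- nxt
  }

  out <- list(states = states, gender = gender, config = config)
  class(out) <- "cohort_occupancy"
  out
}

# Person-years by live state for one group of trajectories (trapezoid
# occupancy): an alive->alive cycle credits half a cycle to the state at
# each endpoint; the cycle in which death occurs credits half a cycle to
# the origin state.
occupancy_years <- function(states, h) {
  ncyc <- ncol(states) - 1L
  py <- numeric(3)
  for (s in 1:3) {
    w <- 0
    for (k in seq_len(ncyc)) {
      a <- states[, k]
      b <- states[, k + 1L]
      alive_pair <- a != DEAD & b != DEAD
      death_pair <- a != DEAD & b == DEAD
      w <- w + sum(alive_pair & a == s) * h / 2 +
        sum(alive_pair & b == s) * h / 2 +
        sum(death_pair & a == s) * h / 2
    }
    py[s] <- w
  }
  py
}

#' Total and state-specific life expectancy from simulated occupancy
#'
#' Averages person-years of occupancy over the cohort: total remaining
#' life expectancy on the simulated age span, partitioned into expected
#' years robust, IADL-disabled, and BADL-disabled. Occupancy is accumulated
#' by the trapezoid convention (half-cycle credit at each live endpoint;
#' half-cycle credit in the origin state for the cycle in which death
#' occurs), so `le_total = le_robust + le_iadl + le_badl` exactly.
#'
#' @param occupancy A `"cohort_occupancy"` from [simulate_cohort()].
#' @param start_state_label Label for the starting-state column of the
#'   output (defaults to `"mix"`, or the state name if the starting
#'   distribution is degenerate).
#' @return A data frame of class `"le_table"`: one row per gender present,
#'   with columns `gender`, `start_age`, `start_state`, `le_total`,
#'   `le_robust`, `le_iadl`, `le_badl`, `n_effective`.
#' @export
life_expectancy <- function(occupancy, start_state_label = NULL) {
  stopifnot(inherits(occupancy, "cohort_occupancy"))
  cfg <- occupancy$config
  if (is.null(start_state_label)) {
    deg <- apply(cfg$start_state_distribution, 1, function(p) match(1, p))
    start_state_label <- if (!any(is.na(deg)) && length(unique(deg)) == 1) {
      STATE_LABELS[deg[1]]
    } else "mix"
  }
  genders <- sort(unique(occupancy$gender))
  rows <- lapply(genders, function(g) {
    st <- occupancy$states[occupancy$gender == g, , drop = FALSE]
    py <- occupancy_years(st, cfg$cycle_years) / nrow(st)
    data.frame(
      gender = c("man", "woman")[g + 1L], start_age = cfg$start_age,
      start_state = start_state_label,
      le_total = sum(py), le_robust = py[1], le_iadl = py[2], le_badl = py[3],
      n_effective = nrow(st)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("le_table", "data.frame")
  out
}

#' Conditional life expectancy by starting age and state
#'
#' Runs a fresh microsimulation for each combination of starting age and
#' starting state (degenerate starting distribution), for each requested
#' gender, and tabulates the resulting life expectancies. Sub-run seeds
#' are derived deterministically from the configuration seed.
#'
#' @param model A `"discrete_transition_model"` or a function
#'   `function(gender01)` returning a 4x4 intensity matrix for that gender.
#' @param config A [sim_config()]; its `start_age` is overridden per run.
#' @param ages Starting ages (each below `max_age`).
#' @param states Starting live states.
#' @return A `"le_table"` data frame with one row per (gender, age, state).
#' @export
conditional_le_by_age <- function(model, config, ages = c(50, 60, 70, 80),
                                  states = 1:3) {
  stopifnot(inherits(config, "sim_config"))
  if (any(ages >= config$max_age)) stop("each starting age must be below max_age")
  if (any(states == DEAD)) stop("the dead state is not a valid starting state")
  genders <- switch(config$gender, man = "man", woman = "woman",
                    both = c("man", "woman"))
  rows <- list()
  off <- 0L
  for (g in genders) {
    for (a in ages) {
      for (s in states) {
        off <- off + 1L
        dist <- c(0, 0, 0)
        dist[s] <- 1
        cfg <- sim_config(
          n_individuals = config$n_individuals, start_age = a,
          max_age = config$max_age, cycle_years = config$cycle_years,
          start_state_distribution = dist, gender = g,
          prop_women = config$prop_women,
          seed = (config$seed + 7919L * off) %% .Machine$integer.max
        )
        mdl <- if (is.function(model)) model(as.integer(g == "woman")) else model
        occ <- simulate_cohort(mdl, cfg)
        rows[[off]] <- life_expectancy(occ, start_state_label = STATE_LABELS[s])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("le_table", "data.frame")
  out
}

#' Gender gap in life expectancy
#'
#' Differences (women minus men) in total, robust, and disabled life
#' expectancy on matching (start_age, start_state) grids. The disabled gap
#' is the difference in IADL + BADL years, so by construction
#' `gap_total = gap_robust + gap_disabled`.
#'
#' @param le_women,le_men `"le_table"` data frames on identical
#'   (start_age, start_state) grids.
#' @return A data frame with columns `start_age`, `start_state`,
#'   `gap_total`, `gap_robust`, `gap_disabled`.
#' @export
gender_gap <- function(le_women, le_men) {
  w <- as.data.frame(le_women)
  m <- as.data.frame(le_men)
  w <- w[w$gender == "woman", ]
  m <- m[m$gender == "man", ]
  if (nrow(w) == 0 || nrow(m) == 0) stop("need one table per gender")
  key <- c("start_age", "start_state")
  w <- w[do.call(order, w[key]), ]
  m <- m[do.call(order, m[key]), ]
  if (nrow(w) != nrow(m) ||
      !all(w$start_age == m$start_age) || !all(w$start_state == m$start_state)) {
    stop("life-expectancy tables are not on the same (age, state) grid")
  }
  data.frame(
    start_age = w$start_age, start_state = w$start_state,
    gap_total = w$le_total - m$le_total,
    gap_robust = w$le_robust - m$le_robust,
    gap_disabled = (w$le_iadl + w$le_badl) - (m$le_iadl + m$le_badl)
  )
}
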