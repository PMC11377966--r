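#' Default true gender hazard ratios of the synthetic generator
#'
#' Per-transition gender effects (women relative to men) used as the
#' generator's truth, in [transition_structure()] order: women progress to
#' IADL disability more (HR 1.392), to BADL slightly less (0.856), recover
#' from BADL to robust less (0.692), move BADL to IADL more (1.356), and
#' die substantially less from every live state (0.232 / 0.285 / 0.692).
#'
#' @return A named numeric vector of nine hazard ratios.
#' @export
default_gender_hr <- function() {
  setNames(
    c(1.392, 0.856, 0.232, 0.970, 1.028, 0.285, 0.692, 1.356, 0.692),
    transition_structure()$label
  )
}

#' Default true baseline log-intensities of the synthetic generator
#'
#' Baseline (men) transition intensities in 1/year, on the log scale, in
#' [transition_structure()] order. Calibrated so the truth model gives a
#' 10-year robust-to-dead probability inside the 7.0-19.3% envelope for
#' both genders and roughly 12% deaths over four biennial waves.
#'
#' @return A named numeric vector of nine log-intensities.
#' @export
default_log_q0 <- function() {
  setNames(
    log(c(0.050, 0.030, 0.006, 0.18, 0.20, 0.035, 0.12, 0.11, 0.145)),
    transition_structure()$label
  )
}

#' Configuration of the synthetic panel-cohort generator
#'
#' Describes the emulated survey: cohort size and composition, baseline
#' age and state mixes, the true continuous-time Markov model (baseline
#' intensities and gender log-hazard ratios), the biennial wave design
#' with jitter, non-informative dropout, and the fraction of deaths whose
#' dates go unrecorded (to exercise midpoint imputation downstream).
#'
#' @param n_subjects Number of subjects.
#' @param prop_women Fraction of women (default 0.55).
#' @param age_band_weights Baseline-age mixture over the bands 50-59,
#'   60-69, 70-79, 80-89, 90+ (ages uniform within band; the open band is
#'   drawn on 90-95).
#' @param baseline_state_distribution Length-3 probability vector (or 2x3
#'   gender-specific matrix) over robust/iadl/badl at baseline.
#' @param true_log_q0 True baseline log-intensities (men), structure order.
#' @param true_beta True gender log-hazard ratios, structure order.
#' @param n_waves Number of interview waves (default 4).
#' @param wave_gap_years Nominal gap between waves (default 2), jittered
#'   uniformly by `+/- wave_gap_jitter` per interval.
#' @param wave_gap_jitter Uniform jitter half-width in years (default 0.25).
#' @param dropout_per_wave Per-wave probability of attrition from wave 2
#'   on (monotone, non-informative; default 0.08). Attrition censors the
#'   subject entirely: later interviews and death reports are both lost.
#' @param death_date_missing_prob Probability that a death's date is not
#'   recorded (default 0.3).
#' @param seed Integer seed; generation is fully determined by it.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(n_subjects = 2000L, prop_women = 0.55,
                             age_band_weights = c(0.32, 0.33, 0.25, 0.09, 0.01),
                             baseline_state_distribution = c(0.75, 0.10, 0.15),
                             true_log_q0 = default_log_q0(),
                             true_beta = log(default_gender_hr()),
                             n_waves = 4L, wave_gap_years = 2,
                             wave_gap_jitter = 0.25,
                             dropout_per_wave = 0.08,
                             death_date_missing_prob = 0.3,
                             seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be positive")
  fr <- c(prop_women, dropout_per_wave, death_date_missing_prob)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(age_band_weights) - 1) > 1e-8 || any(age_band_weights < 0)) {
    stop("age_band_weights must be a probability vector")
  }
  d <- baseline_state_distribution
  if (!is.matrix(d)) d <- rbind(man = d, woman = d)
  if (any(d < 0) || any(abs(rowSums(d) - 1) > 1e-8)) {
    stop("baseline_state_distribution rows must be probability vectors")
  }
  K <- nrow(transition_structure())
  if (length(true_log_q0) != K || length(true_beta) != K) {
    stop("true_log_q0 and true_beta need one entry per allowed transition")
  }
  out <- list(
    n_subjects = as.integer(n_subjects), prop_women = prop_women,
    age_band_weights = age_band_weights, baseline_state_distribution = d,
    true_log_q0 = as.numeric(true_log_q0), true_beta = as.numeric(true_beta),
    n_waves = as.integer(n_waves), wave_gap_years = wave_gap_years,
    wave_gap_jitter = wave_gap_jitter, dropout_per_wave = dropout_per_wave,
    death_date_missing_prob = death_date_missing_prob, seed = as.integer(seed)
  )
  class(out) <- "generator_config"
  out
}

#' Simulate one exact continuous-time Markov trajectory
#'
#' Event-driven simulation of the jump process generated by Q: the holding
#' time in state r is Exponential with rate `-Q[r, r]`, and the destination
#' is drawn with probability proportional to `Q[r, s]`. The path stops at
#' death or at the horizon. A live state with no exits (zero row) holds to
#' the horizon. Draws come from the current R random number generator.
#'
#' @param Q A 4x4 intensity matrix.
#' @param start_state Live starting state code.
#' @param horizon_years Simulation horizon in years.
#' @return A list with `states` (visited states, starting with
#'   `start_state`) and `times` (entry times in years, starting at 0); if
#'   the path ends in death the last state is 4 at the death time.
#' @export
sample_trajectory <- function(Q, start_state, horizon_years) {
  validate_Q(Q)
  if (start_state == DEAD) stop("start_state must be a live state")
  states <- start_state
  times <- 0
  cur <- start_state
  t <- 0
  repeat {
    rate <- -Q[cur, cur]
    if (rate <= 0) break # absorbing live state: hold to horizon
    t <- t + stats::rexp(1, rate)
    if (t >= horizon_years) break
    probs <- Q[cur, ]
    probs[cur] <- 0
    nxt <- sample.int(4L, 1L, prob = probs)
    states <- c(states, nxt)
    times <- c(times, t)
    cur <- nxt
    if (cur == DEAD) break
  }
  list(states = as.integer(states), times = times)
}

# State of a latent path at given times (right-continuous step function).
path_state_at <- function(path, t) {
  idx <- findInterval(t, path$times)
  path$states[pmax(idx, 1L)]
}

#' Observe a latent trajectory at survey waves
#'
#' Reads the latent state at each wave time and synthesises item counts
#' consistent with it (robust: no limitations; IADL: 1-7 limited IADL
#' items, no BADL; BADL: 1-6 limited BADL items, any number of IADL
#' items). If the path reaches death before the last wave, the waves after
#' death are replaced by a single dead record at the first wave after
#' death, carrying the exact death time or — when the death date is
#' flagged missing — no time, leaving it for downstream midpoint
#' imputation. Item-count draws use the current R random number generator.
#'
#' @param path A latent path from [sample_trajectory()].
#' @param wave_times Increasing vector of wave times in years (first
#'   usually 0).
#' @param death_date_missing Whether the death date is withheld.
#' @return A data frame with one row per realised record: `wave_time`,
#'   `state`, `badl_limited`, `iadl_limited`, `vital`, `death_time`.
#' @export
observe_panel <- function(path, wave_times, death_date_missing = FALSE) {
  if (is.unsorted(wave_times, strictly = TRUE)) stop("wave_times must be increasing")
  o <- observe_core(path, wave_times, death_date_missing)
  as.data.frame(o, stringsAsFactors = FALSE)
}

# vector-list version of observe_panel (hot path of the generator)
observe_core <- function(path, wave_times, death_date_missing) {
  died <- path$states[length(path$states)] == DEAD
  death_time <- if (died) path$times[length(path$times)] else Inf
  alive_waves <- wave_times[wave_times < death_time]
  na <- length(alive_waves)
  st <- path_state_at(path, alive_waves)
  badl <- integer(na)
  iadl <- integer(na)
  for (j in seq_len(na)) {
    if (st[j] == 2L) {
      iadl[j] <- sample.int(7L, 1L)
    } else if (st[j] == 3L) {
      badl[j] <- sample.int(6L, 1L)
      iadl[j] <- sample.int(8L, 1L) - 1L
    }
  }
  out <- list(
    wave_time = alive_waves, state = st, badl_limited = badl,
    iadl_limited = iadl, vital = rep.int("alive", na),
    death_time = rep.int(NA_real_, na)
  )
  if (died && death_time <= wave_times[length(wave_times)]) {
    report <- wave_times[wave_times >= death_time][1]
    out$wave_time <- c(out$wave_time, report)
    out$state <- c(out$state, DEAD)
    out$badl_limited <- c(out$badl_limited, NA_integer_)
    out$iadl_limited <- c(out$iadl_limited, NA_integer_)
    out$vital <- c(out$vital, "dead")
    out$death_time <- c(out$death_time,
                        if (death_date_missing) NA_real_ else death_time)
  }
  out
}

#' Generate a synthetic panel cohort with known Markov truth
#'
#' Draws a cohort per [generator_config()]: gender, baseline age band and
#' state, an exact latent trajectory from the gender-specific intensity
#' matrix, biennial wave observation with jitter, monotone non-informative
#' dropout of alive interviews, and partially missing death dates. The
#' output rows follow the raw-interview CSV schema consumed by
#' [build_panels()]; the latent truth travels alongside for validation.
#'
#' @param config A [generator_config()].
#' @return An object of class `"generated_dataset"`: `rows` (raw interview
#'   data frame), `truth` (the config plus each subject's latent path),
#'   and `config`.
#' @examples
#' ds <- generate_panel_data(generator_config(n_subjects = 50, seed = 42))
#' head(ds$rows)
#' @export
generate_panel_data <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  seed_keep <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(seed_keep)) assign(".Random.seed", seed_keep, envir = globalenv())
  })
  set.seed(config$seed)

  K <- nrow(transition_structure())
  model <- intensity_model(config$true_log_q0, config$true_beta)
  Qg <- list(build_Q(model, 0), build_Q(model, 1))
  band_lo <- c(50, 60, 70, 80, 90)
  band_hi <- c(60, 70, 80, 90, 95)
  origin <- as.Date("2010-01-01")

  n <- config$n_subjects
  rows <- vector("list", n)
  paths <- vector("list", n)
  ids <- sprintf("S%06d", seq_len(n))
  for (i in seq_len(n)) {
    gender <- rbinom(1, 1, config$prop_women)
    band <- sample.int(5L, 1L, prob = config$age_band_weights)
    age0 <- runif(1, band_lo[band], band_hi[band])
    state0 <- sample.int(3L, 1L, prob = config$baseline_state_distribution[gender + 1L, ])
    gaps <- config$wave_gap_years +
      runif(config$n_waves - 1L, -config$wave_gap_jitter, config$wave_gap_jitter)
    wave_times <- c(0, cumsum(gaps))
    path <- sample_trajectory(Qg[[gender + 1L]], state0, max(wave_times))
    ddm <- runif(1) < config$death_date_missing_prob
    obs <- observe_core(path, wave_times, death_date_missing = ddm)

    # monotone non-informative attrition from wave 2 on: once a subject
    # leaves the study, later interviews and death reports are both lost,
    # so censoring carries no information about the latent process
    drop_wave <- config$n_waves + 1L
    for (w in 2:config$n_waves) {
      if (runif(1) < config$dropout_per_wave) {
        drop_wave <- w
        break
      }
    }
    keep <- seq_along(obs$wave_time) < drop_wave

    baseline_date <- unclass(origin) + floor(runif(1, 0, 365))
    birth_day <- baseline_date - round(age0 * 365.25)
    rows[[i]] <- list(
      gender = gender, birth_day = birth_day,
      interview_day = baseline_date + round(obs$wave_time[keep] * 365.25),
      badl_limited = obs$badl_limited[keep], iadl_limited = obs$iadl_limited[keep],
      vital = obs$vital[keep],
      death_day = baseline_date + round(obs$death_time[keep] * 365.25)
    )
    paths[[i]] <- list(subject_id = ids[i], gender = gender,
                       start_age = age0,
                       baseline_date = as.character(as.Date(baseline_date, origin = "1970-01-01")),
                       wave_times = wave_times, path = path,
                       death_date_missing = ddm)
  }
  n_per <- vapply(rows, function(r) length(r$interview_day), 0L)
  day2chr <- function(d) {
    out <- rep(NA_character_, length(d))
    ok <- !is.na(d)
    out[ok] <- as.character(as.Date(d[ok], origin = "1970-01-01"))
    out
  }
  row_df <- data.frame(
    subject_id = rep(ids, n_per),
    gender = rep(vapply(rows, `[[`, 0, "gender"), n_per),
    birth_date = day2chr(rep(vapply(rows, `[[`, 0, "birth_day"), n_per)),
    interview_date = day2chr(unlist(lapply(rows, `[[`, "interview_day"))),
    badl_limited = unlist(lapply(rows, `[[`, "badl_limited")),
    iadl_limited = unlist(lapply(rows, `[[`, "iadl_limited")),
    vital = unlist(lapply(rows, `[[`, "vital")),
    death_date = day2chr(unlist(lapply(rows, `[[`, "death_day"))),
    wave_index = unlist(lapply(n_per, seq_len)),
    stringsAsFactors = FALSE
  )
  out <- list(rows = row_df,
              truth = list(config = unclass(config), subjects = paths),
              config = config)
  class(out) <- "generated_dataset"
  out
}

#' @export
print.generated_dataset <- function(x, ...) {
  n <- x$config$n_subjects
  cat("Synthetic panel cohort:", n, "subjects,", nrow(x$rows), "interview rows\n")
  cat(sprintf("  women: %.1f%% | deaths recorded: %d (%.1f%%)\n",
              100 * mean(vapply(x$truth$subjects, function(s) as.numeric(s$gender), 0)),
              sum(x$rows$vital == "dead"),
              100 * sum(x$rows$vital == "dead") / n))
  invisible(x)
}

#' Write a generated dataset to disk
#'
#' Writes the raw interview rows as CSV and the latent truth (config plus
#' per-subject paths) as JSON, both stamped with the generator seed. The
#' CSV is byte-identical across runs with the same configuration.
#'
#' @param dataset A `"generated_dataset"` from [generate_panel_data()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_generated <- function(dataset, dir) {
  stopifnot(inherits(dataset, "generated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, sprintf("panel_seed%d.csv", dataset$config$seed))
  js <- file.path(dir, sprintf("truth_seed%d.json", dataset$config$seed))
  write.csv(dataset$rows, csv, row.names = FALSE, quote = FALSE, na = "")
  jsonlite::write_json(dataset$truth, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(panel = csv, truth = js))
}
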