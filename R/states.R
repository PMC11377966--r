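#' Classify an interview into one of four health states
#'
#' Applies the hierarchical state definition used throughout the package:
#' a dead vital status dominates everything; otherwise one or more limited
#' basic activities of daily living (BADL) puts the respondent in the BADL
#' state regardless of IADL limitations; otherwise one or more limited
#' instrumental activities (IADL) gives the IADL state; otherwise robust.
#' Classification depends only on limitation counts, not on which items are
#' limited, so cohorts with different item batteries are comparable.
#'
#' @param badl_limited Integer count(s) of limited BADL items (>= 0).
#' @param iadl_limited Integer count(s) of limited IADL items (>= 0).
#' @param vital Vital status: `"alive"` or `"dead"` (recycled as needed).
#' @return Integer state code(s): see [health_states()].
#' @examples
#' classify_state(0, 0, "alive") # robust
#' classify_state(2, 3, "alive") # badl (BADL dominates)
#' classify_state(0, 1, "alive") # iadl
#' @export
classify_state <- function(badl_limited, iadl_limited, vital) {
  n <- max(length(badl_limited), length(iadl_limited), length(vital))
  badl_limited <- rep_len(badl_limited, n)
  iadl_limited <- rep_len(iadl_limited, n)
  vital <- rep_len(tolower(as.character(vital)), n)
  if (!all(vital %in% c("alive", "dead"))) {
    stop("`vital` must be 'alive' or 'dead'")
  }
  dead <- vital == "dead"
  if (any(!dead & (is.na(badl_limited) | is.na(iadl_limited)))) {
    stop("missing limitation counts for an alive interview")
  }
  if (any(badl_limited[!dead] < 0) || any(iadl_limited[!dead] < 0)) {
    stop("limitation counts must be non-negative")
  }
  out <- rep.int(ROBUST, n)
  out[!dead & iadl_limited >= 1] <- IADL
  out[!dead & badl_limited >= 1] <- BADL
  out[dead] <- DEAD
  out
}

#' Impute a missing death date at the interval midpoint
#'
#' When a death is reported at a follow-up wave without a recorded date, the
#' death is placed at the day-resolution midpoint of the interval between
#' the last interview at which the subject was alive and the wave at which
#' the death was reported (odd day spans are floored).
#'
#' @param last_alive_interview `Date` of the last interview alive.
#' @param next_wave_reference `Date` of the wave reporting the death.
#' @return A `Date` midway between the two inputs.
#' @examples
#' impute_death_date(as.Date("2013-07-01"), as.Date("2015-07-01"))
#' @seealso [impute_death_date_variant()] for the sensitivity-analysis
#'   placements at the interval edges.
#' @export
impute_death_date <- function(last_alive_interview, next_wave_reference) {
  impute_death_date_variant(last_alive_interview, next_wave_reference, "midpoint")
}

#' Death-date placement within the censoring interval
#'
#' Generalises [impute_death_date()] for sensitivity analysis: the missing
#' death date can be placed just after the last interview alive (`"early"`),
#' at the interval midpoint (`"midpoint"`), or just before the reporting
#' wave (`"late"`). Degenerate zero-length intervals return the shared date.
#'
#' @inheritParams impute_death_date
#' @param mode One of `"early"`, `"midpoint"`, `"late"`.
#' @return A `Date` inside `[last_alive_interview, next_wave_reference]`.
#' @export
impute_death_date_variant <- function(last_alive_interview, next_wave_reference,
                                      mode = c("midpoint", "early", "late")) {
  mode <- match.arg(mode)
  d1 <- as.Date(last_alive_interview)
  d2 <- as.Date(next_wave_reference)
  if (any(is.na(d1)) || any(is.na(d2))) stop("dates must not be missing")
  if (any(d2 < d1)) stop("next_wave_reference precedes last_alive_interview")
  span <- as.integer(d2 - d1)
  out <- switch(mode,
    midpoint = d1 + span %/% 2L,
    early = pmin(d1 + 1L, d2),
    late = pmax(d2 - 1L, d1)
  )
  out
}

# Years between two Dates on the average-Gregorian-year scale.
years_between <- function(d1, d2) as.numeric(d2 - d1) / 365.25

#' Build validated subject panels from raw interview rows
#'
#' Groups raw interview rows by subject, orders them in time, classifies
#' health states (unless a pre-coded `state` column is supplied), imputes
#' missing death dates within the reporting interval, and enforces the
#' panel invariants: strictly increasing dates, entry age of at least 50,
#' and at most one terminal dead record per subject. Subjects entering
#' below age 50 or with fewer than two usable observations are dropped and
#' counted in the exclusion summary; alive waves with missing limitation
#' counts are dropped as item non-response.
#'
#' @param rows A data frame with one row per subject-interview. Required
#'   columns: `subject_id`, `gender` (0 man / 1 woman), `interview_date`
#'   (ISO-8601 or `Date`), `vital` (`"alive"`/`"dead"`), and either
#'   `badl_limited` + `iadl_limited` counts or a pre-coded `state` column
#'   (1-4). Optional: `birth_date` or `age_years` (at least one must be
#'   present), `death_date`, `death_date_imputed`.
#' @param death_mode Placement of missing death dates inside the reporting
#'   interval, see [impute_death_date_variant()]. The default `"midpoint"`
#'   is the primary analysis; `"early"`/`"late"` support the sensitivity
#'   analysis.
#' @return A data frame of class `"health_panels"`: one row per retained
#'   observation with columns `subject_id`, `gender`, `date` (interview
#'   date, or death date for the dead record), `interview_date`,
#'   `age_years`, `badl_limited`, `iadl_limited`, `vital`, `state`,
#'   `death_date`, `death_date_imputed` and `time` (years since the
#'   subject's first interview). The `"exclusions"` attribute summarises
#'   dropped subjects and waves.
#' @examples
#' rows <- data.frame(
#'   subject_id = "s1", gender = 0,
#'   age_years = c(65, NA, NA),
#'   interview_date = c("2010-01-01", "2012-01-01", "2014-01-01"),
#'   badl_limited = c(0, 0, NA), iadl_limited = c(0, 1, NA),
#'   vital = c("alive", "alive", "dead"),
#'   death_date = NA_character_
#' )
#' p <- build_panels(rows)
#' attr(p, "exclusions")
#' @export
build_panels <- function(rows, death_mode = c("midpoint", "early", "late")) {
  death_mode <- match.arg(death_mode)
  rows <- as.data.frame(rows)
  req <- c("subject_id", "gender", "interview_date", "vital")
  miss <- setdiff(req, names(rows))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!("birth_date" %in% names(rows)) && !("age_years" %in% names(rows))) {
    stop("need a birth_date or age_years column")
  }
  has_counts <- all(c("badl_limited", "iadl_limited") %in% names(rows))
  has_state <- "state" %in% names(rows)
  if (!has_counts && !has_state) {
    stop("need badl_limited/iadl_limited counts or a pre-coded state column")
  }

  rows$interview_date <- as.Date(rows$interview_date)
  if (any(is.na(rows$interview_date))) stop("unparseable interview_date")
  rows$vital <- tolower(as.character(rows$vital))
  if (!all(rows$vital %in% c("alive", "dead"))) stop("vital must be 'alive' or 'dead'")
  if (!all(rows$gender %in% c(0, 1))) stop("gender must be coded 0 (man) / 1 (woman)")
  if ("death_date" %in% names(rows)) {
    rows$death_date <- as.Date(rows$death_date)
  } else {
    rows$death_date <- as.Date(NA)
  }
  if (!("death_date_imputed" %in% names(rows))) rows$death_date_imputed <- FALSE
  rows$death_date_imputed[is.na(rows$death_date_imputed)] <- FALSE
  if (!has_counts) {
    rows$badl_limited <- NA_integer_
    rows$iadl_limited <- NA_integer_
  }
  if ("birth_date" %in% names(rows)) rows$birth_date <- as.Date(rows$birth_date)

  if (anyDuplicated(rows[, c("subject_id", "interview_date")])) {
    stop("duplicate (subject_id, interview_date) rows")
  }
  if (any(rows$vital == "alive" & !is.na(rows$death_date))) {
    stop("death_date present on an alive row")
  }

  # flatten to plain vectors ordered by (subject, date); all per-subject
  # work below runs on integer day counts for speed
  o <- order(rows$subject_id, rows$interview_date)
  sid <- as.character(rows$subject_id)[o]
  gen <- rows$gender[o]
  iday <- as.integer(rows$interview_date)[o]
  vital <- rows$vital[o]
  badl <- rows$badl_limited[o]
  iadl <- rows$iadl_limited[o]
  dday <- as.integer(rows$death_date)[o]
  dimp <- as.logical(rows$death_date_imputed)[o]
  bday <- if ("birth_date" %in% names(rows)) as.integer(rows$birth_date)[o] else rep(NA_integer_, length(o))
  given_age <- if ("age_years" %in% names(rows)) rows$age_years[o] else rep(NA_real_, length(o))
  precoded <- if (has_state) suppressWarnings(as.integer(rows$state[o])) else rep(NA_integer_, length(o))

  nr <- length(sid)
  firsts <- which(!duplicated(sid))
  lasts <- c(firsts[-1] - 1L, nr)

  excl <- list(
    n_subjects_in = length(firsts),
    dropped_entry_age = 0L, dropped_too_few_obs = 0L,
    waves_dropped_missing_items = 0L
  )

  keep <- logical(nr)
  state_out <- integer(nr)
  age_out <- numeric(nr)
  day_out <- integer(nr) # effective event day (death day on the dead row)
  time_out <- numeric(nr)
  dday_out <- dday
  dimp_out <- dimp
  n_kept <- 0L

  for (si in seq_along(firsts)) {
    idx <- firsts[si]:lasts[si]
    id <- sid[idx[1]]

    # vital-status monotonicity
    dead_pos <- which(vital[idx] == "dead")
    if (length(dead_pos) > 1L) stop("subject ", id, ": multiple death records")
    if (length(dead_pos) == 1L && dead_pos != length(idx)) {
      stop("subject ", id, ": alive record after death")
    }

    # state: pre-coded when available, else classified (alive waves with
    # missing counts are item non-response and are dropped)
    if (has_state && !all(is.na(precoded[idx]))) {
      st <- precoded[idx]
      if (any(is.na(st)) || !all(st %in% 1:4)) {
        stop("subject ", id, ": invalid pre-coded state")
      }
      if (any((st == DEAD) != (vital[idx] == "dead"))) {
        stop("subject ", id, ": state and vital status disagree")
      }
    } else {
      usable <- vital[idx] == "dead" | (!is.na(badl[idx]) & !is.na(iadl[idx]))
      excl$waves_dropped_missing_items <- excl$waves_dropped_missing_items + sum(!usable)
      idx <- idx[usable]
      if (length(idx) == 0L) {
        excl$dropped_too_few_obs <- excl$dropped_too_few_obs + 1L
        next
      }
      dead <- vital[idx] == "dead"
      st <- classify_state(ifelse(dead, 0L, badl[idx]),
                           ifelse(dead, 0L, iadl[idx]), vital[idx])
    }

    # ages: from birth date when available, cross-checked against age_years
    if (!all(is.na(bday[idx]))) {
      bd <- bday[idx][!is.na(bday[idx])][1]
      age <- (iday[idx] - bd) / 365.25
      bad <- !is.na(given_age[idx]) & abs(given_age[idx] - age) > 1
      if (any(bad)) stop("subject ", id, ": age_years inconsistent with birth date")
    } else {
      ga <- given_age[idx]
      if (all(is.na(ga))) stop("subject ", id, ": no usable age information")
      anchor <- which(!is.na(ga))[1]
      age <- ga[anchor] + (iday[idx] - iday[idx][anchor]) / 365.25
    }

    # eligibility: entry at age >= 50
    if (age[1] < 50) {
      excl$dropped_entry_age <- excl$dropped_entry_age + 1L
      next
    }

    # death date: recorded, or imputed within the reporting interval
    di <- which(st == DEAD)
    if (length(di) == 1L) {
      if (di == 1L) { # death with no prior alive interview is unusable
        excl$dropped_too_few_obs <- excl$dropped_too_few_obs + 1L
        next
      }
      k <- idx[di]
      if (is.na(dday_out[k])) {
        dday_out[k] <- as.integer(impute_death_date_variant(
          as.Date(iday[idx][di - 1L], origin = "1970-01-01"),
          as.Date(iday[idx][di], origin = "1970-01-01"), death_mode
        ))
        dimp_out[k] <- TRUE
      }
      if (dday_out[k] < iday[idx][di - 1L]) {
        stop("subject ", id, ": death date precedes last interview alive")
      }
    }

    if (length(idx) < 2L) {
      excl$dropped_too_few_obs <- excl$dropped_too_few_obs + 1L
      next
    }

    # effective event day: interview day, or the death day on the dead row
    day <- iday[idx]
    if (length(di) == 1L) {
      day[di] <- dday_out[idx[di]]
      age[di] <- age[di - 1L] + (day[di] - iday[idx][di - 1L]) / 365.25
    }
    if (any(diff(day) < 0)) stop("subject ", id, ": dates not increasing")

    keep[idx] <- TRUE
    state_out[idx] <- st
    age_out[idx] <- age
    day_out[idx] <- day
    time_out[idx] <- (day - day[1]) / 365.25
    n_kept <- n_kept + 1L
  }

  panels <- data.frame(
    subject_id = sid[keep], gender = gen[keep],
    date = as.Date(day_out[keep], origin = "1970-01-01"),
    interview_date = as.Date(iday[keep], origin = "1970-01-01"),
    age_years = age_out[keep],
    badl_limited = badl[keep], iadl_limited = iadl[keep],
    vital = vital[keep], state = state_out[keep],
    death_date = as.Date(dday_out[keep], origin = "1970-01-01"),
    death_date_imputed = dimp_out[keep],
    time = time_out[keep],
    stringsAsFactors = FALSE
  )
  rownames(panels) <- NULL
  excl$n_subjects_kept <- n_kept
  attr(panels, "exclusions") <- excl
  class(panels) <- c("health_panels", "data.frame")
  panels
}

#' @export
print.health_panels <- function(x, ...) {
  e <- attr(x, "exclusions")
  cat("Health-state panels:", e$n_subjects_kept, "subjects,",
      nrow(x), "observations\n")
  cat("  deaths observed:", sum(x$state == DEAD),
      sprintf("(%d with imputed dates)\n", sum(x$death_date_imputed, na.rm = TRUE)))
  cat("  excluded: entry age <50:", e$dropped_entry_age,
      "| <2 usable waves:", e$dropped_too_few_obs,
      "| waves with missing items:", e$waves_dropped_missing_items, "\n")
  invisible(x)
}

#' Read / write validated panel CSV files
#'
#' Plain-CSV serialisation of the validated panel layout produced by
#' [build_panels()]; `read_panel_csv` restores the class and column types
#' so a written panel round-trips exactly.
#'
#' @param panels A `"health_panels"` data frame.
#' @param path File path.
#' @return `read_panel_csv` returns a `"health_panels"` data frame.
#' @export
write_panel_csv <- function(panels, path) {
  write.csv(as.data.frame(panels), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("date", "interview_date", "death_date")) {
    df[[col]] <- as.Date(df[[col]])
  }
  df$death_date_imputed <- as.logical(df$death_date_imputed)
  class(df) <- c("health_panels", "data.frame")
  df
}
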