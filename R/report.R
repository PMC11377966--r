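#' Baseline descriptive summary of a panel cohort
#'
#' Counts and percentages of subjects by gender, baseline age band (50-59,
#' 60-69, 70-79, 80-89, 90+), baseline health state, and death during
#' follow-up — the standard baseline-characteristics layout for ageing
#' panel cohorts.
#'
#' @param panels A `"health_panels"` data frame from [build_panels()].
#' @return A data frame of class `"baseline_summary"` with columns
#'   `characteristic`, `level`, `n`, `pct`. Percentages within each
#'   characteristic sum to 100 (deaths are reported against the full
#'   cohort: died / survived).
#' @export
baseline_summary <- function(panels) {
  df <- as.data.frame(panels)
  df <- df[order(df$subject_id, df$time), ]
  first <- df[!duplicated(df$subject_id), ]
  n <- nrow(first)
  died <- tapply(df$state == 4, df$subject_id, any)[first$subject_id]

  band <- cut(first$age_years, c(50, 60, 70, 80, 90, Inf), right = FALSE,
              labels = c("50-59", "60-69", "70-79", "80-89", "90+"))
  blocks <- list(
    gender = table(factor(c("man", "woman")[first$gender + 1L],
                          levels = c("man", "woman"))),
    age_band = table(band),
    baseline_state = table(factor(STATE_LABELS[first$state],
                                  levels = STATE_LABELS[1:3])),
    deaths_during_followup = table(factor(ifelse(died, "died", "survived"),
                                          levels = c("died", "survived")))
  )
  out <- do.call(rbind, lapply(names(blocks), function(nm) {
    tb <- blocks[[nm]]
    data.frame(characteristic = nm, level = names(tb), n = as.integer(tb),
               pct = 100 * as.integer(tb) / n)
  }))
  rownames(out) <- NULL
  class(out) <- c("baseline_summary", "data.frame")
  out
}

#' Serialise a model fit to JSON and back
#'
#' Stores the estimates, covariance, log-likelihood, convergence
#' diagnostics, transition structure and settings of an `"msm_fit"` in a
#' plain JSON file; `read_fit_json` restores a fit usable by [wald_hr()]
#' and [horizon_probability_table()].
#'
#' @param fit An `"msm_fit"` from [fit_mle()].
#' @param path File path.
#' @return `read_fit_json` returns an `"msm_fit"` object.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "msm_fit"))
  payload <- list(
    estimates = as.list(fit$estimates),
    covariance = fit$covariance,
    loglik = fit$loglik, converged = fit$converged,
    n_subjects = fit$n_subjects, n_transitions = fit$n_transitions,
    gradient_max = fit$gradient_max, dropped = fit$dropped,
    structure = as.data.frame(fit$structure),
    covariate_names = fit$covariate_names,
    settings = fit$settings,
    package_version = as.character(utils::packageVersion("mshale"))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  est <- unlist(p$estimates)
  fit <- list(
    estimates = est,
    covariance = matrix(unlist(p$covariance), length(est), length(est),
                        dimnames = list(names(est), names(est))),
    loglik = p$loglik, converged = p$converged,
    n_subjects = p$n_subjects, n_transitions = p$n_transitions,
    gradient_max = p$gradient_max,
    dropped = if (length(p$dropped)) p$dropped else character(0),
    structure = transition_structure(as.matrix(p$structure[, c("from", "to")])),
    covariate_names = p$covariate_names,
    settings = p$settings
  )
  class(fit) <- "msm_fit"
  fit
}

#' Write a life-expectancy or gap table as CSV
#'
#' @param table A data frame (e.g. an `"le_table"` or a [gender_gap()]
#'   result).
#' @param path File path.
#' @export
write_le_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Records everything needed to reproduce a run: the configuration
#' object(s), the seed, and the package version. Written as JSON when a
#' path is given.
#'
#' @param config A configuration object or named list of them (classes are
#'   recorded and stripped for serialisation).
#' @param seed The integer seed that drove the run.
#' @param path Optional output path for the JSON manifest.
#' @return The manifest as a list, invisibly when written to disk.
#' @export
run_manifest <- function(config, seed, path = NULL) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  manifest <- list(
    package = "mshale",
    package_version = as.character(utils::packageVersion("mshale")),
    seed = as.integer(seed),
    config = strip(config)
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
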