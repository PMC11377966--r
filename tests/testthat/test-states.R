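test_that("state classification follows the BADL-dominant hierarchy", {
  expect_identical(classify_state(0, 0, "alive"), 1L) # robust
  expect_identical(classify_state(0, 1, "alive"), 2L) # iadl only
  expect_identical(classify_state(2, 3, "alive"), 3L) # badl dominates iadl
  expect_identical(classify_state(1, 0, "alive"), 3L)
  expect_identical(classify_state(0, 0, "dead"), 4L)  # vital status dominates
  expect_identical(classify_state(5, 7, "dead"), 4L)
  # vectorised
  expect_identical(classify_state(c(0, 0, 2), c(0, 3, 0), "alive"), c(1L, 2L, 3L))
})

test_that("classification rejects invalid inputs", {
  expect_error(classify_state(-1, 0, "alive"), "non-negative")
  expect_error(classify_state(0, -2, "alive"), "non-negative")
  expect_error(classify_state(0, 0, "deceased"), "alive")
  expect_error(classify_state(NA, 0, "alive"), "missing")
})

test_that("midpoint death-date imputation is exact day arithmetic", {
  expect_equal(impute_death_date(as.Date("2013-07-01"), as.Date("2015-07-01")),
               as.Date("2014-07-01"))
  expect_equal(impute_death_date(as.Date("2014-01-01"), as.Date("2014-01-01")),
               as.Date("2014-01-01"))
  # odd span: floor((d2 - d1) / 2) days added, checked by day-count oracle
  d1 <- as.Date("2011-06-01")
  d2 <- as.Date("2013-06-03")
  expect_equal(impute_death_date(d1, d2), d1 + floor(as.integer(d2 - d1) / 2))
  expect_equal(impute_death_date(d1, d2), as.Date("2012-06-01"))
  expect_error(impute_death_date(d2, d1), "precedes")
})

test_that("early/late variants sit just inside the interval edges", {
  d1 <- as.Date("2013-07-01")
  d2 <- as.Date("2015-07-01")
  expect_equal(impute_death_date_variant(d1, d2, "early"), as.Date("2013-07-02"))
  expect_equal(impute_death_date_variant(d1, d2, "late"), as.Date("2015-06-30"))
  expect_equal(impute_death_date_variant(d1, d2, "midpoint"), as.Date("2014-07-01"))
})

test_that("every imputation mode stays inside the censoring interval", {
  set.seed(11)
  for (i in 1:200) {
    d1 <- as.Date("2010-01-01") + sample.int(2000, 1)
    d2 <- d1 + sample.int(1200, 1) - 1L
    for (mode in c("early", "midpoint", "late")) {
      d <- impute_death_date_variant(d1, d2, mode)
      expect_true(d >= d1 && d <= d2)
    }
  }
})

raw_rows <- function() {
  data.frame(
    subject_id = rep(c("a", "b"), c(3, 3)),
    gender = rep(c(0, 1), c(3, 3)),
    age_years = c(61, NA, NA, 72, NA, NA),
    interview_date = rep(c("2010-03-01", "2012-03-01", "2014-03-01"), 2),
    badl_limited = c(0, 0, NA, 0, 1, 2),
    iadl_limited = c(0, 1, NA, 2, 0, 2),
    vital = c("alive", "alive", "dead", "alive", "alive", "alive"),
    death_date = NA_character_
  )
}

test_that("build_panels composes classification and death imputation", {
  p <- build_panels(raw_rows())
  a <- p[p$subject_id == "a", ]
  expect_identical(a$state, c(1L, 2L, 4L))
  # dead record carries the midpoint of the reporting interval
  expect_equal(a$death_date[3],
               impute_death_date(as.Date("2012-03-01"), as.Date("2014-03-01")))
  expect_true(a$death_date_imputed[3])
  expect_equal(a$time[3], as.numeric(a$death_date[3] - a$date[1]) / 365.25)
  b <- p[p$subject_id == "b", ]
  expect_identical(b$state, c(2L, 3L, 3L))
  expect_true(all(diff(a$time) > 0) && all(diff(b$time) > 0))
  expect_true(all(tapply(p$age_years, p$subject_id, min) >= 50))
})

test_that("build_panels drops short and under-age subjects with a count", {
  rows <- raw_rows()
  rows <- rbind(rows, data.frame(
    subject_id = c("single", "young", "young"), gender = 0,
    age_years = c(70, 45, NA),
    interview_date = c("2010-05-01", "2010-05-01", "2012-05-01"),
    badl_limited = 0, iadl_limited = 0, vital = "alive",
    death_date = NA_character_
  ))
  p <- build_panels(rows)
  e <- attr(p, "exclusions")
  expect_identical(sort(unique(p$subject_id)), c("a", "b"))
  expect_identical(e$dropped_too_few_obs, 1L)
  expect_identical(e$dropped_entry_age, 1L)
  expect_identical(e$n_subjects_kept, 2L)
})

test_that("waves with missing item counts are dropped as non-response", {
  rows <- raw_rows()
  rows$badl_limited[5] <- NA # subject b, wave 2
  p <- build_panels(rows)
  expect_identical(nrow(p[p$subject_id == "b", ]), 2L)
  expect_identical(attr(p, "exclusions")$waves_dropped_missing_items, 1L)
})

test_that("build_panels rejects inconsistent raw data", {
  rows <- raw_rows()
  rows$interview_date[2] <- rows$interview_date[1]
  expect_error(build_panels(rows), "duplicate")

  rows <- raw_rows()
  rows$vital[4] <- "dead" # subject b: alive records follow a death
  expect_error(build_panels(rows), "after death")

  rows <- raw_rows()
  rows$birth_date <- as.character(as.Date(rows$interview_date[1]) - 30 * 365.25)
  expect_error(build_panels(rows), "inconsistent")
})

test_that("build_panels is idempotent on its own output", {
  p1 <- build_panels(raw_rows())
  p2 <- build_panels(as.data.frame(p1))
  expect_equal(as.data.frame(p2), as.data.frame(p1), tolerance = 1e-10)
})

test_that("panel CSV serialisation round-trips", {
  p1 <- build_panels(raw_rows())
  f <- tempfile(fileext = ".csv")
  write_panel_csv(p1, f)
  p2 <- read_panel_csv(f)
  expect_equal(as.data.frame(p2)$state, as.data.frame(p1)$state)
  expect_equal(p2$death_date, p1$death_date)
  expect_equal(p2$time, p1$time, tolerance = 1e-9)
  unlink(f)
})
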