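# Monthly aggregation and panel serialization.

test_that("monthly cells sum the sessions of that month", {
  df <- data.frame(
    dyad_id = "d1", group = "boy",
    month = c(5, 5, 6), session = c(1, 2, 1),
    code = "Reach", duration_s = c(30, 15, 4), occurrences = c(3, 2, 1),
    stringsAsFactors = FALSE
  )
  pan <- aggregate_monthly(as_event_log(df), "duration_seconds")
  expect_equal(pan$values[1, "5", "Reach"], 45)   # 30 + 15, hand summed
  expect_equal(pan$values[1, "6", "Reach"], 4)

  occ <- aggregate_monthly(as_event_log(df), "occurrence_count")
  expect_equal(occ$values[1, "5", "Reach"], 5)

  # a code with no events in a month is an (explicit) zero, not a gap
  pan2 <- aggregate_monthly(as_event_log(df), "duration_seconds",
                            variables = c("Reach", "Cry"))
  expect_equal(pan2$values[1, , "Cry"], c("5" = 0, "6" = 0))
})

test_that("the mean statistic divides by the month's session count", {
  df <- data.frame(
    dyad_id = "d1", group = "boy",
    month = c(5, 5, 6, 6), session = c(1, 2, 1, 2),
    code = "Reach", duration_s = c(30, 15, 10, 0),
    occurrences = c(1, 1, 1, 0), stringsAsFactors = FALSE
  )
  pan <- aggregate_monthly(as_event_log(df), "duration_seconds",
                           stat = "mean")
  expect_equal(unname(pan$values[1, , "Reach"]), c(22.5, 5))
})

test_that("a dyad missing an entire month is a gap error", {
  df <- tiny_event_df()
  df <- df[!(df$dyad_id == "d2" & df$month == 4), ]
  expect_error(aggregate_monthly(as_event_log(df), "duration_seconds"),
               "gap error.*d2.*4")
})

test_that("aggregation conserves mass and ignores row order", {
  coh <- generate_cohort(generator_config(n_dyads_per_group = 3,
                                          seed = 21),
                         events = TRUE)
  ev <- coh$events
  for (enc in c("duration_seconds", "occurrence_count")) {
    pan <- aggregate_monthly(ev, enc)
    field <- if (enc == "duration_seconds") "duration_s" else "occurrences"
    # per dyad and per code, panel totals equal event-log totals
    for (d in pan$dyads$dyad_id) {
      rows <- ev$dyad_id == d
      log_tot <- tapply(ev[[field]][rows], ev$code[rows], sum)
      pan_tot <- apply(pan$values[match(d, pan$dyads$dyad_id), , ], 2, sum)
      expect_equal(pan_tot[names(log_tot)], log_tot[names(log_tot)],
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
    # permutation invariance (dyad order follows first appearance, so
    # align before comparing)
    set.seed(9)
    shuf <- aggregate_monthly(as_event_log(ev[sample(nrow(ev)), ]), enc)
    ord <- match(pan$dyads$dyad_id, shuf$dyads$dyad_id)
    expect_identical(unname(shuf$values[ord, , ]), unname(pan$values))
  }
})

test_that("panels round-trip through tidy CSV bit-exactly", {
  coh <- generate_cohort(generator_config(n_dyads_per_group = 2,
                                          seed = 5), events = TRUE)
  pan <- coh$panels$duration_seconds
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(pan, path)
  back <- read_panel(path)
  expect_identical(back$values, pan$values)
  expect_identical(back$variables, pan$variables)
  expect_identical(back$months, pan$months)
  expect_identical(back$dyads, pan$dyads)
  expect_identical(back$encoding, pan$encoding)
})

test_that("panel invariants are enforced", {
  vals <- array(1, dim = c(2, 3, 2))
  dy <- data.frame(dyad_id = c("a", "b"), group = "boy")
  expect_silent(monthly_panel(vals, dy, months = c(2, 4, 6),
                              variables = c("Crawl", "Cry")))
  expect_error(monthly_panel(vals, dy, months = c(2, 3, 6),
                             variables = c("Crawl", "Cry")),
               "equally spaced")
  neg <- vals; neg[1, 1, 1] <- -1
  expect_error(monthly_panel(neg, dy, months = 3:5,
                             variables = c("Crawl", "Cry"),
                             encoding = "duration_seconds"),
               "non-negative")
  expect_silent(monthly_panel(neg, dy, months = 3:5,
                              variables = c("Crawl", "Cry"),
                              encoding = "gaussian_latent"))
})

test_that("group splitting and variable selection preserve structure", {
  coh <- generate_cohort(generator_config(n_dyads_per_group = 3, seed = 2))
  by_g <- split_panel_by_group(coh$panel)
  expect_named(by_g, c("boy", "girl"))
  expect_equal(nrow(by_g$boy$dyads), 3)
  sub <- panel_select(coh$panel, c("Cry", "Crawl"))
  expect_identical(sub$variables, c("Cry", "Crawl"))
  expect_equal(sub$values[, , 2], coh$panel$values[, , "Crawl"],
               ignore_attr = TRUE)
  expect_error(panel_select(coh$panel, "Walks"), "Walks")
})
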