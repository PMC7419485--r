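# End-to-end study orchestration.

study_vars <- c("Crawl", "Stand Independently", "Points to Object",
                "Rocks/Jiggles Infant")

small_study_cfg <- function(seed = 11) {
  generator_config(n_dyads_per_group = 8, variables = study_vars,
                   coupling_by_group = default_coupling(study_vars),
                   seed = seed)
}

test_that("two groups x two encodings yields four fitted models", {
  rep <- run_study(small_study_cfg(), reps = 25, seed = 11)
  expect_s3_class(rep, "study_report")
  expect_length(rep$models, 4)
  expect_setequal(names(rep$models),
                  c("boy.duration_seconds", "girl.duration_seconds",
                    "boy.occurrence_count", "girl.occurrence_count"))
  for (e in rep$models) {
    expect_false(e$failed)
    expect_equal(e$p, 1)
    # coefficient bookkeeping: p*m^2 lagged + m intercepts
    expect_equal(length(unlist(e$model$B)), e$p * e$model$m^2)
    expect_length(e$model$intercepts, e$model$m)
    expect_named(e$sign_tables,
                 c("infant_responses", "maternal_responses"))
  }
  # combined tables exist for both directions
  expect_named(rep$tables, c("infant_responses", "maternal_responses"))
  expect_equal(dim(rep$tables$maternal_responses), c(2, 2))
})

test_that("restricting groups or encodings restricts the model count", {
  coh <- generate_cohort(small_study_cfg(), seed = 11, events = TRUE)
  boys <- split_panel_by_group(coh$panels$occurrence_count)$boy
  rep1 <- run_study(boys, reps = 10, seed = 3)
  expect_length(rep1$models, 1)
  expect_named(rep1$models, "boy.occurrence_count")

  rep2 <- run_study(coh, encodings = "duration_seconds", reps = 10,
                    seed = 3)
  expect_length(rep2$models, 2)
})

test_that("identical config and seed give byte-identical outputs", {
  a <- run_study(small_study_cfg(), reps = 20, seed = 9)
  b <- run_study(small_study_cfg(), reps = 20, seed = 9)
  expect_identical(a$tables, b$tables)
  for (key in names(a$models)) {
    expect_identical(a$models[[key]]$irf$lower, b$models[[key]]$irf$lower)
    expect_identical(a$models[[key]]$model$B, b$models[[key]]$model$B)
  }
  out_a <- withr::local_tempdir(); out_b <- withr::local_tempdir()
  man_a <- write_report(a, out_a, force = TRUE)
  man_b <- write_report(b, out_b, force = TRUE)
  expect_identical(man_a$md5, man_b$md5)
})

test_that("a study runs end to end from an event log on disk", {
  coh <- generate_cohort(small_study_cfg(), seed = 4, events = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(coh$events, path)
  rep <- run_study(path, reps = 10, seed = 4)
  expect_length(rep$models, 4)
  # aggregation inside the study matches the generator's own panels
  # (variable order may differ: align by name before comparing)
  direct <- fit_var(split_panel_by_group(
    coh$panels$occurrence_count)$boy, p = 1)
  got <- rep$models[["boy.occurrence_count"]]$model$B[[1]]
  v <- rownames(direct$B[[1]])
  expect_max_abs(got[v, v], direct$B[[1]], 1e-10)
})

test_that("write_report refuses to clobber and checksums verify", {
  rep <- run_study(small_study_cfg(), reps = 10, seed = 6)
  out <- withr::local_tempdir()
  manifest <- write_report(rep, out, force = TRUE)
  # >= 4 model files and >= 4 sign tables in the manifest
  expect_gte(sum(grepl("^model_", manifest$file)), 4)
  expect_gte(sum(grepl("^signs_", manifest$file)), 4)
  # checksums match the files on disk
  again <- tools::md5sum(file.path(out, manifest$file))
  expect_identical(unname(again), manifest$md5)
  expect_error(write_report(rep, out), "refusing")
  expect_silent(write_report(rep, out, force = TRUE))
})

test_that("a failing model is recorded without sinking the study", {
  coh <- generate_cohort(small_study_cfg(), seed = 12, events = TRUE)
  pan <- coh$panels$occurrence_count
  vals <- pan$values
  vals[pan$dyads$group == "girl", , 1] <- 2   # constant column for girls
  broken <- monthly_panel(vals, dyads = pan$dyads, months = pan$months,
                          variables = pan$variables,
                          encoding = pan$encoding)
  rep <- run_study(broken, reps = 10, seed = 5)
  expect_true(rep$models[["girl.occurrence_count"]]$failed)
  expect_match(rep$models[["girl.occurrence_count"]]$error, "Crawl")
  expect_false(rep$models[["boy.occurrence_count"]]$failed)
})
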