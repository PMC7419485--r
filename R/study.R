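# End-to-end study orchestration: group x encoding VAR-IRF models.

#' Run the full dyadic VAR-IRF study
#'
#' Orchestrates the study design end to end: obtains monthly panels from
#' an event log (on disk or in memory), a synthetic cohort, or a
#' pre-built panel; splits the dyads by group; and for each group and
#' each encoding selects (or fixes) the lag order, fits the pooled VAR,
#' runs residual diagnostics, performs the conservative entered-last IRF
#' sweep with bootstrap bands, and assembles sign tables. With the
#' default two groups and two encodings this yields four fitted models.
#' Each group is modeled separately; group membership never enters a
#' model as a predictor.
#'
#' Sign tables are built in both directions when the variables come from
#' the standard vocabulary: infant-behavior responses to maternal-behavior
#' impulses, and maternal responses to infant impulses. Otherwise a single
#' all-pairs table is built.
#'
#' @param source One of: a path to an event log file, an `event_log`
#'   data frame, a [generator_config()] (a synthetic cohort is generated),
#'   a `dyad_cohort`, or a [monthly_panel()].
#' @param encodings Encodings to run (default both). Ignored when
#'   `source` is already a panel or a latent-emission cohort.
#' @param lag `"fixed"` (use `p`) or `"auto"` ([select_lag()] up to
#'   `p_max`).
#' @param p Lag order when `lag = "fixed"` (default 1).
#' @param p_max Cap for automatic lag selection (default 4).
#' @param alpha Diagnostics level (default 0.05).
#' @param horizon IRF horizon in months (default 10).
#' @param reps Bootstrap replicates (default 100).
#' @param level Confidence level in percent (default 95).
#' @param window Sign-table significance window in months (default `1:3`).
#' @param seed Master seed; each model's bootstrap seed is derived from it
#'   deterministically.
#' @param monthly_stat Aggregation statistic across a month's sessions
#'   (`"sum"` or `"mean"`).
#' @param ... Passed to [fit_var()].
#' @return Object of class `"study_report"`: list with `models` (one
#'   entry per group x encoding carrying the fit, diagnostics,
#'   conservative IRFs and sign tables, or a failure record), `tables`
#'   (rendered bracket-dialect matrices, when both directions exist),
#'   and `meta`.
#' @export
run_study <- function(source,
                      encodings = c("duration_seconds",
                                    "occurrence_count"),
                      lag = c("fixed", "auto"), p = 1L, p_max = 4L,
                      alpha = 0.05, horizon = 10L, reps = 100L,
                      level = 95, window = 1:3, seed = 1L,
                      monthly_stat = "sum", ...) {
  lag <- match.arg(lag)
  encodings <- match.arg(encodings, several.ok = TRUE)
  t0 <- Sys.time()

  panels <- .study_panels(source, encodings, seed, monthly_stat)

  models <- list()
  idx <- 0L
  for (enc in names(panels)) {
    by_group <- split_panel_by_group(panels[[enc]])
    if (any(vapply(by_group, function(pp) nrow(pp$dyads), 0L) < 1L)) {
      stop("configuration error: empty group in panel", call. = FALSE)
    }
    for (g in names(by_group)) {
      idx <- idx + 1L
      key <- paste(g, enc, sep = ".")
      model_seed <- seed + 1000L * idx
      entry <- tryCatch(
        .study_fit_one(by_group[[g]], lag, p, p_max, alpha, horizon,
                       reps, level, window, model_seed, ...),
        error = function(e) {
          list(failed = TRUE, error = conditionMessage(e),
               reports = attr(e, "reports"))
        })
      entry$group <- g
      entry$encoding <- enc
      entry$seed <- model_seed
      if (is.null(entry$failed)) entry$failed <- FALSE
      models[[key]] <- entry
    }
  }

  tables <- .study_tables(models)
  structure(
    list(models = models, tables = tables,
         meta = list(seed = seed, lag = lag, p = p, p_max = p_max,
                     alpha = alpha, horizon = horizon, reps = reps,
                     level = level, window = window,
                     encodings = names(panels),
                     package_version =
                       as.character(utils::packageVersion("dyadVAR")),
                     started = t0, finished = Sys.time())),
    class = "study_report"
  )
}

# Resolve the input source into a named list of panels per encoding.
.study_panels <- function(source, encodings, seed, monthly_stat) {
  if (is.character(source) && length(source) == 1L) {
    source <- read_event_log(source)
  }
  if (inherits(source, "generator_config")) {
    source <- generate_cohort(source, seed = seed,
                              events = source$emission == "poisson_counts")
  }
  if (inherits(source, "dyad_cohort")) {
    if (source$config$emission == "gaussian_latent") {
      return(list(gaussian_latent = source$panel))
    }
    return(source$panels[encodings])
  }
  if (inherits(source, "monthly_panel")) {
    out <- list(source)
    names(out) <- source$encoding
    return(out)
  }
  if (inherits(source, "event_log") || is.data.frame(source)) {
    events <- as_event_log(source)
    out <- lapply(encodings, function(enc) {
      aggregate_monthly(events, encoding = enc, stat = monthly_stat)
    })
    names(out) <- encodings
    return(out)
  }
  stop("unsupported study source of class ",
       paste(class(source), collapse = "/"), call. = FALSE)
}

.study_fit_one <- function(panel, lag, p, p_max, alpha, horizon, reps,
                           level, window, seed, ...) {
  if (lag == "auto") {
    sel <- select_lag(panel, p_max = p_max, alpha = alpha, ...)
    p_use <- sel$p
    model <- sel$model
    reports <- sel$reports
  } else {
    p_use <- p
    model <- fit_var(panel, p = p, ...)
    reports <- NULL
  }
  diag_m <- var_diagnostics(model, alpha = alpha)
  cons <- conservative_irf_sweep(panel, p = p_use, horizon = horizon,
                                 reps = reps, level = level, seed = seed,
                                 ...)
  roles <- code_role(panel$variables)
  infant <- panel$variables[roles %in% "infant"]
  maternal <- panel$variables[roles %in% "maternal"]
  sign_tables <- if (length(infant) > 0L && length(maternal) > 0L) {
    list(
      infant_responses = build_sign_table(cons, impulses = maternal,
                                          responses = infant,
                                          window = window),
      maternal_responses = build_sign_table(cons, impulses = infant,
                                            responses = maternal,
                                            window = window)
    )
  } else {
    list(all_pairs = build_sign_table(cons, window = window))
  }
  list(p = p_use, model = model, diagnostics = diag_m,
       lag_reports = reports, irf = cons, sign_tables = sign_tables,
       failed = FALSE)
}

# Bracket-dialect matrices combining groups and encodings, one per
# direction, when both encodings were run on standard-vocabulary panels.
.study_tables <- function(models) {
  ok <- !vapply(models, function(x) isTRUE(x$failed), logical(1))
  models <- models[ok]
  if (length(models) == 0L) return(NULL)
  directions <- unique(unlist(lapply(models, function(x) {
    names(x$sign_tables)
  })))
  out <- list()
  for (dir in directions) {
    dur <- list(); occ <- list()
    for (x in models) {
      if (is.null(x$sign_tables[[dir]])) next
      if (x$encoding == "duration_seconds") {
        dur[[x$group]] <- x$sign_tables[[dir]]
      } else if (x$encoding == "occurrence_count") {
        occ[[x$group]] <- x$sign_tables[[dir]]
      } else {
        dur[[x$group]] <- x$sign_tables[[dir]]   # latent: single encoding
      }
    }
    out[[dir]] <- render_sign_matrix(
      duration = if (length(dur)) dur else NULL,
      occurrence = if (length(occ)) occ else NULL)
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("Dyadic VAR-IRF study report:", length(x$models), "model(s)\n")
  for (key in names(x$models)) {
    e <- x$models[[key]]
    if (isTRUE(e$failed)) {
      cat(sprintf("  %-30s FAILED: %s\n", key, e$error))
    } else {
      cat(sprintf(
        "  %-30s p = %d, diagnostics %s, %d significant pair(s)\n",
        key, e$p, if (e$diagnostics$pass) "pass" else "FAIL",
        sum(vapply(e$sign_tables, function(tt) sum(tt != ""), 0L))))
    }
  }
  cat("  seed:", x$meta$seed, "\n")
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes, per model: the VAR coefficients and diagnostics as JSON, the
#' conservative IRF curves and bands as tidy CSV, and each sign table as
#' CSV; plus the combined bracket-dialect tables, a plain-text
#' diagnostics summary, and `manifest.csv` listing every written file
#' with its MD5 checksum.
#'
#' @param report A `"study_report"`.
#' @param outdir Output directory.
#' @param force Overwrite a non-empty existing directory (default
#'   `FALSE`: refuse).
#' @return Data frame manifest (file, md5), invisibly.
#' @export
write_report <- function(report, outdir, force = FALSE) {
  stopifnot(inherits(report, "study_report"))
  if (dir.exists(outdir) &&
      length(list.files(outdir, all.files = TRUE, no.. = TRUE)) > 0L &&
      !force) {
    stop("refusing to write into non-empty directory ", sQuote(outdir),
         "; use force = TRUE to overwrite", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(f) files <<- c(files, f)

  diag_lines <- character(0)
  for (key in names(report$models)) {
    e <- report$models[[key]]
    if (isTRUE(e$failed)) {
      diag_lines <- c(diag_lines,
                      sprintf("%s: FAILED (%s)", key, e$error))
      next
    }
    mf <- file.path(outdir, paste0("model_", key, ".json"))
    jsonlite::write_json(serialize_var_model(e$model, e$diagnostics),
                         mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    put(mf)

    irf_df <- .irf_long(e$irf)
    cf <- file.path(outdir, paste0("irf_", key, ".csv"))
    utils::write.csv(irf_df, cf, row.names = FALSE)
    put(cf)

    for (dir_name in names(e$sign_tables)) {
      sf <- file.path(outdir,
                      paste0("signs_", key, "_", dir_name, ".csv"))
      utils::write.csv(as.data.frame(unclass(e$sign_tables[[dir_name]])),
                       sf, row.names = TRUE)
      put(sf)
    }
    diag_lines <- c(diag_lines, sprintf(
      "%s: p = %d; Portmanteau p = %.4f; ARCH-LM p = %.4f; max|eig| = %.4f; %s",
      key, e$p, e$diagnostics$portmanteau$p.value,
      e$diagnostics$arch_lm$p.value, e$diagnostics$max_modulus,
      if (e$diagnostics$pass) "pass" else "FAIL"))
  }
  for (dir_name in names(report$tables)) {
    tf <- file.path(outdir, paste0("table_", dir_name, ".csv"))
    utils::write.csv(as.data.frame(report$tables[[dir_name]]), tf,
                     row.names = TRUE)
    put(tf)
  }
  df <- file.path(outdir, "diagnostics.txt")
  writeLines(diag_lines, df)
  put(df)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

.irf_long <- function(irf) {
  dn <- dimnames(irf$theta)
  grid <- expand.grid(response = dn[[1]], impulse = dn[[2]],
                      horizon = as.integer(dn[[3]]),
                      stringsAsFactors = FALSE)
  grid$point <- as.vector(irf$theta)
  grid$lower <- as.vector(irf$lower)
  grid$upper <- as.vector(irf$upper)
  grid$significant <- as.vector(irf$significant)
  grid
}

#' Serialize a fitted VAR (and optional diagnostics) to a plain list
#'
#' Suitable for `jsonlite::write_json()`; inverse-free, intended as an
#' audit artifact rather than a reload format.
#'
#' @param model A `"dyad_var"`.
#' @param diagnostics Optional `"var_diagnostics"`.
#' @return A named list.
#' @export
serialize_var_model <- function(model, diagnostics = NULL) {
  out <- list(
    variables = model$variables, p = model$p, m = model$m,
    group = model$group, encoding = model$encoding,
    n_dyads = model$n_dyads, nobs = model$nobs,
    intercepts = as.list(model$intercepts),
    B = lapply(model$B, function(Bk) apply(Bk, 1, as.list)),
    Sigma = apply(model$Sigma, 1, as.list),
    eigenvalue_moduli = Mod(model$eigenvalues),
    stable = is_stable(model)
  )
  if (!is.null(diagnostics)) {
    out$diagnostics <- list(
      portmanteau = list(
        statistic = unname(diagnostics$portmanteau$statistic),
        df = unname(diagnostics$portmanteau$parameter),
        p_value = diagnostics$portmanteau$p.value),
      arch_lm = list(
        statistic = unname(diagnostics$arch_lm$statistic),
        df = unname(diagnostics$arch_lm$parameter),
        p_value = diagnostics$arch_lm$p.value),
      alpha = diagnostics$alpha, pass = diagnostics$pass)
  }
  out
}
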