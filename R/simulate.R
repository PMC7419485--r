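# Synthetic dyad cohorts with known VAR(1) ground truth.

#' Configure a synthetic dyad cohort
#'
#' Builds the configuration for a cohort of mother-infant dyads whose
#' latent monthly behavior vector follows a stationary group-specific
#' VAR(1): `x(t) = c + A x(t-1) + eta`, `eta ~ N(0, Sigma)`. The defaults
#' emulate the design of a longitudinal play-observation study: 15 dyads
#' per group (30 total), two 5-minute coded play sessions per month over
#' months of age 3-12, aggregated to 10 monthly observations per dyad,
#' with the full 26-code vocabulary.
#'
#' @param n_dyads_per_group Dyads per group (default 15).
#' @param months Integer month-of-age grid (default `3:12`).
#' @param sessions_per_month Coded sessions per month (default 2).
#' @param session_length Session length in seconds (default 300).
#' @param variables Ordered subset of [behavior_codes()] (default all 26).
#' @param coupling_by_group Named list of `m x m` lag-1 coefficient
#'   matrices, one per group; entry `[i, j]` is the effect of variable `j`
#'   at month `t - 1` on variable `i` at month `t`. Each matrix must have
#'   spectral radius < 1. Default: [default_coupling()] for groups
#'   `boy` and `girl`.
#' @param intercepts Named list of length-`m` intercept vectors per group;
#'   default chosen so every latent series has stationary mean
#'   `latent_mean`.
#' @param innovation_cov Positive-definite `m x m` innovation covariance
#'   `Sigma` (shared across groups; default `0.1 * I`).
#' @param emission `"gaussian_latent"` (panel = the latent VAR draws; used
#'   for exact parameter-recovery checks) or `"poisson_counts"`
#'   (occurrence counts drawn Poisson with a log link on the latent,
#'   durations as sums of exponential event lengths; realistic
#'   non-negative data, approximate recovery).
#' @param latent_mean Stationary mean of each latent series (default
#'   `log(3)`, i.e. about 3 expected events per month under the count
#'   emission's log link).
#' @param mean_event_duration Mean seconds per event used by the count
#'   emission when rendering durations (default 2).
#' @param burn_in Latent burn-in steps discarded before the recorded
#'   window so series start at stationarity (default 50).
#' @param seed Default RNG seed used by [generate_cohort()].
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(n_dyads_per_group = 15,
                             months = 3:12,
                             sessions_per_month = 2,
                             session_length = 300,
                             variables = behavior_codes(),
                             coupling_by_group = NULL,
                             intercepts = NULL,
                             innovation_cov = NULL,
                             emission = c("poisson_counts",
                                          "gaussian_latent"),
                             latent_mean = log(3),
                             mean_event_duration = 2,
                             burn_in = 50,
                             seed = 1L) {
  emission <- match.arg(emission)
  m <- length(variables)
  if (is.null(coupling_by_group)) {
    coupling_by_group <- default_coupling(variables)
  }
  if (is.null(names(coupling_by_group)) ||
      any(names(coupling_by_group) == "")) {
    stop("'coupling_by_group' must be a named list (one matrix per group)",
         call. = FALSE)
  }
  coupling_by_group <- lapply(coupling_by_group, function(A) {
    A <- as.matrix(A)
    if (!identical(dim(A), c(m, m))) {
      stop("configuration error: each coupling matrix must be ", m, " x ",
           m, call. = FALSE)
    }
    rad <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (rad >= 1) {
      stop("configuration error: coupling matrix has spectral radius ",
           format(rad, digits = 4), " >= 1 (non-stationary VAR)",
           call. = FALSE)
    }
    dimnames(A) <- list(variables, variables)
    A
  })
  if (is.null(innovation_cov)) {
    innovation_cov <- diag(0.1, m)
  }
  innovation_cov <- as.matrix(innovation_cov)
  if (!identical(dim(innovation_cov), c(m, m)) ||
      max(abs(innovation_cov - t(innovation_cov))) > 1e-10) {
    stop("configuration error: innovation_cov must be a symmetric ", m,
         " x ", m, " matrix", call. = FALSE)
  }
  ok <- tryCatch({ chol(innovation_cov); TRUE },
                 error = function(e) FALSE)
  if (!ok) {
    stop("configuration error: innovation_cov is not positive-definite",
         call. = FALSE)
  }
  dimnames(innovation_cov) <- list(variables, variables)
  if (is.null(intercepts)) {
    intercepts <- lapply(coupling_by_group, function(A) {
      drop((diag(m) - A) %*% rep(latent_mean, m))
    })
  }
  intercepts <- lapply(intercepts, function(cc) {
    if (length(cc) != m) {
      stop("configuration error: each intercept vector must have length ",
           m, call. = FALSE)
    }
    stats::setNames(as.numeric(cc), variables)
  })
  if (!identical(sort(names(intercepts)), sort(names(coupling_by_group)))) {
    stop("configuration error: intercepts and coupling_by_group must name ",
         "the same groups", call. = FALSE)
  }
  if (n_dyads_per_group < 1) {
    stop("configuration error: n_dyads_per_group must be >= 1",
         call. = FALSE)
  }
  structure(
    list(n_dyads_per_group = as.integer(n_dyads_per_group),
         months = as.integer(months),
         sessions_per_month = as.integer(sessions_per_month),
         session_length = session_length,
         variables = as.character(variables),
         groups = names(coupling_by_group),
         coupling_by_group = coupling_by_group,
         intercepts = intercepts,
         innovation_cov = innovation_cov,
         emission = emission,
         latent_mean = latent_mean,
         mean_event_duration = mean_event_duration,
         burn_in = as.integer(burn_in),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Default group-specific coupling matrices
#'
#' A stable lag-1 coefficient matrix per group: persistence 0.3 on the
#' diagonal, plus a small set of cross-behavior couplings that differ
#' between the two groups (e.g. a mother-responds-to-independent-standing
#' link that is positive for boys and negative for girls, and a
#' pointing/crawling feedback loop for boys only). Couplings involving
#' codes absent from `variables` are silently skipped, so reduced variable
#' sets fall back to purely diagonal dynamics.
#'
#' @param variables Variable list the matrices should cover.
#' @param groups Group labels (default `c("boy", "girl")`).
#' @return Named list of `m x m` matrices.
#' @export
default_coupling <- function(variables = behavior_codes(),
                             groups = c("boy", "girl")) {
  m <- length(variables)
  base <- diag(0.3, m)
  dimnames(base) <- list(variables, variables)
  put <- function(A, resp, imp, w) {
    if (resp %in% variables && imp %in% variables) A[resp, imp] <- w
    A
  }
  A_boy <- base
  A_boy <- put(A_boy, "Rocks/Jiggles Infant", "Stand Independently", 0.30)
  A_boy <- put(A_boy, "Affectionate Touch", "Stand Independently", 0.25)
  A_boy <- put(A_boy, "Crawl", "Points to Object", 0.25)
  A_boy <- put(A_boy, "Points to Object", "Crawl", 0.25)
  A_girl <- base
  A_girl <- put(A_girl, "Rocks/Jiggles Infant", "Stand Independently", -0.30)
  A_girl <- put(A_girl, "Offers Object", "Stand Independently", -0.25)
  A_girl <- put(A_girl, "Holds Object", "Crawl", 0.25)
  out <- list(A_boy, A_girl)[seq_along(groups)]
  names(out) <- groups
  out
}

#' Generate a synthetic dyad cohort
#'
#' Draws each dyad's latent monthly series from its group's VAR(1) (after
#' a burn-in so the recorded window starts at stationarity) and renders
#' the configured emission. Dyads are independent given their group's
#' parameters. The same seed always yields an identical cohort.
#'
#' @param config A [generator_config()].
#' @param seed RNG seed; default `config$seed`.
#' @param events If `TRUE` (count emission only) also generate a
#'   session-level [as_event_log()] whose monthly aggregation reproduces
#'   the panels exactly.
#' @return An object of class `"dyad_cohort"`: a list with
#'   \describe{
#'     \item{panel}{the primary [monthly_panel()] (latent panel for
#'       `gaussian_latent`; occurrence-count panel for `poisson_counts`)}
#'     \item{panels}{named list of panels by encoding (count emission
#'       yields both `occurrence_count` and `duration_seconds`)}
#'     \item{events}{the session-level event log, or `NULL`}
#'     \item{latent}{the latent draws as a `gaussian_latent` panel}
#'     \item{config, seed}{provenance}
#'   }
#' @export
generate_cohort <- function(config, seed = config$seed, events = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  m <- length(config$variables)
  n_m <- length(config$months)
  n_g <- length(config$groups)
  n_d <- config$n_dyads_per_group * n_g
  S <- config$sessions_per_month

  P <- t(chol(config$innovation_cov))
  latent <- array(NA_real_, dim = c(n_d, n_m, m))
  dyad_ids <- character(n_d)
  dyad_groups <- character(n_d)
  k <- 0L
  for (g in config$groups) {
    A <- config$coupling_by_group[[g]]
    cc <- config$intercepts[[g]]
    mu <- drop(solve(diag(m) - A, cc))
    for (d in seq_len(config$n_dyads_per_group)) {
      k <- k + 1L
      dyad_ids[k] <- sprintf("%s%02d", g, d)
      dyad_groups[k] <- g
      x <- mu
      for (t in seq_len(config$burn_in)) {
        x <- cc + drop(A %*% x) + drop(P %*% stats::rnorm(m))
      }
      for (t in seq_len(n_m)) {
        x <- cc + drop(A %*% x) + drop(P %*% stats::rnorm(m))
        latent[k, t, ] <- x
      }
    }
  }
  dyads <- data.frame(dyad_id = dyad_ids, group = dyad_groups,
                      stringsAsFactors = FALSE)
  latent_panel <- monthly_panel(latent, dyads = dyads,
                                months = config$months,
                                variables = config$variables,
                                encoding = "gaussian_latent")

  if (config$emission == "gaussian_latent") {
    if (events) {
      stop("session-level event logs require the poisson_counts emission",
           call. = FALSE)
    }
    return(structure(list(panel = latent_panel,
                          panels = list(gaussian_latent = latent_panel),
                          events = NULL, latent = latent_panel,
                          config = config, seed = seed),
                     class = "dyad_cohort"))
  }

  # count emission: monthly rate via log link, split over sessions
  counts <- array(0, dim = dim(latent))
  durations <- array(0, dim = dim(latent))
  ev <- vector("list", n_d * n_m)
  r <- 0L
  for (k in seq_len(n_d)) {
    for (t in seq_len(n_m)) {
      lambda <- exp(latent[k, t, ]) / S
      n_sv <- matrix(stats::rpois(S * m, rep(lambda, each = S)),
                     nrow = S)                    # sessions x variables
      d_sv <- matrix(0, nrow = S, ncol = m)
      pos <- which(n_sv > 0)
      if (length(pos) > 0L) {
        d_sv[pos] <- stats::rgamma(length(pos), shape = n_sv[pos],
                                   rate = 1 / config$mean_event_duration)
      }
      counts[k, t, ] <- colSums(n_sv)
      durations[k, t, ] <- colSums(d_sv)
      if (events) {
        keep <- which(n_sv > 0, arr.ind = TRUE)
        if (nrow(keep) > 0L) {
          r <- r + 1L
          ev[[r]] <- data.frame(
            dyad_id = dyad_ids[k], group = dyad_groups[k],
            month = config$months[t], session = keep[, 1],
            code = config$variables[keep[, 2]],
            duration_s = d_sv[keep], occurrences = n_sv[keep],
            stringsAsFactors = FALSE)
        } else {
          # keep the month visible in the log even if no behavior occurred,
          # so aggregation sees no gaps: record a zero row for session 1
          r <- r + 1L
          ev[[r]] <- data.frame(
            dyad_id = dyad_ids[k], group = dyad_groups[k],
            month = config$months[t], session = 1L,
            code = config$variables[1], duration_s = 0, occurrences = 0,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  panels <- list(
    occurrence_count = monthly_panel(counts, dyads = dyads,
                                     months = config$months,
                                     variables = config$variables,
                                     encoding = "occurrence_count"),
    duration_seconds = monthly_panel(durations, dyads = dyads,
                                     months = config$months,
                                     variables = config$variables,
                                     encoding = "duration_seconds")
  )
  log <- NULL
  if (events) {
    log <- as_event_log(do.call(rbind, ev[seq_len(r)]),
                        vocabulary = config$variables)
  }
  structure(list(panel = panels$occurrence_count, panels = panels,
                 events = log, latent = latent_panel,
                 config = config, seed = seed),
            class = "dyad_cohort")
}

#' @export
print.dyad_cohort <- function(x, ...) {
  cat("Synthetic dyad cohort (seed ", x$seed, ", emission ",
      x$config$emission, ")\n", sep = "")
  print(x$panel)
  invisible(x)
}

#' Closed-form orthogonalized impulse responses of a generator config
#'
#' For each group, returns the analytic orthogonalized IRF of the planted
#' VAR(1): `Theta_0 = chol(Sigma)` (lower triangular) and
#' `Theta_h = A %*% Theta_{h-1}` for `h = 1, ..., horizon`. These are the
#' curves the estimation pipeline should recover on large cohorts, and
#' they decay geometrically to zero because every planted `A` is stable.
#'
#' @param config A [generator_config()].
#' @param horizon Non-negative integer number of steps beyond impact.
#' @return Object of class `"ground_truth_irf"`: named list per group of
#'   arrays `m x m x (horizon + 1)` (response x impulse x horizon).
#' @export
ground_truth_irf <- function(config, horizon = 10) {
  stopifnot(inherits(config, "generator_config"))
  if (length(horizon) != 1L || horizon < 0) {
    stop("'horizon' must be a non-negative integer", call. = FALSE)
  }
  horizon <- as.integer(horizon)
  m <- length(config$variables)
  P <- t(chol(config$innovation_cov))
  out <- lapply(config$coupling_by_group, function(A) {
    theta <- array(NA_real_, dim = c(m, m, horizon + 1L),
                   dimnames = list(config$variables, config$variables,
                                   0:horizon))
    theta[, , 1] <- P
    if (horizon >= 1L) {
      for (h in seq_len(horizon)) {
        theta[, , h + 1] <- A %*% theta[, , h]
      }
    }
    theta
  })
  structure(out, class = "ground_truth_irf",
            horizon = horizon, variables = config$variables)
}
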