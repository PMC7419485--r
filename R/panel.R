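# Monthly multivariate panels: construction, aggregation, serialization.

#' Construct a monthly panel
#'
#' A monthly panel holds, for each dyad, a cotemporaneous multivariate time
#' series on an equally spaced integer month grid: one value per
#' (dyad, month, behavior code). Every dyad shares the same month grid and
#' the same ordered variable list; the variable order is stable and defines
#' the default Cholesky ordering used downstream.
#'
#' @param values Numeric array `n_dyads x n_months x n_variables`.
#' @param dyads Data frame with columns `dyad_id` and `group` (one row per
#'   dyad, in the order of the first array dimension).
#' @param months Strictly increasing, equally spaced integer vector.
#' @param variables Ordered character vector of code names.
#' @param encoding One of `"duration_seconds"`, `"occurrence_count"` or
#'   `"gaussian_latent"` (the last for synthetic latent-scale panels, which
#'   may contain negative values).
#' @return An object of class `"monthly_panel"`.
#' @export
monthly_panel <- function(values, dyads, months, variables,
                          encoding = c("duration_seconds",
                                       "occurrence_count",
                                       "gaussian_latent")) {
  encoding <- match.arg(encoding)
  values <- unname(values)
  if (length(dim(values)) != 3L) {
    stop("'values' must be a 3-d array (dyad x month x variable)",
         call. = FALSE)
  }
  months <- as.integer(months)
  if (length(months) < 2L) {
    stop("a monthly panel needs at least two months", call. = FALSE)
  }
  steps <- diff(months)
  if (any(steps <= 0L) || length(unique(steps)) != 1L) {
    stop("months must be strictly increasing and equally spaced",
         call. = FALSE)
  }
  if (!is.data.frame(dyads) || !all(c("dyad_id", "group") %in% names(dyads))) {
    stop("'dyads' must be a data frame with columns dyad_id and group",
         call. = FALSE)
  }
  dyads <- data.frame(dyad_id = as.character(dyads$dyad_id),
                      group = tolower(as.character(dyads$group)),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(dyads$dyad_id)) {
    stop("duplicate dyad_id in panel", call. = FALSE)
  }
  if (!identical(dim(values),
                 c(nrow(dyads), length(months), length(variables)))) {
    stop("'values' dimensions do not match dyads/months/variables",
         call. = FALSE)
  }
  if (anyNA(values)) {
    stop("panel has missing cells; every (dyad, month) must be present",
         call. = FALSE)
  }
  if (encoding != "gaussian_latent" && any(values < 0)) {
    stop("panel values must be non-negative for encoding ", encoding,
         call. = FALSE)
  }
  dimnames(values) <- list(dyads$dyad_id, months, variables)
  structure(
    list(values = values, dyads = dyads, months = months,
         variables = as.character(variables), encoding = encoding),
    class = "monthly_panel"
  )
}

#' @export
print.monthly_panel <- function(x, ...) {
  cat("Monthly panel:", nrow(x$dyads), "dyads x", length(x$months),
      "months x", length(x$variables), "variables\n")
  cat("  encoding:", x$encoding, "\n")
  cat("  months:", x$months[1], "-", x$months[length(x$months)], "\n")
  grp <- table(x$dyads$group)
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate a behavioral event log into a monthly panel
#'
#' Pools session-level events by month: each (dyad, month, code) cell is
#' the sum (default) or mean across that month's sessions of the chosen
#' encoding. Codes with no events in a month contribute 0. Pooling sessions
#' by month yields the equally spaced, cotemporaneous series that VAR
#' modeling requires; a dyad missing an entire month therefore raises an
#' error rather than being imputed.
#'
#' @param events An `event_log` (see [read_event_log()]).
#' @param encoding `"duration_seconds"` (sums `duration_s`) or
#'   `"occurrence_count"` (sums `occurrences`).
#' @param stat `"sum"` (default) or `"mean"` across a month's sessions.
#'   With a fixed number of fixed-length sessions per month the two differ
#'   only by a constant factor.
#' @param months Integer grid of months the panel must cover; default the
#'   full range observed in `events`.
#' @param variables Ordered variable list for the panel; default the
#'   standard vocabulary restricted to codes present in `events`.
#' @return A [monthly_panel()].
#' @export
aggregate_monthly <- function(events,
                              encoding = c("duration_seconds",
                                           "occurrence_count"),
                              stat = c("sum", "mean"),
                              months = NULL, variables = NULL) {
  encoding <- match.arg(encoding)
  stat <- match.arg(stat)
  events <- as.data.frame(events)
  if (is.null(months)) {
    months <- seq(min(events$month), max(events$month))
  }
  months <- as.integer(months)
  if (is.null(variables)) {
    vocab <- behavior_codes()
    present <- unique(events$code)
    variables <- if (all(present %in% vocab)) {
      vocab[vocab %in% present]
    } else {
      sort(present)
    }
  }
  stray <- setdiff(unique(events$code), variables)
  if (length(stray) > 0L) {
    stop("events contain code(s) not in the requested variable list: ",
         paste(sQuote(stray), collapse = ", "), call. = FALSE)
  }

  dyad_ids <- unique(events$dyad_id)
  groups <- events$group[match(dyad_ids, events$dyad_id)]

  # equal spacing is a modeling requirement: a dyad with no coded session
  # in some month cannot enter the panel
  have <- unique(events[, c("dyad_id", "month")])
  for (d in dyad_ids) {
    miss <- setdiff(months, have$month[have$dyad_id == d])
    if (length(miss) > 0L) {
      stop("gap error: dyad ", sQuote(d), " has no events in month(s) ",
           paste(miss, collapse = ", "),
           "; equal spacing cannot be guaranteed", call. = FALSE)
    }
  }

  field <- if (encoding == "duration_seconds") "duration_s" else "occurrences"
  di <- match(events$dyad_id, dyad_ids)
  mi <- match(events$month, months)
  vi <- match(events$code, variables)
  vals <- array(0, dim = c(length(dyad_ids), length(months),
                           length(variables)))
  idx <- cbind(di, mi, vi)
  # sum over sessions (and over repeated rows within a session)
  for (r in seq_len(nrow(events))) {
    vals[idx[r, , drop = FALSE]] <-
      vals[idx[r, , drop = FALSE]] + events[[field]][r]
  }
  if (stat == "mean") {
    ses <- unique(events[, c("dyad_id", "month", "session")])
    n_ses <- table(factor(ses$dyad_id, levels = dyad_ids),
                   factor(ses$month, levels = months))
    vals <- vals / array(as.numeric(n_ses), dim = dim(vals))
  }
  monthly_panel(vals,
                dyads = data.frame(dyad_id = dyad_ids, group = groups,
                                   stringsAsFactors = FALSE),
                months = months, variables = variables, encoding = encoding)
}

#' Extract one dyad's series as a months-by-variables matrix
#'
#' @param panel A `monthly_panel`.
#' @param dyad A dyad id or index.
#' @return Numeric matrix with months as rows and variables as columns.
#' @export
panel_matrix <- function(panel, dyad) {
  m <- panel$values[dyad, , , drop = FALSE]
  dim(m) <- dim(panel$values)[2:3]
  dimnames(m) <- list(panel$months, panel$variables)
  m
}

#' Split a panel by group label
#'
#' @param panel A `monthly_panel`.
#' @return Named list of single-group `monthly_panel` objects.
#' @export
split_panel_by_group <- function(panel) {
  out <- lapply(unique(panel$dyads$group), function(g) {
    keep <- which(panel$dyads$group == g)
    monthly_panel(panel$values[keep, , , drop = FALSE],
                  dyads = panel$dyads[keep, , drop = FALSE],
                  months = panel$months, variables = panel$variables,
                  encoding = panel$encoding)
  })
  names(out) <- unique(panel$dyads$group)
  out
}

#' Restrict a panel to a subset of variables
#'
#' @param panel A `monthly_panel`.
#' @param variables Character vector (ordered) of variables to keep.
#' @return A `monthly_panel` with the requested variable order.
#' @export
panel_select <- function(panel, variables) {
  missing_v <- setdiff(variables, panel$variables)
  if (length(missing_v) > 0L) {
    stop("panel does not contain variable(s): ",
         paste(sQuote(missing_v), collapse = ", "), call. = FALSE)
  }
  vi <- match(variables, panel$variables)
  monthly_panel(panel$values[, , vi, drop = FALSE], dyads = panel$dyads,
                months = panel$months, variables = variables,
                encoding = panel$encoding)
}

#' Coerce a matrix to a single-dyad monthly panel
#'
#' Convenience for feeding a plain multivariate time series (rows = time,
#' columns = variables) to [fit_var()].
#'
#' @param x Numeric matrix, rows in time order.
#' @param encoding Panel encoding label; default `"gaussian_latent"` so
#'   arbitrary real values are accepted.
#' @return A `monthly_panel` with one dyad on months `1:nrow(x)`.
#' @export
as_monthly_panel <- function(x, encoding = "gaussian_latent") {
  x <- as.matrix(x)
  vars <- colnames(x)
  if (is.null(vars)) vars <- paste0("x", seq_len(ncol(x)))
  vals <- array(x, dim = c(1L, nrow(x), ncol(x)))
  monthly_panel(vals,
                dyads = data.frame(dyad_id = "series1", group = "all",
                                   stringsAsFactors = FALSE),
                months = seq_len(nrow(x)), variables = vars,
                encoding = encoding)
}

#' Write a monthly panel as tidy CSV
#'
#' One row per (dyad, month, code):
#' `dyad_id,group,month,code,value,encoding`. Values are written at full
#' precision so that [read_panel()] recovers the panel bit-exactly.
#'
#' @param panel A `monthly_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  n_d <- nrow(panel$dyads); n_m <- length(panel$months)
  n_v <- length(panel$variables)
  out <- data.frame(
    dyad_id = rep(panel$dyads$dyad_id, times = n_m * n_v),
    group = rep(panel$dyads$group, times = n_m * n_v),
    month = rep(rep(panel$months, each = n_d), times = n_v),
    code = rep(panel$variables, each = n_d * n_m),
    value = vapply(as.vector(panel$values), .num_chr, character(1)),
    encoding = panel$encoding,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a monthly panel written by [write_panel()]
#'
#' @param path CSV path.
#' @return A `monthly_panel`. Dyad, month and variable order follow first
#'   appearance in the file, so a write/read round trip is an identity.
#' @export
read_panel <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("dyad_id", "group", "month", "code", "value", "encoding")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stop("panel file schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$dyad_id <- as.character(x$dyad_id)
  encoding <- unique(x$encoding)
  if (length(encoding) != 1L) {
    stop("panel file mixes encodings", call. = FALSE)
  }
  dyad_ids <- unique(x$dyad_id)
  months <- sort(unique(as.integer(x$month)))
  variables <- unique(x$code)
  vals <- array(NA_real_, dim = c(length(dyad_ids), length(months),
                                  length(variables)))
  vals[cbind(match(x$dyad_id, dyad_ids), match(x$month, months),
             match(x$code, variables))] <- as.numeric(x$value)
  groups <- x$group[match(dyad_ids, x$dyad_id)]
  monthly_panel(vals,
                dyads = data.frame(dyad_id = dyad_ids, group = groups,
                                   stringsAsFactors = FALSE),
                months = months, variables = variables, encoding = encoding)
}
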