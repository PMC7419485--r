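# Reading and validating coded behavioral event logs.

.event_cols <- c("dyad_id", "group", "month", "session", "code",
                 "duration_s", "occurrences")

#' Read a coded behavioral event log
#'
#' Reads a delimited text file of session-level behavioral coding events.
#' Each row records, for one dyad, month-of-age, and session, the total
#' duration (seconds) and number of occurrences of one behavior code.
#' The delimiter is chosen from the file extension: `.tsv`/`.tab` are read
#' as tab-separated, anything else as comma-separated.
#'
#' Required columns: `dyad_id`, `group`, `month`, `session`, `code`,
#' `duration_s`, `occurrences`. Group labels are canonicalized to lower
#' case at read time. Codes are validated against `vocabulary`; durations
#' and counts must be non-negative; each dyad must carry a single group
#' label throughout.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param vocabulary Character vector of permitted code names
#'   (default [behavior_codes()]).
#' @param months Optional integer vector; if given, every event month must
#'   fall inside this observation window.
#' @return A `data.frame` of validated events with class `"event_log"`.
#' @seealso [aggregate_monthly()] to build a monthly panel.
#' @export
read_event_log <- function(path, vocabulary = behavior_codes(),
                           months = NULL) {
  if (!file.exists(path)) {
    stop("event log file not found: ", path, call. = FALSE)
  }
  tab_sep <- grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)
  events <- utils::read.table(path, header = TRUE,
                              sep = if (tab_sep) "\t" else ",",
                              quote = "\"", comment.char = "",
                              stringsAsFactors = FALSE,
                              check.names = FALSE, fileEncoding = "UTF-8")
  as_event_log(events, vocabulary = vocabulary, months = months)
}

#' Validate a data frame of behavioral coding events
#'
#' Applies the same validation as [read_event_log()] to an in-memory
#' data frame: schema check, vocabulary membership, non-negativity,
#' one group per dyad, and (optionally) the observation window.
#'
#' @param events A data frame with the event-log columns.
#' @inheritParams read_event_log
#' @return The validated events with class `"event_log"`.
#' @export
as_event_log <- function(events, vocabulary = behavior_codes(),
                         months = NULL) {
  missing_cols <- setdiff(.event_cols, names(events))
  if (length(missing_cols) > 0L) {
    stop("event log schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  events <- events[, .event_cols]
  events$dyad_id <- as.character(events$dyad_id)
  events$group <- tolower(trimws(as.character(events$group)))
  events$code <- as.character(events$code)
  for (col in c("month", "session", "duration_s", "occurrences")) {
    events[[col]] <- as.numeric(events[[col]])
    if (anyNA(events[[col]])) {
      stop("event log validation error: non-numeric or missing values in ",
           "column '", col, "' at row(s) ",
           .row_list(which(is.na(events[[col]]))), call. = FALSE)
    }
  }

  bad_code <- which(!(events$code %in% vocabulary))
  if (length(bad_code) > 0L) {
    stop("event log validation error: unknown behavior code(s) ",
         paste(sQuote(unique(events$code[bad_code])), collapse = ", "),
         " at row(s) ", .row_list(bad_code), call. = FALSE)
  }
  bad_dur <- which(events$duration_s < 0)
  if (length(bad_dur) > 0L) {
    stop("event log validation error: negative duration at row(s) ",
         .row_list(bad_dur), call. = FALSE)
  }
  bad_occ <- which(events$occurrences < 0)
  if (length(bad_occ) > 0L) {
    stop("event log validation error: negative occurrence count at row(s) ",
         .row_list(bad_occ), call. = FALSE)
  }
  if (!is.null(months)) {
    bad_month <- which(!(events$month %in% months))
    if (length(bad_month) > 0L) {
      stop("event log validation error: month outside the observation ",
           "window at row(s) ", .row_list(bad_month), call. = FALSE)
    }
  }
  n_groups <- tapply(events$group, events$dyad_id,
                     function(g) length(unique(g)))
  mixed <- names(n_groups)[n_groups > 1L]
  if (length(mixed) > 0L) {
    stop("event log consistency error: dyad(s) ",
         paste(sQuote(mixed), collapse = ", "),
         " carry more than one group label", call. = FALSE)
  }
  class(events) <- c("event_log", "data.frame")
  events
}

#' Write an event log to delimited text
#'
#' @param events An `event_log` data frame.
#' @param path Output path; `.tsv`/`.tab` write tab-separated, otherwise CSV.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  tab_sep <- grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)
  out <- as.data.frame(events)[, .event_cols]
  # full-precision durations so a written log re-reads bit-exactly
  out$duration_s <- vapply(out$duration_s, .num_chr, character(1))
  utils::write.table(out, path, sep = if (tab_sep) "\t" else ",",
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

.row_list <- function(rows, max_show = 5L) {
  shown <- utils::head(rows, max_show)
  txt <- paste(shown, collapse = ", ")
  if (length(rows) > max_show) {
    txt <- paste0(txt, ", ... (", length(rows), " rows total)")
  }
  txt
}

# decimal representation that survives a write/read round trip bit-exactly
.num_chr <- function(x) {
  if (is.finite(x) && x == round(x) && abs(x) < 2^53) {
    sprintf("%.0f", x)
  } else {
    sprintf("%.17g", x)
  }
}
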