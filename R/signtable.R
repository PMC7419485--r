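# Sign tables: collapsing IRF significance into presence/direction cells.

#' Build a sign table from impulse-response results
#'
#' Collapses bootstrap-banded impulse responses into a matrix of cells
#' with `""` (no significant later response), `"+"` or `"-"`: a cell is
#' non-blank only if the band excludes zero at some horizon inside the
#' window (default horizons 1-3, i.e. responses one to three months
#' after the shock), and its sign is the sign of the point curve at the
#' first significant horizon. If the curve is significant with both signs
#' at different horizons inside the window, the first sign wins and the
#' pair is recorded in the `mixed` attribute.
#'
#' @param irfs An `"irf_set"` with bands (from [bootstrap_irf_ci()]) or a
#'   `"conservative_irf"` (from [conservative_irf_sweep()]).
#' @param impulses Impulse variables to use as columns (default: all).
#' @param responses Response variables to use as rows (default: all).
#' @param window Integer horizons examined for significance (default
#'   `1:3`); must lie within the computed horizon.
#' @return Object of class `"sign_table"`: a character matrix
#'   (responses x impulses) with attributes `window`, `group`,
#'   `encoding` and `mixed` (data frame of mixed-sign pairs).
#' @export
build_sign_table <- function(irfs, impulses = NULL, responses = NULL,
                             window = 1:3) {
  if (!inherits(irfs, c("irf_set", "conservative_irf"))) {
    stop("'irfs' must come from bootstrap_irf_ci() or ",
         "conservative_irf_sweep()", call. = FALSE)
  }
  if (is.null(irfs$significant)) {
    stop("'irfs' has no confidence bands; run the bootstrap first",
         call. = FALSE)
  }
  window <- as.integer(window)
  if (any(window < 1L) || any(window > irfs$horizon)) {
    stop("'window' must lie within 1..horizon (", irfs$horizon, ")",
         call. = FALSE)
  }
  vars_resp <- rownames(irfs$theta)
  vars_imp <- colnames(irfs$theta)
  if (is.null(impulses)) impulses <- vars_imp
  if (is.null(responses)) responses <- vars_resp
  bad <- c(setdiff(impulses, vars_imp), setdiff(responses, vars_resp))
  if (length(bad) > 0L) {
    stop("variable(s) not covered by the IRF set: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  tab <- matrix("", nrow = length(responses), ncol = length(impulses),
                dimnames = list(responses, impulses))
  mixed <- list()
  for (rv in responses) {
    for (iv in impulses) {
      if (rv == iv) next   # self-pairs are not tabulated
      sig <- irfs$significant[rv, iv, window + 1L]
      if (!any(sig)) next
      hs <- window[sig]
      signs <- sign(irfs$theta[rv, iv, hs + 1L])
      tab[rv, iv] <- if (signs[1] >= 0) "+" else "-"
      if (length(unique(signs)) > 1L) {
        mixed[[length(mixed) + 1L]] <-
          data.frame(response = rv, impulse = iv,
                     horizons = paste(hs, collapse = ","),
                     stringsAsFactors = FALSE)
        warning("mixed-sign significant response for ", sQuote(rv),
                " to impulse ", sQuote(iv),
                "; reporting the sign at the first significant horizon",
                call. = FALSE)
      }
    }
  }
  structure(tab, class = c("sign_table", "matrix"),
            window = window,
            group = irfs$model$group %||% NA_character_,
            encoding = irfs$model$encoding %||% NA_character_,
            mixed = if (length(mixed)) do.call(rbind, mixed) else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sign_table <- function(x, ...) {
  cat("Sign table (window: horizons ",
      paste(range(attr(x, "window")), collapse = "-"), ")",
      if (!is.na(attr(x, "group"))) paste0("; group: ", attr(x, "group")),
      if (!is.na(attr(x, "encoding")))
        paste0("; encoding: ", attr(x, "encoding")),
      "\n", sep = "")
  y <- unclass(x)
  attributes(y)[setdiff(names(attributes(y)),
                        c("dim", "dimnames"))] <- NULL
  y[y == ""] <- "."
  print(y, quote = FALSE)
  invisible(x)
}

#' Render group-by-encoding sign tables in the bracket dialect
#'
#' Combines per-group, per-encoding sign tables into a single character
#' matrix whose cells read like `"+B[-G]"`: duration-encoding effects
#' appear outside the brackets and occurrence-encoding effects inside,
#' each as the sign followed by the group letter.
#'
#' @param duration Named list of `"sign_table"`s for the duration
#'   encoding, one per group (may be `NULL` if that encoding was not run).
#' @param occurrence Named list for the occurrence encoding (or `NULL`).
#' @param group_letters Named character vector mapping group labels to
#'   display letters; default `c(boy = "B", girl = "G")`.
#' @return Character matrix (responses x impulses).
#' @export
render_sign_matrix <- function(duration = NULL, occurrence = NULL,
                               group_letters = c(boy = "B", girl = "G")) {
  all_tabs <- c(duration, occurrence)
  if (length(all_tabs) == 0L) stop("no sign tables given", call. = FALSE)
  ref <- all_tabs[[1]]
  rs <- rownames(ref); is <- colnames(ref)
  collect <- function(tabs) {
    if (is.null(tabs)) {
      return(matrix("", length(rs), length(is), dimnames = list(rs, is)))
    }
    out <- matrix("", length(rs), length(is), dimnames = list(rs, is))
    for (g in names(tabs)) {
      letter <- if (g %in% names(group_letters)) {
        group_letters[[g]]
      } else {
        toupper(substr(g, 1, 1))
      }
      tg <- tabs[[g]]
      hit <- tg != ""
      out[hit] <- paste0(out[hit], tg[hit], letter)
    }
    out
  }
  dur <- collect(duration)
  occ <- collect(occurrence)
  cells <- matrix("", length(rs), length(is), dimnames = list(rs, is))
  nz <- occ != ""
  cells[] <- dur
  cells[nz] <- paste0(dur[nz], "[", occ[nz], "]")
  cells
}
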