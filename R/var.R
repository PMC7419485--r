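# Pooled VAR estimation on monthly panels.

# Build the pooled regression design: lagged predictors constructed WITHIN
# each dyad only (no lag pairs spanning a dyad boundary), then stacked.
# series_list: per-dyad T x m matrices on a shared grid.
.var_design <- function(series_list, p) {
  m <- ncol(series_list[[1]])
  ys <- vector("list", length(series_list))
  xs <- vector("list", length(series_list))
  for (i in seq_along(series_list)) {
    V <- series_list[[i]]
    T_i <- nrow(V)
    if (T_i <= p) {
      stop("sample-size error: a dyad series of length ", T_i,
           " cannot support lag order ", p, call. = FALSE)
    }
    ys[[i]] <- V[(p + 1):T_i, , drop = FALSE]
    lags <- lapply(seq_len(p), function(k) {
      V[(p + 1 - k):(T_i - k), , drop = FALSE]
    })
    xs[[i]] <- do.call(cbind, lags)
  }
  Y <- do.call(rbind, ys)
  X <- cbind(1, do.call(rbind, xs))
  blocks <- rep(seq_along(series_list),
                vapply(series_list, function(V) nrow(V) - p, integer(1)))
  list(Y = Y, X = X, blocks = blocks)
}

# Core least-squares fit shared by fit_var() and the bootstrap.
.var_ls <- function(series_list, p, variables) {
  m <- length(variables)
  d <- .var_design(series_list, p)
  n <- nrow(d$Y)
  if (n <= m * p + 1L) {
    stop("sample-size error: ", n, " usable rows cannot identify ",
         m * p + 1L, " parameters per equation", call. = FALSE)
  }
  qrx <- qr(d$X)
  if (qrx$rank < ncol(d$X)) {
    lag_names <- c("(intercept)",
                   paste0(rep(variables, times = p), ".l",
                          rep(seq_len(p), each = m)))
    dropped <- lag_names[qrx$pivot[(qrx$rank + 1):ncol(d$X)]]
    stop("estimation error: rank-deficient design; offending column(s): ",
         paste(sQuote(dropped), collapse = ", "),
         " (constant or collinear series)", call. = FALSE)
  }
  coefs <- qr.coef(qrx, d$Y)             # (1 + m*p) x m
  resid <- d$Y - d$X %*% coefs
  Sigma <- crossprod(resid) / max(1, n - m * p - 1L)
  B <- lapply(seq_len(p), function(k) {
    Bk <- t(coefs[1L + ((k - 1L) * m + 1L):(k * m), , drop = FALSE])
    dimnames(Bk) <- list(variables, variables)
    Bk
  })
  dimnames(Sigma) <- list(variables, variables)
  list(intercepts = stats::setNames(coefs[1, ], variables),
       B = B, residuals = resid, Sigma = Sigma, blocks = d$blocks, n = n)
}

# Companion-form coefficient matrix of a VAR(p).
.companion <- function(B) {
  p <- length(B)
  m <- nrow(B[[1]])
  C <- matrix(0, m * p, m * p)
  for (k in seq_len(p)) {
    C[1:m, ((k - 1) * m + 1):(k * m)] <- B[[k]]
  }
  if (p > 1) {
    C[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  }
  C
}

#' Fit a pooled VAR(p) to a monthly panel
#'
#' Estimates, by per-equation ordinary least squares, the vector
#' autoregression `x(t) = c + B_1 x(t-1) + ... + B_p x(t-p) + eps` on the
#' panel's dyads pooled into one design: lagged predictors are built
#' within each dyad (no pair of observations spans a dyad boundary) and
#' the stacked system shares a single intercept per equation. With `m`
#' variables the system carries `p * m^2` lagged coefficients plus `m`
#' intercepts. The residual covariance uses the degrees-of-freedom
#' adjusted denominator `rows - m*p - 1`.
#'
#' @param panel A [monthly_panel()] (or matrix, coerced via
#'   [as_monthly_panel()]).
#' @param p Lag order (default 1).
#' @param center If `TRUE`, subtract each variable's pooled mean before
#'   fitting. Default `FALSE` (raw monthly values).
#' @param drop_degenerate If `TRUE`, variables that are constant across
#'   the whole panel are dropped with a message instead of raising an
#'   error.
#' @return Object of class `"dyad_var"` with elements `variables`, `p`,
#'   `m`, `intercepts`, `B` (list of `p` coefficient matrices, entry
#'   `[i, j]` = effect of variable `j` at lag `k` on variable `i`),
#'   `residuals`, `Sigma`, `blocks` (dyad of each residual row),
#'   `eigenvalues` (companion-matrix eigenvalues), `nobs`, plus panel
#'   metadata (`group`, `encoding`, `months`).
#' @export
fit_var <- function(panel, p = 1L, center = FALSE,
                    drop_degenerate = FALSE) {
  if (is.matrix(panel) || is.data.frame(panel)) {
    panel <- as_monthly_panel(as.matrix(panel))
  }
  stopifnot(inherits(panel, "monthly_panel"))
  if (length(p) != 1L || p < 1L) {
    stop("'p' must be a positive integer", call. = FALSE)
  }
  p <- as.integer(p)

  variables <- panel$variables
  sds <- apply(panel$values, 3, stats::sd)
  if (any(sds == 0)) {
    bad <- variables[sds == 0]
    if (drop_degenerate) {
      message("dropping degenerate (constant) variable(s): ",
              paste(sQuote(bad), collapse = ", "))
      panel <- panel_select(panel, setdiff(variables, bad))
      variables <- panel$variables
    } else {
      stop("estimation error: variable(s) ",
           paste(sQuote(bad), collapse = ", "),
           " are constant across the panel; drop them or rerun with ",
           "drop_degenerate = TRUE", call. = FALSE)
    }
  }
  m <- length(variables)
  vals <- panel$values
  if (center) {
    mu <- apply(vals, 3, mean)
    vals <- sweep(vals, 3, mu, "-")
  }
  series_list <- lapply(seq_len(nrow(panel$dyads)), function(i) {
    M <- vals[i, , , drop = FALSE]
    dim(M) <- dim(vals)[2:3]
    M
  })
  fit <- .var_ls(series_list, p, variables)
  ev <- eigen(.companion(fit$B), only.values = TRUE)$values
  group <- unique(panel$dyads$group)
  structure(
    list(variables = variables, p = p, m = m,
         intercepts = fit$intercepts, B = fit$B,
         residuals = fit$residuals, Sigma = fit$Sigma,
         blocks = panel$dyads$dyad_id[fit$blocks],
         eigenvalues = ev, nobs = fit$n,
         n_dyads = nrow(panel$dyads),
         group = if (length(group) == 1L) group else "mixed",
         encoding = panel$encoding, months = panel$months,
         center = center),
    class = "dyad_var"
  )
}

#' @export
print.dyad_var <- function(x, ...) {
  cat("Pooled VAR(", x$p, "): ", x$m, " variables, ", x$n_dyads,
      " dyad(s), ", x$nobs, " usable rows\n", sep = "")
  cat("  group: ", x$group, "; encoding: ", x$encoding, "\n", sep = "")
  cat("  lagged coefficients: ", x$p * x$m^2,
      " (+ ", x$m, " intercepts)\n", sep = "")
  cat("  max |companion eigenvalue|: ",
      format(max(Mod(x$eigenvalues)), digits = 4),
      if (is_stable(x)) " (stable)\n" else " (UNSTABLE)\n", sep = "")
  invisible(x)
}

#' Is a fitted VAR stationary/stable?
#'
#' A VAR is stable when all eigenvalues of its companion-form coefficient
#' matrix lie strictly inside the unit circle; only then do impulse
#' responses decay to zero.
#'
#' @param model A `"dyad_var"`.
#' @return Logical.
#' @export
is_stable <- function(model) {
  stopifnot(inherits(model, "dyad_var"))
  max(Mod(model$eigenvalues)) < 1
}

#' Simulate a fitted VAR forward
#'
#' Deterministic (noise-free) forward iteration of the fitted coefficient
#' structure from given initial conditions, optionally adding a shock
#' vector to the innovation of the first simulated step. Used as the
#' brute-force oracle for impulse-response curves and for empirical
#' stability checks.
#'
#' @param model A `"dyad_var"`.
#' @param init `p x m` matrix of initial values (earliest row first).
#' @param steps Number of steps to simulate.
#' @param shock Optional length-`m` innovation added at the first step.
#' @return `steps x m` matrix of simulated values.
#' @export
simulate_var <- function(model, init = NULL, steps = 10L, shock = NULL) {
  stopifnot(inherits(model, "dyad_var"))
  m <- model$m; p <- model$p
  if (is.null(init)) init <- matrix(0, p, m)
  init <- matrix(init, ncol = m)
  if (nrow(init) < p) {
    stop("'init' must supply at least p rows", call. = FALSE)
  }
  hist <- init[nrow(init) - (p:1) + 1L, , drop = FALSE]
  out <- matrix(NA_real_, steps, m)
  colnames(out) <- model$variables
  for (t in seq_len(steps)) {
    x <- model$intercepts
    for (k in seq_len(p)) {
      x <- x + drop(model$B[[k]] %*% hist[p - k + 1L, ])
    }
    if (t == 1L && !is.null(shock)) x <- x + shock
    out[t, ] <- x
    hist <- rbind(hist[-1, , drop = FALSE], x)
  }
  out
}
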