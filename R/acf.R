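# Autocorrelation weights and univariate autoregression.

#' Lagged autocorrelation weights of a series
#'
#' For a length-`N` series there are `N - 1` possible lags; the weight at
#' lag `j` is the sample correlation between the overlapping pairs
#' `x(t)` and `x(t - j)`. A full-length call therefore returns exactly
#' `N - 1` weights. At extreme lags where one of the lagged segments has
#' zero variance (e.g. the single pair at lag `N - 1`) the correlation is
#' undefined and the weight is `NA`.
#'
#' @param x Numeric series, length >= 2, finite, non-constant.
#' @param max_lag Largest lag to evaluate (default `length(x) - 1`, i.e.
#'   all of them).
#' @return Named numeric vector of weights for lags `1:max_lag`.
#' @examples
#' w <- acf_weights(rnorm(100))
#' length(w)  # 99
#' acf_weights(rep(c(1, -1), 10), max_lag = 1)  # exactly -1
#' @export
acf_weights <- function(x, max_lag = length(x) - 1L) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 2L) stop("series must have length >= 2", call. = FALSE)
  if (!all(is.finite(x))) stop("series must be finite", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate series: zero variance, autocorrelation undefined",
         call. = FALSE)
  }
  if (max_lag < 1L || max_lag > N - 1L) {
    stop("'max_lag' must be between 1 and N - 1", call. = FALSE)
  }
  w <- vapply(seq_len(max_lag), function(j) {
    a <- x[(1 + j):N]
    b <- x[1:(N - j)]
    if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(NA_real_)
    }
    stats::cor(a, b)
  }, numeric(1))
  names(w) <- paste0("lag", seq_len(max_lag))
  w
}

#' Fit a univariate autoregression AR(p) by least squares
#'
#' Regresses `x(t)` on an intercept and its own `p` lagged values:
#' `x(t) = intercept + B_1 x(t-1) + ... + B_p x(t-p) + eps`.
#'
#' @param x Numeric series.
#' @param p Lag order, `1 <= p < N - 2`.
#' @return Object of class `"dyad_ar"` with elements `intercept`,
#'   `coefficients` (`B_1 ... B_p`), `residuals` (length `N - p`),
#'   `fitted`, `sigma2` (residual variance, denominator `N - 2p - 1`),
#'   `mean` (the implied stationary mean) and `p`.
#' @export
fit_ar <- function(x, p = 1L) {
  x <- as.numeric(x)
  N <- length(x)
  if (length(p) != 1L || p < 1L) {
    stop("'p' must be a positive integer", call. = FALSE)
  }
  p <- as.integer(p)
  if (N <= p + 2L) {
    stop("series too short: need N > p + 2", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate series: zero variance", call. = FALSE)
  }
  E <- stats::embed(x, p + 1L)       # col 1 = x(t), cols 2.. = lags 1..p
  y <- E[, 1]
  X <- cbind(1, E[, -1, drop = FALSE])
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  B <- fit$coefficients[-1]
  names(B) <- paste0("B", seq_len(p))
  structure(
    list(intercept = unname(fit$coefficients[1]),
         coefficients = B,
         residuals = res,
         fitted = fit$fitted.values,
         sigma2 = sum(res^2) / max(1, length(res) - (p + 1L)),
         mean = unname(fit$coefficients[1]) / (1 - sum(B)),
         p = p, n = N),
    class = "dyad_ar"
  )
}

#' @export
print.dyad_ar <- function(x, ...) {
  cat("AR(", x$p, ") fit, N = ", x$n, "\n", sep = "")
  cat("  intercept:", format(x$intercept, digits = 4), "\n")
  cat("  lag coefficients:",
      paste(format(x$coefficients, digits = 4), collapse = ", "), "\n")
  cat("  residual variance:", format(x$sigma2, digits = 4), "\n")
  invisible(x)
}
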