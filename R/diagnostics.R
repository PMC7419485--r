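# Residual diagnostics and lag selection for pooled VAR models.

# Pooled residual autocovariance at lag j, computed within dyad blocks so
# no cross-product spans a dyad boundary. Returns the matrix sum and the
# number of contributing pairs.
.block_autocov <- function(u, blocks, j) {
  m <- ncol(u)
  M <- matrix(0, m, m)
  n_pairs <- 0L
  for (b in unique(blocks)) {
    rows <- which(blocks == b)
    T_b <- length(rows)
    if (T_b > j) {
      a <- u[rows[(j + 1):T_b], , drop = FALSE]
      l <- u[rows[1:(T_b - j)], , drop = FALSE]
      M <- M + crossprod(a, l)
      n_pairs <- n_pairs + (T_b - j)
    }
  }
  list(M = M, n = n_pairs)
}

#' Portmanteau tests for residual serial correlation
#'
#' Tests the pooled VAR residuals for remaining temporal structure, with
#' autocovariances accumulated within dyad blocks. Two statistic forms:
#' \describe{
#'   \item{`"multivariate"` (default)}{small-sample (Ljung-Box-weighted)
#'     multivariate Portmanteau Q; under the null it is asymptotically
#'     chi-squared with `m^2 * (h - p)` degrees of freedom. The
#'     approximation requires those degrees of freedom to be small
#'     relative to the number of residual rows — with many variables and
#'     short panels it becomes severely size-distorted
#'     ([var_diagnostics()] guards this automatically).}
#'   \item{`"univariate"`}{per-equation Ljung-Box Q on each residual
#'     series' own autocorrelations (each chi-squared with `h - p` df),
#'     combined by Bonferroni across the `m` equations. Conservative but
#'     valid for any `m`, including systems too large for the
#'     multivariate form.}
#' }
#' A small p-value signals serial correlation, i.e. the lag order is too
#' small.
#'
#' @param model A `"dyad_var"`.
#' @param h Number of residual autocovariance lags to accumulate; must
#'   exceed the model's lag order `p`. Default `min(8, floor(nobs / 2))`.
#' @param statistic Which form to compute (see above).
#' @return An object of class `"htest"`.
#' @export
portmanteau_test <- function(model, h = NULL,
                             statistic = c("multivariate",
                                           "univariate")) {
  stopifnot(inherits(model, "dyad_var"))
  statistic <- match.arg(statistic)
  u <- model$residuals
  n <- nrow(u)
  m <- ncol(u)
  if (is.null(h)) h <- max(model$p + 1L, min(8L, floor(n / 2)))
  if (length(h) != 1L || h <= model$p) {
    stop("'h' must be a single integer greater than the lag order p",
         call. = FALSE)
  }
  h <- as.integer(h)
  C0 <- crossprod(u) / n
  if (statistic == "univariate") {
    Qk <- numeric(m)
    for (j in seq_len(h)) {
      ac <- .block_autocov(u, model$blocks, j)
      if (ac$n <= 0L) {
        stop("'h' too large: no lag-", j, " residual pairs available",
             call. = FALSE)
      }
      rk <- diag(ac$M / n) / diag(C0)
      Qk <- Qk + n^2 / ac$n * rk^2
    }
    df <- h - model$p
    pk <- stats::pchisq(Qk, df, lower.tail = FALSE)
    best <- which.min(pk)
    return(structure(
      list(statistic = c(Q = Qk[best]), parameter = c(df = df),
           p.value = min(1, m * pk[best]),
           method = paste0("Per-equation Ljung-Box (Bonferroni over ",
                           m, " equations), h = ", h),
           data.name = "VAR residuals"),
      class = "htest"))
  }
  C0inv <- solve(C0)
  Q <- 0
  for (j in seq_len(h)) {
    ac <- .block_autocov(u, model$blocks, j)
    if (ac$n <= 0L) {
      stop("'h' too large: no lag-", j, " residual pairs available",
           call. = FALSE)
    }
    Cj <- ac$M / n
    Q <- Q + n^2 / ac$n * sum(diag(t(Cj) %*% C0inv %*% Cj %*% C0inv))
  }
  df <- m^2 * (h - model$p)
  structure(
    list(statistic = c(Q = Q), parameter = c(df = df),
         p.value = stats::pchisq(Q, df, lower.tail = FALSE),
         method = paste0("Multivariate Portmanteau test (adjusted), h = ",
                         h),
         data.name = "VAR residuals"),
    class = "htest"
  )
}

#' Multivariate ARCH-LM test for residual heteroscedasticity
#'
#' Lagrange-multiplier test for time-varying residual variance, with two
#' statistic forms:
#' \describe{
#'   \item{`"vech"` (default)}{regresses the half-vectorized outer
#'     products of the residuals, `vech(u_t u_t')`, on an intercept and
#'     their own `q` lags (built within dyad blocks). Under the null the
#'     statistic `0.5 * n * m * (m + 1) * R^2_m` is asymptotically
#'     chi-squared with `q * m^2 * (m + 1)^2 / 4` degrees of freedom.}
#'   \item{`"aggregate"`}{regresses the scalar squared Mahalanobis norm
#'     of the residuals, `u_t' C0^{-1} u_t`, on an intercept and its own
#'     `q` lags; the statistic `n * R^2` is asymptotically chi-squared
#'     with `q` degrees of freedom. This form stays feasible when
#'     `m (m + 1) / 2` regressand dimensions would exceed the usable
#'     rows (e.g. a 26-variable model on a 10-month cohort).}
#' }
#' A small p-value signals heteroscedastic residuals.
#'
#' @param model A `"dyad_var"`.
#' @param q Number of lags of the squared-residual terms (default 4).
#' @param statistic Which form to compute (see above).
#' @return An object of class `"htest"`.
#' @export
arch_lm_test <- function(model, q = 4L,
                         statistic = c("vech", "aggregate")) {
  stopifnot(inherits(model, "dyad_var"))
  statistic <- match.arg(statistic)
  if (length(q) != 1L || q < 1L) {
    stop("'q' must be a positive integer", call. = FALSE)
  }
  q <- as.integer(q)
  u <- model$residuals
  m <- ncol(u)
  if (statistic == "aggregate") {
    C0 <- crossprod(u) / nrow(u)
    Yall <- matrix(rowSums((u %*% solve(C0)) * u), ncol = 1L)
    K <- 1L
  } else {
    K <- m * (m + 1L) / 2L
    lo <- lower.tri(diag(m), diag = TRUE)
    # vech(u_t u_t') rows
    Yall <- t(apply(u, 1, function(r) (tcrossprod(r))[lo]))
    if (K == 1L) Yall <- matrix(Yall, ncol = 1L)
  }

  ys <- list(); xs <- list()
  i <- 0L
  for (b in unique(model$blocks)) {
    rows <- which(model$blocks == b)
    T_b <- length(rows)
    if (T_b > q) {
      i <- i + 1L
      Vb <- Yall[rows, , drop = FALSE]
      ys[[i]] <- Vb[(q + 1):T_b, , drop = FALSE]
      xs[[i]] <- do.call(cbind, lapply(seq_len(q), function(k) {
        Vb[(q + 1 - k):(T_b - k), , drop = FALSE]
      }))
    }
  }
  if (i == 0L) {
    stop("sample-size error: no dyad block is longer than q = ", q,
         call. = FALSE)
  }
  Y <- do.call(rbind, ys)
  X <- cbind(1, do.call(rbind, xs))
  n_u <- nrow(Y)
  if (n_u <= ncol(X)) {
    stop("sample-size error: ", n_u, " usable rows for ", ncol(X),
         " ARCH-LM regressors; reduce q", call. = FALSE)
  }
  fit <- stats::lm.fit(X, Y)
  E <- as.matrix(fit$residuals)
  Omega <- crossprod(E) / n_u
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Omega0 <- crossprod(Yc) / n_u
  if (statistic == "aggregate") {
    R2 <- 1 - drop(Omega) / drop(Omega0)
    stat <- n_u * R2
    df <- q
  } else {
    R2m <- 1 - 2 / (m * (m + 1L)) * sum(diag(Omega %*% solve(Omega0)))
    stat <- 0.5 * n_u * m * (m + 1L) * R2m
    df <- q * m^2 * (m + 1L)^2 / 4
  }
  structure(
    list(statistic = c(LM = stat), parameter = c(df = df),
         p.value = stats::pchisq(stat, df, lower.tail = FALSE),
         method = paste0("Multivariate ARCH-LM test (", statistic,
                         "), q = ", q),
         data.name = "VAR residuals"),
    class = "htest"
  )
}

# Largest feasible settings for the vech-form ARCH-LM given block sizes:
# returns TRUE when the vech regression at lag q is identified.
.arch_vech_feasible <- function(model, q) {
  m <- ncol(model$residuals)
  K <- m * (m + 1L) / 2L
  sizes <- table(model$blocks)
  n_u <- sum(pmax(0L, sizes - q))
  n_u > 1L + q * K
}

#' Residual diagnostics report for a fitted VAR
#'
#' Runs the Portmanteau and ARCH-LM tests and the companion-eigenvalue
#' stability check, and records a pass/fail verdict at level `alpha`:
#' the model passes when both residual tests fail to reject (p-value
#' above `alpha`) and the model is eigenvalue-stable. The ARCH-LM uses
#' the richest feasible form: the vech regression when the design is
#' identified at lag `q`, otherwise the aggregate (squared-norm) form
#' (see [arch_lm_test()]); the form actually used is recorded.
#'
#' @param model A `"dyad_var"`.
#' @param alpha Significance level for the residual tests (default 0.05).
#' @param h Portmanteau lag span (see [portmanteau_test()]).
#' @param q ARCH-LM lag count (see [arch_lm_test()]).
#' @return Object of class `"var_diagnostics"`.
#' @export
var_diagnostics <- function(model, alpha = 0.05, h = NULL, q = 4L) {
  n <- nrow(model$residuals)
  m <- model$m
  if (is.null(h)) h <- max(model$p + 1L, min(8L, floor(n / 2)))
  # keep the multivariate chi-square in its valid regime: df <= n / 2;
  # shrink the lag span if needed, fall back to the per-equation form
  # when even one extra lag would overload it
  h_cap <- model$p + floor(n / (2 * m^2))
  if (h_cap > model$p) {
    pt_form <- "multivariate"
    pt <- portmanteau_test(model, h = min(h, h_cap),
                           statistic = "multivariate")
  } else {
    pt_form <- "univariate"
    pt <- portmanteau_test(model, h = h, statistic = "univariate")
  }
  arch_form <- if (.arch_vech_feasible(model, q)) "vech" else "aggregate"
  at <- arch_lm_test(model, q = q, statistic = arch_form)
  stable <- is_stable(model)
  structure(
    list(portmanteau = pt, arch_lm = at,
         portmanteau_form = pt_form, arch_form = arch_form,
         max_modulus = max(Mod(model$eigenvalues)),
         stable = stable, alpha = alpha, p = model$p,
         serial_ok = pt$p.value > alpha,
         variance_ok = at$p.value > alpha,
         pass = stable && pt$p.value > alpha && at$p.value > alpha),
    class = "var_diagnostics"
  )
}

#' @export
print.var_diagnostics <- function(x, ...) {
  cat("VAR residual diagnostics (lag p = ", x$p, ", alpha = ", x$alpha,
      ")\n", sep = "")
  cat(sprintf("  Portmanteau (%s): Q = %.3f, df = %d, p = %.4f  [%s]\n",
              x$portmanteau_form %||% "multivariate",
              x$portmanteau$statistic, x$portmanteau$parameter,
              x$portmanteau$p.value,
              if (x$serial_ok) "no serial correlation" else "REJECT"))
  cat(sprintf("  ARCH-LM (%s): LM = %.3f, df = %d, p = %.4f  [%s]\n",
              x$arch_form %||% "vech",
              x$arch_lm$statistic, x$arch_lm$parameter,
              x$arch_lm$p.value,
              if (x$variance_ok) "homoscedastic" else "REJECT"))
  cat(sprintf("  Stability:   max |eigenvalue| = %.4f  [%s]\n",
              x$max_modulus, if (x$stable) "stable" else "UNSTABLE"))
  cat("  verdict:", if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Select the VAR lag order by incremental residual diagnostics
#'
#' Starting from `p = 1`, fits a pooled VAR and checks the residual
#' requirements (no serial correlation, homoscedasticity) and stability;
#' the lag order is incremented until the first `p` whose fitted model
#' passes all three, mirroring the prescription to increase `p` until the
#' residual requirements are met. The full audit trail of per-`p`
#' diagnostics is returned.
#'
#' @param panel A [monthly_panel()].
#' @param p_max Largest lag order to try (default 4).
#' @param alpha Level for the residual tests.
#' @param h,q Passed to the residual tests.
#' @param ... Passed to [fit_var()].
#' @return Object of class `"lag_selection"`: list with the chosen `p`,
#'   the fitted `model`, and `reports` (one `"var_diagnostics"` per tried
#'   `p`). If no `p <= p_max` passes, an error of class
#'   `"dyadvar_no_convergence"` is signalled; its `reports` field carries
#'   the audit trail.
#' @export
select_lag <- function(panel, p_max = 4L, alpha = 0.05, h = NULL,
                       q = 4L, ...) {
  if (length(p_max) != 1L || p_max < 1L) {
    stop("'p_max' must be a positive integer", call. = FALSE)
  }
  reports <- list()
  for (p in seq_len(p_max)) {
    model <- tryCatch(fit_var(panel, p = p, ...), error = identity)
    if (inherits(model, "error")) {
      reports[[as.character(p)]] <- list(error = conditionMessage(model))
      next
    }
    diag_p <- tryCatch(var_diagnostics(model, alpha = alpha, h = h, q = q),
                       error = identity)
    if (inherits(diag_p, "error")) {
      reports[[as.character(p)]] <- list(error = conditionMessage(diag_p))
      next
    }
    reports[[as.character(p)]] <- diag_p
    if (diag_p$pass) {
      return(structure(list(p = p, model = model, reports = reports),
                       class = "lag_selection"))
    }
  }
  stop(errorCondition(
    paste0("no lag order p <= ", p_max, " yields residuals that pass ",
           "the diagnostics at alpha = ", alpha),
    reports = reports,
    class = c("dyadvar_no_convergence", "error", "condition")))
}

#' @export
print.lag_selection <- function(x, ...) {
  cat("Selected lag order p =", x$p, "after trying",
      length(x$reports), "order(s)\n")
  print(x$reports[[length(x$reports)]])
  invisible(x)
}
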