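# Shared fixtures: all built in code at test time.

# A minimal well-formed event log covering two dyads, two months,
# two sessions per month.
tiny_event_df <- function() {
  data.frame(
    dyad_id = rep(c("d1", "d2"), each = 8),
    group = rep(c("boy", "girl"), each = 8),
    month = rep(rep(3:4, each = 4), 2),
    session = rep(rep(1:2, each = 2), 4),
    code = rep(c("Crawl", "Reach"), 8),
    duration_s = c(10, 30, 12, 15, 8, 5, 6, 7,
                   20, 25, 18, 16, 9, 11, 13, 14),
    occurrences = rep(1:2, 8),
    stringsAsFactors = FALSE
  )
}

# Small 4-variable configs reused across VAR/IRF tests. Codes are drawn
# from the standard vocabulary so role-based sign tables work.
test_vars4 <- c("Crawl", "Babble", "Points to Object", "Holds Object")

# Stable 4x4 coupling with one planted cross-link (Crawl responds to
# prior Points to Object).
planted_A4 <- function(w = 0.4) {
  A <- diag(0.3, 4)
  A[1, 3] <- w
  A
}

latent_config4 <- function(n_dyads = 10, months = 1:30, w = 0.4,
                           seed = 1L) {
  generator_config(
    n_dyads_per_group = n_dyads, months = months,
    variables = test_vars4,
    coupling_by_group = list(all = planted_A4(w)),
    innovation_cov = diag(1, 4),
    emission = "gaussian_latent", seed = seed
  )
}

# Single long bivariate series as a one-dyad panel (gaussian VAR(1)).
sim_var1_matrix <- function(n, A, seed, Sigma_chol = diag(nrow(A))) {
  set.seed(seed)
  m <- nrow(A)
  X <- matrix(0, n, m)
  x <- rnorm(m)
  for (t in seq_len(n)) {
    x <- drop(A %*% x) + drop(Sigma_chol %*% rnorm(m))
    X[t, ] <- x
  }
  colnames(X) <- paste0("x", seq_len(m))
  X
}

expect_max_abs <- function(x, y, tol) {
  expect_lt(max(abs(x - y)), tol)
}

# Hand-built "dyad_var" object with known coefficients, for exercising the
# IRF algebra independently of estimation.
manual_var_model <- function(B, Sigma, intercepts = NULL,
                             residuals = NULL) {
  if (!is.list(B)) B <- list(B)
  m <- nrow(B[[1]])
  vars <- colnames(B[[1]])
  if (is.null(vars)) vars <- paste0("x", seq_len(m))
  for (k in seq_along(B)) dimnames(B[[k]]) <- list(vars, vars)
  dimnames(Sigma) <- list(vars, vars)
  if (is.null(intercepts)) intercepts <- rep(0, m)
  comp <- dyadVAR:::.companion(B)
  structure(
    list(variables = vars, p = length(B), m = m,
         intercepts = stats::setNames(intercepts, vars), B = B,
         residuals = residuals, Sigma = Sigma,
         blocks = if (is.null(residuals)) NULL
                  else rep("d1", nrow(residuals)),
         eigenvalues = eigen(comp, only.values = TRUE)$values,
         nobs = if (is.null(residuals)) NA_integer_ else nrow(residuals),
         n_dyads = 1L, group = "all", encoding = "gaussian_latent",
         months = NULL, center = FALSE),
    class = "dyad_var")
}
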