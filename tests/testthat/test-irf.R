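# Orthogonalized IRFs, bootstrap bands, and the conservative sweep.

test_that("the Cholesky factor reconstructs Sigma and exposes s1", {
  I2 <- diag(1, 2); dimnames(I2) <- list(c("a", "b"), c("a", "b"))
  expect_equal(unname(cholesky_factor(I2)$P), diag(2))

  S <- matrix(c(4, 2, 2, 3), 2, dimnames = list(c("a", "b"), c("a", "b")))
  cf <- cholesky_factor(S)
  expect_max_abs(cf$P, matrix(c(2, 1, 0, sqrt(2)), 2), 1e-12)
  expect_max_abs(cf$P %*% t(cf$P), S, 1e-12)
  # entry (1,1) is the first variable's residual sd; below it, cov / s1
  expect_equal(cf$P[1, 1], sqrt(S["a", "a"]))
  expect_equal(cf$P[2, 1], S["b", "a"] / sqrt(S["a", "a"]))
  # reordering re-attributes the shared variance
  cf_rev <- cholesky_factor(S, order = c("b", "a"))
  expect_equal(cf_rev$P[1, 1], sqrt(S["b", "b"]))
  expect_max_abs(cf_rev$P %*% t(cf_rev$P), S[2:1, 2:1], 1e-12)

  expect_error(cholesky_factor(matrix(c(1, 1, 1, 1), 2)),
               "not positive-definite")
})

test_that("null dynamics give a one-step impact and nothing after", {
  model <- manual_var_model(matrix(0, 2, 2), diag(1, 2))
  irf <- compute_irf(model, horizon = 5)
  expect_equal(unname(irf$theta[, , 1]), diag(2))
  expect_true(all(irf$theta[, , -1] == 0))
})

test_that("IRFs match the closed form and the simulation oracle", {
  # estimated VAR(1): Theta_h = B^h P
  coh <- generate_cohort(latent_config4(n_dyads = 8, months = 1:20),
                         seed = 14)
  model <- fit_var(coh$panel, p = 1)
  irf <- compute_irf(model, horizon = 10)
  P <- t(chol(model$Sigma))
  Bh <- diag(model$m)
  for (h in 0:10) {
    expect_max_abs(irf$theta[, , h + 1], Bh %*% P, 1e-10)
    Bh <- model$B[[1]] %*% Bh
  }

  # any p: shocked-minus-baseline trajectories difference to the curve
  model2 <- fit_var(coh$panel, p = 2)
  irf2 <- compute_irf(model2, horizon = 8)
  P2 <- t(chol(model2$Sigma))
  init <- matrix(0, 2, model2$m)
  base <- simulate_var(model2, init = init, steps = 9)
  for (j in seq_len(model2$m)) {
    shocked <- simulate_var(model2, init = init, steps = 9,
                            shock = P2[, j])
    # step 1 is the impact (horizon 0), steps 2..9 are horizons 1..8
    expect_max_abs(t(shocked - base), irf2$theta[, j, ], 1e-10)
    expect_max_abs(irf2$theta[, j, 1], P2[, j], 1e-12)
  }

  expect_error(compute_irf(model, horizon = 0), "positive integer")
})

test_that("unstable models are refused", {
  model <- manual_var_model(diag(1.05, 2), diag(1, 2))
  expect_error(compute_irf(model), "stability error")
})

test_that("scaling the innovations by k scales point IRFs and bands by k", {
  A <- matrix(c(0.5, 0.2, -0.1, 0.3), 2)
  m1 <- manual_var_model(A, diag(1, 2))
  m2 <- manual_var_model(A, diag(9, 2))
  i1 <- compute_irf(m1, horizon = 6)
  i2 <- compute_irf(m2, horizon = 6)
  expect_max_abs(i2$theta, 3 * i1$theta, 1e-12)

  # full bootstrap equivariance: scaling the panel scales the bands
  X <- sim_var1_matrix(80, A, seed = 9)
  p1 <- as_monthly_panel(X); p2 <- as_monthly_panel(3 * X)
  f1 <- fit_var(p1); f2 <- fit_var(p2)
  b1 <- bootstrap_irf_ci(f1, p1, reps = 50, seed = 123)
  b2 <- bootstrap_irf_ci(f2, p2, reps = 50, seed = 123)
  expect_max_abs(b2$theta, 3 * b1$theta, 1e-9)
  expect_max_abs(b2$lower, 3 * b1$lower, 1e-9)
  expect_max_abs(b2$upper, 3 * b1$upper, 1e-9)
})

test_that("IRFs of stable models decay to zero", {
  coh <- generate_cohort(latent_config4(n_dyads = 6, months = 1:20),
                         seed = 16)
  model <- fit_var(coh$panel, p = 1)
  irf <- compute_irf(model, horizon = 60)
  expect_lt(max(abs(irf$theta[, , 61])), 1e-3)
})

test_that("bands bracket the point curve and flag zero-exclusion", {
  coh <- generate_cohort(latent_config4(n_dyads = 10, months = 1:25,
                                        w = 0.5), seed = 18)
  pan <- coh$panel
  model <- fit_var(pan, p = 1)
  ci <- bootstrap_irf_ci(model, pan, reps = 100, seed = 44)
  expect_true(all(ci$lower <= ci$upper))
  expect_identical(ci$significant, ci$lower > 0 | ci$upper < 0)
  # the planted Crawl <- Points link is significant at horizon 1
  expect_true(ci$significant["Crawl", "Points to Object", "1"])
  # diagonal impacts (own residual sd) are positive and significant
  expect_true(all(diag(ci$significant[, , 1])))
  expect_error(bootstrap_irf_ci(model, pan, reps = 1), "reps")
  expect_error(bootstrap_irf_ci(model, pan, level = 101), "level")
})

test_that("exactly-zero residuals give zero-width bands at the point IRF", {
  A <- diag(c(0.5, 0.3)); dimnames(A) <- list(c("a", "b"), c("a", "b"))
  # deterministic panel: x(t) = A x(t-1) exactly, from a nonzero start
  X <- matrix(0, 20, 2, dimnames = list(NULL, c("a", "b")))
  X[1, ] <- c(4, -2)
  for (t in 2:20) X[t, ] <- drop(A %*% X[t - 1, ])
  pan <- as_monthly_panel(X)
  model <- fit_var(pan, p = 1)
  expect_lt(max(abs(model$residuals)), 1e-10)
  # force the degenerate covariance exactly to zero
  model$Sigma[] <- 0
  model$residuals[] <- 0
  ci <- bootstrap_irf_ci(model, pan, reps = 20, seed = 2)
  expect_max_abs(ci$theta, 0, 1e-12)          # zero shock, zero response
  expect_max_abs(ci$upper - ci$lower, 0, 1e-10)  # zero-width bands
  expect_max_abs(ci$lower - ci$theta, 0, 1e-10)
})

test_that("the conservative sweep takes each impulse from its own last slot", {
  X <- sim_var1_matrix(120, matrix(c(0.5, 0.3, 0, 0.4), 2), seed = 25,
                       Sigma_chol = t(chol(matrix(c(1, .5, .5, 1), 2))))
  pan <- as_monthly_panel(X)
  cons <- conservative_irf_sweep(pan, p = 1, reps = 40, seed = 77)
  expect_equal(cons$n_orderings, 2)
  expect_lt(cons$coef_max_dev, 1e-10)
  model <- fit_var(pan, p = 1)
  # x1 impulses from ordering (x2, x1); x2 impulses from (x1, x2)
  irf_x1_last <- compute_irf(model, order = c("x2", "x1"))
  irf_x2_last <- compute_irf(model, order = c("x1", "x2"))
  expect_max_abs(cons$theta[, "x1", ], irf_x1_last$theta[, "x1", ], 1e-12)
  expect_max_abs(cons$theta[, "x2", ], irf_x2_last$theta[, "x2", ], 1e-12)
  # entered-last attribution differs from entered-first when residuals
  # correlate
  irf_first <- compute_irf(model, order = c("x1", "x2"))
  expect_gt(max(abs(irf_first$theta[, "x1", ] - cons$theta[, "x1", ])), 0.01)
})

test_that("sweep bands match a per-ordering bootstrap with shared seed", {
  X <- sim_var1_matrix(100, diag(c(0.5, 0.3)), seed = 33)
  pan <- as_monthly_panel(X)
  cons <- conservative_irf_sweep(pan, p = 1, reps = 30, seed = 55)
  model <- fit_var(pan, p = 1)
  ci_x2 <- bootstrap_irf_ci(model, pan, reps = 30, seed = 55,
                            order = c("x1", "x2"))
  expect_max_abs(cons$lower[, "x2", ], ci_x2$lower[, "x2", ], 1e-12)
  expect_max_abs(cons$upper[, "x2", ], ci_x2$upper[, "x2", ], 1e-12)
})
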