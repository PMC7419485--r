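# Pooled VAR estimation.

test_that("pooled least squares recovers a planted coupling matrix", {
  cfg <- latent_config4(n_dyads = 40, months = 1:40)
  coh <- generate_cohort(cfg, seed = 31)
  model <- fit_var(coh$panel, p = 1)
  expect_max_abs(model$B[[1]], planted_A4(), 0.1)
  expect_equal(model$nobs, 40 * 39)   # 40 dyads pooled, 39 rows each
  expect_equal(length(unlist(model$B)), 1 * 4^2)
})

test_that("a single-dyad panel reduces to plain single-series VAR", {
  X <- sim_var1_matrix(60, diag(c(0.5, 0.2)), seed = 3)
  model <- fit_var(X, p = 1)
  # oracle: per-equation lm on the embedded design
  E <- embed(X, 2)
  for (j in 1:2) {
    ols <- lm.fit(cbind(1, E[, 3:4]), E[, j])
    expect_max_abs(c(model$intercepts[j], model$B[[1]][j, ]),
                   ols$coefficients, 1e-10)
  }
})

test_that("pooling builds lagged pairs within dyads only", {
  X <- sim_var1_matrix(40, diag(c(0.5, 0.2)), seed = 8)
  # split the series into two pseudo-dyads of 20 rows each
  vals <- array(NA_real_, dim = c(2, 20, 2))
  vals[1, , ] <- X[1:20, ]
  vals[2, , ] <- X[21:40, ]
  pan <- monthly_panel(vals,
                       dyads = data.frame(dyad_id = c("a", "b"),
                                          group = "all"),
                       months = 1:20, variables = colnames(X),
                       encoding = "gaussian_latent")
  model <- fit_var(pan, p = 1)
  expect_equal(model$nobs, 38)   # 2 x (20 - 1): the boundary pair is gone
  # oracle: stack the two embedded designs by hand
  Ea <- embed(X[1:20, ], 2); Eb <- embed(X[21:40, ], 2)
  Y <- rbind(Ea[, 1:2], Eb[, 1:2])
  D <- cbind(1, rbind(Ea[, 3:4], Eb[, 3:4]))
  for (j in 1:2) {
    ols <- lm.fit(D, Y[, j])
    expect_max_abs(c(model$intercepts[j], model$B[[1]][j, ]),
                   ols$coefficients, 1e-10)
  }
})

test_that("residuals are orthogonal to the design (normal equations)", {
  cfg <- latent_config4(n_dyads = 5, months = 1:15)
  coh <- generate_cohort(cfg, seed = 12)
  model <- fit_var(coh$panel, p = 2)
  # rebuild the stacked lagged design and check X'e ~ 0 per equation
  vals <- coh$panel$values
  xs <- list(); k <- 0
  for (i in seq_len(nrow(coh$panel$dyads))) {
    V <- vals[i, , ]
    k <- k + 1
    xs[[k]] <- cbind(V[2:14, ], V[1:13, ])
  }
  X <- cbind(1, do.call(rbind, xs))
  expect_max_abs(crossprod(X, model$residuals), 0, 1e-7)
})

test_that("coefficients are invariant to variable entry order", {
  cfg <- latent_config4(n_dyads = 6, months = 1:20)
  coh <- generate_cohort(cfg, seed = 4)
  model <- fit_var(coh$panel, p = 1)
  rev_panel <- panel_select(coh$panel, rev(coh$panel$variables))
  model_r <- fit_var(rev_panel, p = 1)
  back <- match(coh$panel$variables, rev_panel$variables)
  expect_max_abs(model_r$B[[1]][back, back], model$B[[1]], 1e-10)
  expect_max_abs(model_r$Sigma[back, back], model$Sigma, 1e-10)
})

test_that("degenerate columns error by name unless dropped", {
  coh <- generate_cohort(latent_config4(n_dyads = 4, months = 1:10),
                         seed = 2)
  vals <- coh$panel$values
  vals[, , 2] <- 5   # make Babble constant
  pan <- monthly_panel(vals, dyads = coh$panel$dyads,
                       months = coh$panel$months,
                       variables = coh$panel$variables,
                       encoding = "gaussian_latent")
  expect_error(fit_var(pan, p = 1), "Babble")
  expect_message(m2 <- fit_var(pan, p = 1, drop_degenerate = TRUE),
                 "Babble")
  expect_equal(m2$m, 3)
})

test_that("insufficient data raises sample-size errors", {
  X <- matrix(rnorm(8), 4, 2)
  expect_error(fit_var(X, p = 4), "lag order")
  expect_error(fit_var(X, p = 3), "sample-size")
})

test_that("the stability flag agrees with long forward simulation", {
  stable <- fit_var(sim_var1_matrix(300, diag(c(0.6, 0.4)), seed = 6),
                    p = 1)
  expect_true(is_stable(stable))
  traj <- simulate_var(stable, init = matrix(5, 1, 2), steps = 1000)
  expect_true(all(is.finite(traj)))
  expect_lt(max(abs(traj[1000, ])), max(abs(traj[1, ])) + 1)

  set.seed(13)
  Xu <- matrix(0, 40, 2); x <- c(0.1, 0.1)
  for (t in 1:40) {
    x <- drop(diag(c(1.08, 1.05)) %*% x) + rnorm(2, sd = 0.01)
    Xu[t, ] <- x
  }
  unstable <- fit_var(Xu, p = 1)
  expect_false(is_stable(unstable))
  traj_u <- simulate_var(unstable, init = matrix(1, 1, 2), steps = 1000)
  expect_gt(max(abs(traj_u[1000, ])), 1e6)
})
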