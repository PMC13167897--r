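test_that("P-spline penalty: second differences, vanishing on linear blocks", {
  b <- time_basis(1:19, K = 7)
  blk <- penalty_block(b, "pspline")
  expect_equal(dim(blk), c(6, 6))
  expect_equal(qr(blk)$rank, 4)  # D is 4 x 6
  theta_lin <- 2 * (1:6) - 3
  expect_equal(drop(theta_lin %*% blk %*% theta_lin), 0, tolerance = 1e-20)
  # full penalty matrix: block-diagonal on theta, zero on gamma/phi/alpha
  st <- list(phi = c(1, 3), theta = c(2, 5),
             alpha = cbind(j = 1, jp = 3))
  pen <- penalty_spec(b, "pspline", lambda = 1, structure = st, S_times = 19)
  expect_true(isSymmetric(pen$Smat))
  expect_true(all(eigen(pen$Smat, only.values = TRUE)$values > -1e-10))
  lay <- pen$lay
  expect_true(all(pen$Smat[lay$idx_gamma, ] == 0))
  expect_true(all(pen$Smat[lay$idx_phi, ] == 0))
  expect_true(all(pen$Smat[lay$idx_alpha, ] == 0))
  expect_equal(pen$Smat[lay$idx_theta[1:6], lay$idx_theta[1:6]], blk)
  # empty TV set -> zero matrix
  pen0 <- penalty_spec(b, "pspline", lambda = 1,
                       structure = list(phi = 1, theta = integer(0),
                                        alpha = NULL), S_times = 19)
  expect_true(all(pen0$Smat == 0))
})

test_that("smoothing-spline penalty matches fine trapezoid quadrature", {
  b <- time_basis(1:19, K = 7)
  blk <- penalty_block(b, "smoothing_spline")
  npts <- 8001
  xs <- seq(1, 19, length.out = npts)
  ak <- c(rep(1, 4), b$knots, rep(19, 4))
  D2 <- splines::splineDesign(ak, xs, derivs = rep(2L, npts))[, -1]
  h <- xs[2] - xs[1]
  wq <- rep(h, npts); wq[c(1, npts)] <- h / 2
  oracle <- crossprod(D2 * sqrt(wq))
  expect_equal(blk, oracle, tolerance = 1e-6)
})

test_that("penalized log-likelihood reduces correctly at lambda = 0 / theta = 0", {
  ds <- toy_dsurv(n = 15, S = 5, P = 3, seed = 13)
  b <- time_basis(ds$grid, K = 5)
  st <- list(phi = 1:2, theta = c(1L, 3L), alpha = cbind(j = 1, jp = 2))
  lay <- discboost:::refit_layout(5, st, ncol(b$Bmat))
  set.seed(3)
  om <- rnorm(lay$p, 0, 0.3)
  pen0 <- penalty_spec(b, "none", 0, st, 5)
  pen2 <- penalty_spec(b, "pspline", 2, st, 5)
  # direct evaluation through the model-state machinery
  state <- refit_state(structure(list(omega = om, layout = lay, structure = st,
                                      P = 3), class = "disc_refit"), P = 3)
  expect_equal(penalized_loglik(om, ds, b, st, pen0),
               log_likelihood(state, ds, b), tolerance = 1e-10)
  quad <- 0.5 * 2 * drop(om %*% pen2$Smat %*% om) / 2  # lambda/2 * theta S theta
  expect_equal(penalized_loglik(om, ds, b, st, pen2),
               log_likelihood(state, ds, b) -
                 0.5 * pen2$lambda * drop(om %*% pen2$Smat %*% om),
               tolerance = 1e-10)
  om_nt <- om
  om_nt[lay$idx_theta] <- 0
  expect_equal(penalized_loglik(om_nt, ds, b, st, pen2),
               penalized_loglik(om_nt, ds, b, st, pen0), tolerance = 1e-12)
})

test_that("score and information match finite differences", {
  ds <- toy_dsurv(n = 25, S = 4, P = 3, seed = 19)
  b <- time_basis(ds$grid, K = 5)
  st <- list(phi = 1:3, theta = c(2L), alpha = cbind(j = 2, jp = 3))
  pen <- penalty_spec(b, "pspline", 1.5, st, 4)
  lay <- pen$lay
  set.seed(8)
  om <- rnorm(lay$p, 0, 0.25)
  si <- score_and_information(om, ds, b, st, pen)
  h <- 1e-5
  fd_g <- vapply(seq_len(lay$p), function(k) {
    e <- rep(0, lay$p); e[k] <- h
    (penalized_loglik(om + e, ds, b, st, pen) -
       penalized_loglik(om - e, ds, b, st, pen)) / (2 * h)
  }, numeric(1))
  expect_equal(si$gradient, fd_g, tolerance = 1e-5)
  pen0 <- penalty_spec(b, "none", 0, st, 4)
  fd_H <- vapply(seq_len(lay$p), function(k) {
    e <- rep(0, lay$p); e[k] <- h
    (score_and_information(om + e, ds, b, st, pen0)$gradient -
       score_and_information(om - e, ds, b, st, pen0)$gradient) / (2 * h)
  }, numeric(lay$p))
  expect_equal(si$I0, -(fd_H + t(fd_H)) / 2, tolerance = 1e-4)
  expect_equal(si$Ilambda, si$I0 + 1.5 * pen$Smat, tolerance = 1e-12)
})

test_that("gamma-only Newton fit equals the closed-form discrete-hazard MLE", {
  set.seed(5)
  n <- 200; S <- 4
  df <- data.frame(time = sample.int(S, n, TRUE),
                   event = rbinom(n, 1, 0.7), z1 = rnorm(n))
  ds <- as_dsurv(df, grid = 1:S, time_mode = "index")
  b <- time_basis(ds$grid, K = 5)
  fit <- newton_fit(ds, b, list(phi = integer(0), theta = integer(0),
                                alpha = NULL))
  d <- vapply(1:S, function(s) sum(ds$event == 1 & ds$time_index == s), 1)
  r <- vapply(1:S, function(s) sum(ds$time_index >= s), 1)
  expect_true(all(d > 0))
  expect_equal(fit$omega, qlogis(d / r), tolerance = 1e-6)
  expect_true(fit$converged)
  # at the MLE the score vanishes
  pen0 <- penalty_spec(b, "none", 0, list(phi = integer(0),
                                          theta = integer(0), alpha = NULL), S)
  g <- score_and_information(fit$omega, ds, b,
                             list(phi = integer(0), theta = integer(0),
                                  alpha = NULL), pen0)$gradient
  expect_lt(max(abs(g)), 1e-6)
})

test_that("lambda = 0 penalized fit equals the unpenalized MLE", {
  sim <- simulate_dsurv(scenario_spec("highdim", n = 150, P = 4, seed = 37))
  ds <- sim$dsurv
  b <- time_basis(ds$grid)
  st <- list(phi = 1:2, theta = 2L, alpha = NULL)
  f0 <- newton_fit(ds, b, st, penalty = "none", lambda = 0)
  fp <- newton_fit(ds, b, st, penalty = "pspline", lambda = 0)
  expect_equal(f0$loglik, fp$loglik, tolerance = 1e-8)
  expect_equal(f0$omega, fp$omega, tolerance = 1e-6)
  expect_equal(f0$df_reest, f0$layout$p, tolerance = 1e-8)
})

test_that("time-independent truth is recovered within three standard errors", {
  spec <- scenario_spec("custom", n = 2000, P = 3, rho = 0.3,
                        gamma_true = rep(-2, 6),
                        beta_funs = list(function(t) rep(0.8, length(t)),
                                         function(t) rep(-0.5, length(t)),
                                         function(t) rep(0, length(t))),
                        seed = 41)
  sim <- simulate_dsurv(spec)
  b <- time_basis(sim$dsurv$grid)
  st <- list(phi = 1:3, theta = integer(0), alpha = NULL)
  fit <- newton_fit(sim$dsurv, b, st)
  se <- sqrt(diag(solve(fit$Ilambda)))
  idx <- fit$layout$idx_phi
  expect_true(all(abs(fit$omega[idx] - c(0.8, -0.5, 0)) < 3 * se[idx]))
})

test_that("re-estimation degrees of freedom follow the trace formula", {
  # scalar closed form 2r - r^2 per coordinate
  I0 <- diag(c(2, 2))
  S <- diag(c(1, 0))
  expect_equal(reestimation_df(I0, I0 + 2 * S), 1.75)
  expect_equal(reestimation_df(I0, I0), 2)
  # p at lambda 0; decreasing and continuous in lambda; below p for large lambda
  set.seed(6)
  A <- crossprod(matrix(rnorm(36), 6))
  Sm <- crossprod(matrix(rnorm(36), 6))
  lams <- c(0, 10^seq(-2, 6, by = 1))
  dfs <- vapply(lams, function(l) reestimation_df(A, A + l * Sm), numeric(1))
  expect_equal(dfs[1], 6, tolerance = 1e-10)
  expect_true(all(diff(dfs) < 1e-8))
  expect_lt(dfs[length(dfs)], 6)
})

test_that("TIC at lambda = 0 is -2 loglik + 2p; the trace is monotone", {
  sim <- simulate_dsurv(scenario_spec("highdim", n = 150, P = 4, seed = 43))
  ds <- sim$dsurv
  b <- time_basis(ds$grid)
  st <- list(phi = 1:2, theta = 1:2, alpha = NULL)
  sel <- tic_select_lambda(ds, b, st, penalty = "pspline",
                           lambda_grid = c(0, 1, 10, 100))
  f0_tic <- sel$path$tic[sel$path$lambda == 0]
  f0 <- newton_fit(ds, b, st, penalty = "none")
  expect_equal(f0_tic, -2 * f0$loglik + 2 * f0$layout$p, tolerance = 1e-6)
  # trace term tr(I_lambda^{-1} I_0) non-increasing along the grid
  traces <- vapply(c(0, 1, 10, 100), function(l) {
    f <- newton_fit(ds, b, st, penalty = "pspline", lambda = l)
    sum(diag(solve(f$Ilambda, f$I0)))
  }, numeric(1))
  expect_true(all(diff(traces) < 1e-8))
  # degenerate grid {0} returns the unpenalized MLE
  sel0 <- tic_select_lambda(ds, b, st, penalty = "pspline", lambda_grid = 0)
  expect_equal(sel0$fit$loglik, f0$loglik, tolerance = 1e-8)
})

test_that("re-estimation BIC path schedules refits and finds true structure", {
  spec <- scenario_spec("custom", n = 400, P = 10, rho = 0.5,
                        gamma_true = rep(-1.8, 8),
                        beta_funs = pad_beta_test(1.2, 10), seed = 47)
  sim <- simulate_dsurv(spec)
  fit <- disc_boost(sim$dsurv, m_max = 20, stopping = "fixed",
                    interactions = FALSE)
  re1 <- reestimation_bic_path(sim$dsurv, fit, every = 5)
  expect_equal(re1$path$m, c(5, 10, 15, 20))
  re2 <- reestimation_bic_path(sim$dsurv, fit, every = 1)
  expect_equal(nrow(re2$path), 20)
  expect_true(1 %in% c(re1$structure$phi, re1$structure$theta))
})

test_that("hazard-ratio curves: identity contrast, flat TI curve, delta-method
           band against a parametric-bootstrap oracle", {
  sim <- simulate_dsurv(scenario_spec("highdim", n = 300, P = 3, seed = 53))
  ds <- sim$dsurv
  b <- time_basis(ds$grid)
  st <- list(phi = 1:2, theta = 2L, alpha = NULL)
  fit <- newton_fit(ds, b, st)
  z0 <- rep(0, 3)
  same <- hazard_ratio_curve(fit, z0, z0)
  expect_true(all(same$estimate == 1 & same$lo == 1 & same$hi == 1))
  # TI-only contrast in covariate 1: flat curve exp(phi_1)
  z1 <- c(1, 0, 0)
  hr <- hazard_ratio_curve(fit, z1, z0)
  expect_equal(hr$estimate,
               rep(exp(fit$omega[fit$layout$idx_phi[1]]), ds$S),
               tolerance = 1e-10)
  # bootstrap oracle for the log-scale SE at a contrast involving the spline
  z2 <- c(0, 1, 0)
  hr2 <- hazard_ratio_curve(fit, z2, z0)
  set.seed(11)
  draws <- MASS::mvrnorm(2000, fit$omega, solve(fit$Ilambda))
  cs <- numeric(fit$layout$p)
  s_at <- 10
  cs[fit$layout$idx_phi[2]] <- 1
  cs[fit$layout$idx_theta] <- b$Bmat[s_at, ]
  boot_sd <- sd(draws %*% cs)
  expect_equal(hr2$se_log[s_at], boot_sd, tolerance = 0.1)
})

test_that("Newton never decreases the penalized objective across iterations", {
  # tracked implicitly by convergence; verify the final objective dominates
  # the starting one and a perturbed start still converges to the same optimum
  sim <- simulate_dsurv(scenario_spec("highdim", n = 200, P = 4, seed = 59))
  ds <- sim$dsurv
  b <- time_basis(ds$grid)
  st <- list(phi = 1:3, theta = 1:2, alpha = NULL)
  f1 <- newton_fit(ds, b, st, penalty = "pspline", lambda = 5)
  lay <- f1$layout
  pen <- penalty_spec(b, "pspline", 5, st, ds$S)
  pll0 <- penalized_loglik(numeric(lay$p), ds, b, st, pen)
  expect_gt(f1$penalized_loglik, pll0)
  set.seed(3)
  f2 <- newton_fit(ds, b, st, penalty = "pspline", lambda = 5,
                   init = rnorm(lay$p, 0, 0.2))
  expect_equal(f1$penalized_loglik, f2$penalized_loglik, tolerance = 1e-7)
})
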