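test_that("baseline_ls is the per-time risk-set mean; empty risk sets give 0", {
  ds <- toy_dsurv(n = 10, S = 4, P = 2, seed = 3)
  b <- time_basis(ds$grid, K = 5)
  U <- gradient_eta(model_state(4, 2, ncol(b$Bmat)), ds, b)
  gt <- baseline_ls(U, ds)
  mask <- outer(ds$time_index, 1:4, ">=")
  for (s in 1:4) expect_equal(gt[s], mean(U[mask[, s], s]))
  # brute-force grid minimization of the least-squares objective, one time at
  # a time (the objective separates over s)
  obj <- function(g, s) sum((U[mask[, s], s] - g)^2)
  for (s in 1:4) {
    grid <- seq(-1, 1, by = 1e-4)
    expect_equal(gt[s], grid[which.min(vapply(grid, obj, numeric(1), s = s))],
                 tolerance = 1e-3)
  }
  # an empty risk set contributes zero
  ds2 <- toy_dsurv(n = 5, S = 3, P = 1, seed = 2)
  ds2$time_index <- pmin(ds2$time_index, 2L)  # nobody reaches s = 3
  U2 <- matrix(0.1, 5, 3)
  expect_equal(baseline_ls(U2 * outer(ds2$time_index, 1:3, ">="), ds2)[3], 0)
})

test_that("apply_baseline centers the gradient within every risk set", {
  ds <- toy_dsurv(n = 12, S = 4, P = 2, seed = 5)
  b <- time_basis(ds$grid, K = 5)
  st <- model_state(4, 2, ncol(b$Bmat), gamma = rep(-2, 4))
  U <- gradient_eta(st, ds, b)
  gt <- baseline_ls(U, ds)
  out <- apply_baseline(st, U, gt, nu_gamma = 1, ds)
  expect_equal(out$state$gamma, rep(-2, 4) + gt)
  mask <- outer(ds$time_index, 1:4, ">=")
  for (s in which(colSums(mask) > 0)) {
    expect_equal(mean(out$U[mask[, s], s]), 0, tolerance = 1e-12)
  }
  noop <- apply_baseline(st, U, rep(0, 4), 1, ds)
  expect_identical(noop$U, U)
})

test_that("group least-squares fits equal long-format regression oracles", {
  ds <- toy_dsurv(n = 40, S = 6, P = 3, seed = 11)
  b <- time_basis(ds$grid, K = 5)
  st <- random_state(6, 3, ncol(b$Bmat), seed = 2)
  U <- gradient_eta(st, ds, b)
  li <- long_index(ds)
  u <- U[li]
  for (j in 1:3) {
    ti <- group_ls_fit(U, ds, b, list(type = "TI", j = j))
    x <- ds$Z[li[, "i"], j]
    lmf <- lm(u ~ x - 1)
    expect_equal(ti$coef, unname(coef(lmf)), tolerance = 1e-8)
    expect_equal(ti$rss, sum(resid(lmf)^2), tolerance = 1e-8)

    tv <- group_ls_fit(U, ds, b, list(type = "TV", j = j))
    X <- b$Bmat[li[, "s"], ] * ds$Z[li[, "i"], j]
    lmv <- lm(u ~ X - 1)
    expect_equal(unname(tv$coef), unname(coef(lmv)), tolerance = 1e-8)
    expect_equal(tv$rss, sum(resid(lmv)^2), tolerance = 1e-8)
  }
  int <- group_ls_fit(U, ds, b, list(type = "INT", j = 1, jp = 3))
  x <- (ds$Z[, 1] * ds$Z[, 3])[li[, "i"]]
  lmi <- lm(u ~ x - 1)
  expect_equal(int$coef, unname(coef(lmi)), tolerance = 1e-8)
  # single pseudo-observation closed form: x = 2, U = 1 -> 2/4
  ds1 <- as_dsurv(data.frame(time = 1, event = 1, z1 = 2),
                  grid = c(1, 2), time_mode = "index")
  U1 <- matrix(c(1, 0), 1, 2)
  expect_equal(group_ls_fit(U1, ds1, b = time_basis(c(1, 2), K = 5),
                            list(type = "TI", j = 1))$coef, 0.5)
})

test_that("a degenerate design column is skipped with a warning", {
  ds <- toy_dsurv(n = 10, S = 4, P = 2, seed = 3)
  ds$Z[, 2] <- 0
  b <- time_basis(ds$grid, K = 5)
  U <- gradient_eta(model_state(4, 2, ncol(b$Bmat)), ds, b)
  expect_warning(out <- group_ls_fit(U, ds, b, list(type = "TV", j = 2)),
                 "singular|degenerate")
  expect_identical(out$rss, Inf)
})

test_that("select_term minimizes RSS over eligible candidates", {
  # z1 strongly predicts U, z2 is noise
  set.seed(21)
  n <- 80; S <- 4
  df <- data.frame(time = sample.int(S, n, TRUE), event = rbinom(n, 1, 0.5),
                   z1 = rnorm(n), z2 = rnorm(n))
  ds <- as_dsurv(df, grid = 1:S, time_mode = "index")
  b <- time_basis(ds$grid, K = 5)
  U <- (0.8 * ds$Z[, 1]) * outer(ds$time_index, 1:S, ">=")
  sets <- candidate_sets(2, "none")
  sel <- select_term(U, ds, b, sets)
  expect_equal(sel$j, 1)
  rss_loop <- c(
    vapply(1:2, function(j) group_ls_fit(U, ds, b, list(type = "TI", j = j))$rss, 1),
    vapply(1:2, function(j) group_ls_fit(U, ds, b, list(type = "TV", j = j))$rss, 1),
    group_ls_fit(U, ds, b, list(type = "INT", j = 1, jp = 2))$rss
  )
  expect_equal(sel$rss, min(rss_loop), tolerance = 1e-10)
})

test_that("exact RSS ties break by category TI < TV < INT, then lowest index", {
  # duplicated covariate: identical TI RSS for j = 1, 2
  set.seed(4)
  n <- 30; S <- 3
  z <- rnorm(n)
  df <- data.frame(time = sample.int(S, n, TRUE), event = rbinom(n, 1, 0.6),
                   z1 = z, z2 = z)
  ds <- as_dsurv(df, grid = 1:S, time_mode = "index")
  b <- time_basis(ds$grid, K = 5)
  U <- (0.5 * z) * outer(ds$time_index, 1:S, ">=")
  sel <- select_term(U, ds, b, candidate_sets(2, "none"))
  expect_equal(sel$type, "TI")
  expect_equal(sel$j, 1)
})

test_that("update_state moves only the selected term by nu times the fit", {
  st <- model_state(3, 4, 4)
  st1 <- update_state(st, list(type = "TI", j = 2, coef = 0.4), nu = 0.5)
  expect_equal(st1$phi, c(0, 0.2, 0, 0))
  expect_identical(st1$theta, st$theta)
  st2 <- update_state(st1, list(type = "TI", j = 2, coef = 0.4), nu = 0.5)
  expect_equal(st2$phi[2], 0.4)  # additivity of successive increments
  st3 <- update_state(st, list(type = "TV", j = 3, coef = rep(1, 4)), nu = 0)
  expect_identical(st3$theta, st$theta)
  st4 <- update_state(st, list(type = "INT", j = 1, jp = 4, coef = -0.6), nu = 0.5)
  expect_equal(unname(st4$alpha[1, ]), c(1, 4, -0.3))
})

test_that("candidate sets follow the hierarchy definitions", {
  # strong: selecting TI 3, then the TV block of covariate 7
  s <- candidate_sets(8, "strong")
  expect_equal(nrow(eligible_pairs(s)), 0)
  s <- update_candidates(s, list(type = "TI", j = 3))
  expect_equal(nrow(eligible_pairs(s)), 0)
  s <- update_candidates(s, list(type = "TV", j = 7))
  expect_equal(unname(eligible_pairs(s)), cbind(3L, 7L))
  # selecting an interaction leaves G1 unchanged
  s2 <- update_candidates(s, list(type = "INT", j = 3, jp = 7))
  expect_equal(sort(s2$G1), c(3L, 7L))
  # weak: any pair touching G1
  w <- candidate_sets(4, "weak")
  w$G1 <- 3L
  expect_equal(unname(eligible_pairs(w)),
               cbind(c(1L, 2L, 3L), c(3L, 3L, 4L)))
  # none: always all pairs
  expect_equal(nrow(eligible_pairs(candidate_sets(4, "none"))), 6)
})

test_that("boosting BIC is -2 loglik + log(n) df", {
  expect_equal(boosting_bic(-100, 5, exp(1)), 205)
  expect_equal(boosting_bic(-50, 0, 100), 100)
  expect_true(boosting_bic(-10, 3, 50) > boosting_bic(-10, 2, 50))
  expect_error(boosting_bic(-10, -1, 50))
})

test_that("a single strong signal is selected at the first iteration and the
           training log-likelihood increases along the path", {
  spec <- scenario_spec("custom", n = 250, P = 6, rho = 0,
                        gamma_true = rep(-1.5, 6),
                        beta_funs = pad_beta_test(1.5, 6), seed = 31)
  sim <- simulate_dsurv(spec)
  fit <- disc_boost(sim$dsurv, m_max = 15, stopping = "fixed",
                    interactions = FALSE)
  expect_equal(fit$trace$j[1], 1)
  expect_true(all(diff(fit$trace$loglik[1:10]) > -1e-8))
})

test_that("selection is invariant to subject ordering", {
  sim <- simulate_dsurv(scenario_spec("highdim", n = 120, P = 8, seed = 17))
  ds <- sim$dsurv
  fit1 <- disc_boost(ds, m_max = 10, stopping = "fixed", interactions = FALSE)
  set.seed(99)
  perm <- sample.int(ds$n)
  df2 <- as.data.frame(ds)[perm, ]
  ds2 <- as_dsurv(df2, id = "id", grid = ds$grid)
  fit2 <- disc_boost(ds2, m_max = 10, stopping = "fixed", interactions = FALSE)
  expect_equal(fit1$trace$type, fit2$trace$type)
  expect_equal(fit1$trace$j, fit2$trace$j)
  expect_equal(fit1$trace$loglik, fit2$trace$loglik, tolerance = 1e-10)
})

test_that("hierarchy safety holds on every boosting run", {
  for (hier in c("strong", "weak")) {
    sim <- simulate_dsurv(scenario_spec("interaction", n = 300, P = 8,
                                        seed = 23))
    fit <- disc_boost(sim$dsurv, m_max = 80, stopping = "fixed",
                      hierarchy = hier)
    tr <- fit$trace
    main_first <- function(j, m) {
      any(tr$type[seq_len(m)] %in% c("TI", "TV") & tr$j[seq_len(m)] == j)
    }
    ints <- which(tr$type == "INT")
    for (m in ints) {
      ok_j <- main_first(tr$j[m], m - 1)
      ok_jp <- main_first(tr$jp[m], m - 1)
      if (hier == "strong") expect_true(ok_j && ok_jp)
      if (hier == "weak") expect_true(ok_j || ok_jp)
    }
    # final-state check
    st <- fit$state
    ap <- st$alpha[st$alpha[, "value"] != 0, , drop = FALSE]
    for (r in seq_len(nrow(ap))) {
      inj <- st$phi[ap[r, "j"]] != 0 || any(st$theta[ap[r, "j"], ] != 0)
      injp <- st$phi[ap[r, "jp"]] != 0 || any(st$theta[ap[r, "jp"], ] != 0)
      if (hier == "strong") expect_true(inj && injp)
      if (hier == "weak") expect_true(inj || injp)
    }
  }
})

test_that("the time-varying hierarchy keeps spline blocks behind main effects", {
  sim <- simulate_dsurv(scenario_spec("highdim", n = 250, P = 6, seed = 29))
  fit <- disc_boost(sim$dsurv, m_max = 40, stopping = "fixed",
                    interactions = FALSE, tv_hierarchy = TRUE)
  st <- fit$state
  tv_sel <- which(rowSums(st$theta != 0) > 0)
  expect_true(all(st$phi[tv_sel] != 0))
  tr <- fit$trace
  for (m in which(tr$type == "TV")) {
    expect_true(any(tr$type[seq_len(m - 1)] == "TI" &
                      tr$j[seq_len(m - 1)] == tr$j[m]))
  }
})

test_that("oracle recovery: one strong covariate among noise is found within
           the first iterations across seeded replicates", {
  hits <- 0
  reps <- 25
  for (r in seq_len(reps)) {
    spec <- scenario_spec("custom", n = 150, P = 10, rho = 0.5,
                          gamma_true = rep(-1.6, 5),
                          beta_funs = pad_beta_test(1.5, 10),
                          seed = 400 + r)
    sim <- simulate_dsurv(spec)
    fit <- disc_boost(sim$dsurv, m_max = 3, stopping = "fixed",
                      interactions = FALSE)
    if (any(fit$trace$j[1:3] == 1)) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})
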