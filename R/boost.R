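#' Component-wise gradient boosting for discrete failure time models
#'
#' Runs the iterative selection procedure: every iteration first refreshes
#' the baseline hazard by a least-squares step on the gradient, then fits the
#' gradient to each eligible time-independent term, time-varying spline block
#' and interaction pair, advances only the best-fitting term by a step `nu`,
#' and updates the hierarchy candidate sets. Two stopping rules are
#' available: `"boosting_bic"` tracks an approximate hat matrix whose trace
#' gives the degrees of freedom in \eqn{-2\ell + \log(n)\,\mathrm{df}};
#' `"reestimation_bic"` refits the selected structure by penalized Newton
#' every `every` iterations and uses the information-based degrees of
#' freedom (see [reestimation_bic_path()]); `"fixed"` simply runs to `m_max`.
#' The stopping iteration is the global BIC argmin over the evaluated
#' iterations (smallest `m` on ties).
#'
#' @param data A data frame (one row per subject) or a `dsurv` object.
#' @param ... Passed to [as_dsurv()] when `data` is a data frame
#'   (`time`, `event`, `covariates`, `id`, `grid`, `time_mode`).
#' @param K Number of B-spline basis functions before reduction (default 7).
#' @param nu Step size for covariate terms (default 0.5).
#' @param nu_gamma Step size for the baseline (default 1).
#' @param m_max Maximum number of boosting iterations.
#' @param hierarchy Interaction hierarchy: `"strong"`, `"weak"` or `"none"`.
#' @param tv_hierarchy Logical; if `TRUE` a covariate's spline block is
#'   eligible only once its time-independent effect is non-zero.
#' @param interactions Logical; set `FALSE` to exclude interaction candidates
#'   entirely (main-effects-only selection).
#' @param stopping `"boosting_bic"`, `"reestimation_bic"` or `"fixed"`.
#' @param hat_cap Maximum pseudo-observation count for the dense hat-matrix
#'   path (default 20000).
#' @param hat_include_gamma Logical; also compose the baseline step's
#'   projection into the hat-matrix recursion (default `FALSE`: only the
#'   selected term's projection enters, matching the recursion's initial
#'   condition `B_1 = nu W H`).
#' @param every Refit schedule for the re-estimation rule (default 5).
#' @param penalty,lambda_grid Penalty kind and smoothing grid for the
#'   re-estimation refits (see [reestimation_bic_path()]).
#' @return An object of class `disc_boost` with, among others, `trace`
#'   (tibble of per-iteration records), `m_stop`, `state` (the model state at
#'   `m_stop`), `sets` (final candidate sets) and, for the re-estimation
#'   rule, `reest` (the BIC path and the penalized refit at `m_stop`).
#' @examples
#' sim <- simulate_dsurv(scenario_spec("highdim", n = 150, P = 8, seed = 1))
#' fit <- disc_boost(sim$data, m_max = 25, stopping = "fixed", interactions = FALSE)
#' fit$trace
#' @export
disc_boost <- function(data, ..., K = 7, nu = 0.5, nu_gamma = 1, m_max = 500,
                       hierarchy = c("strong", "weak", "none"),
                       tv_hierarchy = FALSE, interactions = TRUE,
                       stopping = c("boosting_bic", "reestimation_bic", "fixed"),
                       hat_cap = 20000, hat_include_gamma = FALSE,
                       every = 5, penalty = "pspline",
                       lambda_grid = NULL) {
  hierarchy <- match.arg(hierarchy)
  stopping <- match.arg(stopping)
  stopifnot(nu > 0, nu <= 1, m_max >= 1)
  ds <- if (inherits(data, "dsurv")) data else as_dsurv(data, ...)
  basis <- time_basis(ds$grid, K = K)
  q <- ncol(basis$Bmat)
  n <- ds$n; P <- ds$P; S <- ds$S

  mask <- risk_mask(ds)
  Y <- pseudo_response(ds)
  riskcount <- colSums(mask)
  pre <- boost_precompute(ds, basis)
  sets <- candidate_sets(P, hierarchy)
  state <- model_state(S, P, q)
  eta <- matrix(0, n, S)

  use_hat <- stopping == "boosting_bic"
  if (use_hat) {
    fh <- fast_hat_init(ds, hat_cap)
    tmask <- t(mask)
    Tidx <- ds$time_index
  }

  inc_gamma <- matrix(0, m_max, S)
  terms <- vector("list", m_max)
  ll <- df <- bic <- rep(NA_real_, m_max)

  for (m in seq_len(m_max)) {
    lam <- stats::plogis(eta)
    U <- (Y - lam) * mask
    if (use_hat) w <- smaj_vec(lam * (1 - lam) * mask, tmask)

    # (c.1) baseline least-squares step
    gt <- ifelse(riskcount > 0, colSums(U) / pmax(riskcount, 1), 0)
    U <- U - mask * rep(gt, each = n)
    state$gamma <- state$gamma + nu_gamma * gt
    eta <- eta + rep(nu_gamma * gt, each = n)
    inc_gamma[m, ] <- gt

    # (c.2) term selection and update
    rss <- rss_all(U, pre, ds, basis, sets, state,
                   tv_hierarchy = tv_hierarchy, interactions = interactions)
    term <- pick_term(rss, P)
    state <- update_state(state, term, nu)
    eta <- eta + eta_increment(ds, basis, term, nu)
    terms[[m]] <- term

    # (c.3) candidate-set update
    sets <- update_candidates(sets, term)

    # degrees of freedom via the hat-matrix recursion
    if (use_hat) {
      if (hat_include_gamma) fast_hat_gamma(fh, w, S, nu_gamma)
      X <- term_design_columns(ds, basis, term)
      df[m] <- fast_hat_term(fh, w, X, nu)
    }

    ll[m] <- loglik_from_eta(eta, mask, Y)
    if (use_hat) bic[m] <- boosting_bic(ll[m], df[m], n)
  }

  trace <- tibble::tibble(
    m = seq_len(m_max),
    type = vapply(terms, function(t) t$type, character(1)),
    j = vapply(terms, function(t) as.integer(t$j), integer(1)),
    jp = vapply(terms, function(t) as.integer(t$jp), integer(1)),
    rss = vapply(terms, function(t) t$rss, numeric(1)),
    loglik = ll, df = df, bic = bic
  )

  fit <- structure(
    list(
      trace = trace, increments = list(gamma = inc_gamma, terms = terms),
      basis = basis, sets = sets, n = n, P = P, S = S, q = q,
      covariate_names = colnames(ds$Z),
      config = list(K = K, nu = nu, nu_gamma = nu_gamma, m_max = m_max,
                    hierarchy = hierarchy, tv_hierarchy = tv_hierarchy,
                    interactions = interactions, stopping = stopping,
                    every = every, penalty = penalty),
      state_mmax = state
    ),
    class = "disc_boost"
  )

  if (stopping == "boosting_bic") {
    fit$m_stop <- which.min(bic)
  } else if (stopping == "fixed") {
    fit$m_stop <- m_max
  } else {
    re <- reestimation_bic_path(ds, fit, every = every, penalty = penalty,
                                lambda_grid = lambda_grid)
    fit$reest <- re
    fit$m_stop <- re$m_stop
  }
  fit$state <- state_at(fit, fit$m_stop)
  fit
}

# eta contribution of one term increment, as an n x S matrix
eta_increment <- function(data, basis, term, nu) {
  if (term$type == "TI") {
    outer(nu * term$coef * data$Z[, term$j], rep(1, data$S))
  } else if (term$type == "INT") {
    outer(nu * term$coef * data$Z[, term$j] * data$Z[, term$jp], rep(1, data$S))
  } else {
    outer(data$Z[, term$j], drop(basis$Bmat %*% (nu * term$coef)))
  }
}

#' Reconstruct the boosting model state after m iterations
#'
#' @param fit A `disc_boost` object.
#' @param m Iteration count (0 gives the all-zero state).
#' @return A `model_state`.
#' @export
state_at <- function(fit, m) {
  stopifnot(m >= 0, m <= fit$config$m_max)
  state <- model_state(fit$S, fit$P, fit$q)
  nu <- fit$config$nu
  nu_gamma <- fit$config$nu_gamma
  if (m == 0) return(state)
  state$gamma <- nu_gamma * colSums(fit$increments$gamma[seq_len(m), , drop = FALSE])
  for (k in seq_len(m)) state <- update_state(state, fit$increments$terms[[k]], nu)
  state
}

#' Structure (selected term sets) after m iterations
#'
#' @param fit A `disc_boost` object.
#' @param m Iteration count; defaults to the stopping iteration.
#' @return List with integer vectors `phi` (covariates with a selected
#'   time-independent effect), `theta` (selected spline blocks) and a 2-column
#'   matrix `alpha` of selected interaction pairs.
#' @export
structure_at <- function(fit, m = fit$m_stop) {
  tr <- fit$trace[seq_len(m), ]
  phi <- sort(unique(tr$j[tr$type == "TI"]))
  theta <- sort(unique(tr$j[tr$type == "TV"]))
  ints <- unique(cbind(tr$j[tr$type == "INT"], tr$jp[tr$type == "INT"]))
  ints <- ints[order(ints[, 1], ints[, 2]), , drop = FALSE]
  colnames(ints) <- c("j", "jp")
  list(phi = phi, theta = theta, alpha = ints)
}

#' Selected covariate/interaction sets of a fitted object
#'
#' @param fit A `disc_boost` object.
#' @param m Iteration at which to read the selection (defaults to `m_stop`).
#' @return List with `ti_or_tv` (covariates with any selected main term),
#'   `tv` (covariates with a selected spline block) and `int` (2-column
#'   matrix of selected pairs).
#' @export
selected_sets <- function(fit, m = fit$m_stop) {
  st <- structure_at(fit, m)
  list(ti_or_tv = sort(union(st$phi, st$theta)), tv = st$theta, int = st$alpha)
}

#' @export
print.disc_boost <- function(x, ...) {
  cat("<disc_boost> component-wise boosting fit\n")
  cat("  n =", x$n, " P =", x$P, " S =", x$S, "\n")
  cat("  hierarchy:", x$config$hierarchy,
      " stopping:", x$config$stopping, "\n")
  cat("  m_stop =", x$m_stop, "of m_max =", x$config$m_max, "\n")
  sel <- selected_sets(x)
  cat("  selected: ", length(sel$ti_or_tv), " covariates (",
      length(sel$tv), " time-varying), ", nrow(sel$int), " interactions\n",
      sep = "")
  invisible(x)
}
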