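# Penalized Newton re-estimation of a selected model structure.
#
# The parameter vector omega = (gamma_1..gamma_S, phi over the selected
# time-independent set, theta blocks (K-1 each) over the selected
# time-varying set, alpha over the selected interaction pairs). Score and
# information are assembled from subject-by-interval arrays, exploiting that
# phi/alpha design columns are constant over a subject's intervals and theta
# columns factor as covariate x basis; no long-format table is built.

refit_layout <- function(S, structure, q) {
  np <- length(structure$phi)
  nv <- length(structure$theta)
  na <- if (is.null(structure$alpha)) 0L else nrow(structure$alpha)
  p <- S + np + nv * q + na
  list(
    S = S, q = q, np = np, nv = nv, na = na, p = p,
    idx_gamma = seq_len(S),
    idx_phi = S + seq_len(np),
    idx_theta = S + np + seq_len(nv * q),
    idx_alpha = S + np + nv * q + seq_len(na)
  )
}

refit_context <- function(data, basis, structure) {
  lay <- refit_layout(data$S, structure, ncol(basis$Bmat))
  Bq <- basis$Bmat
  BBf <- t(apply(Bq, 1, function(b) as.vector(tcrossprod(b)))) # S x q^2
  if (lay$q == 1) BBf <- matrix(BBf, nrow = data$S)
  list(
    lay = lay, data = data, basis = basis, structure = structure,
    Zphi = data$Z[, structure$phi, drop = FALSE],
    Ztv = data$Z[, structure$theta, drop = FALSE],
    Zint = if (lay$na > 0) {
      data$Z[, structure$alpha[, 1], drop = FALSE] *
        data$Z[, structure$alpha[, 2], drop = FALSE]
    } else matrix(0, data$n, 0),
    Bq = Bq, BBf = BBf,
    mask = risk_mask(data), Y = pseudo_response(data)
  )
}

ctx_eta <- function(omega, ctx) {
  lay <- ctx$lay
  n <- ctx$data$n
  eta <- matrix(omega[lay$idx_gamma], n, lay$S, byrow = TRUE)
  add <- numeric(n)
  if (lay$np > 0) add <- add + drop(ctx$Zphi %*% omega[lay$idx_phi])
  if (lay$na > 0) add <- add + drop(ctx$Zint %*% omega[lay$idx_alpha])
  eta <- eta + add
  if (lay$nv > 0) {
    Theta <- matrix(omega[lay$idx_theta], lay$nv, lay$q, byrow = TRUE)
    eta <- eta + ctx$Ztv %*% t(ctx$Bq %*% t(Theta))
  }
  eta
}

ctx_loglik <- function(omega, ctx) {
  eta <- ctx_eta(omega, ctx)
  loglik_from_eta(eta, ctx$mask, ctx$Y)
}

ctx_score <- function(omega, ctx) {
  lay <- ctx$lay
  eta <- ctx_eta(omega, ctx)
  U <- (ctx$Y - stats::plogis(eta)) * ctx$mask
  Ur <- rowSums(U)
  g <- numeric(lay$p)
  g[lay$idx_gamma] <- colSums(U)
  if (lay$np > 0) g[lay$idx_phi] <- drop(crossprod(ctx$Zphi, Ur))
  if (lay$nv > 0) {
    UB <- U %*% ctx$Bq
    g[lay$idx_theta] <- as.vector(t(crossprod(ctx$Ztv, UB)))
  }
  if (lay$na > 0) g[lay$idx_alpha] <- drop(crossprod(ctx$Zint, Ur))
  g
}

# Fisher information (= observed information under the canonical logit link)
ctx_information <- function(omega, ctx) {
  lay <- ctx$lay
  eta <- ctx_eta(omega, ctx)
  lam <- stats::plogis(eta)
  W <- lam * (1 - lam) * ctx$mask
  Wr <- rowSums(W)
  X1 <- cbind(ctx$Zphi, ctx$Zint)   # time-constant columns
  idx1 <- c(lay$idx_phi, lay$idx_alpha)
  I0 <- matrix(0, lay$p, lay$p)

  I0[cbind(lay$idx_gamma, lay$idx_gamma)] <- colSums(W)
  if (length(idx1) > 0) {
    tWX <- crossprod(W, X1)                         # S x p1
    I0[lay$idx_gamma, idx1] <- tWX
    I0[idx1, lay$idx_gamma] <- t(tWX)
    I11 <- crossprod(X1, Wr * X1)
    I0[idx1, idx1] <- I11
  }
  if (lay$nv > 0) {
    WB <- W %*% ctx$Bq                              # n x q
    WBB <- W %*% ctx$BBf                            # n x q^2
    for (v in seq_len(lay$nv)) {
      zv <- ctx$Ztv[, v]
      it <- lay$idx_theta[(v - 1) * lay$q + seq_len(lay$q)]
      blk_g <- drop(crossprod(W, zv)) * ctx$Bq      # S x q
      I0[lay$idx_gamma, it] <- blk_g
      I0[it, lay$idx_gamma] <- t(blk_g)
      if (length(idx1) > 0) {
        blk_1 <- crossprod(X1, zv * WB)             # p1 x q
        I0[idx1, it] <- blk_1
        I0[it, idx1] <- t(blk_1)
      }
      for (v2 in v:lay$nv) {
        it2 <- lay$idx_theta[(v2 - 1) * lay$q + seq_len(lay$q)]
        blk <- matrix(colSums(zv * ctx$Ztv[, v2] * WBB), lay$q, lay$q)
        I0[it, it2] <- blk
        if (v2 > v) I0[it2, it] <- t(blk)
      }
    }
  }
  I0
}

#' Penalty specification for the spline coefficient blocks
#'
#' Builds the quadratic roughness penalty matrix used in the penalized
#' log-likelihood \eqn{\ell(\omega) - \tfrac{\lambda}{2}\theta^\top S \theta}.
#' `"pspline"` penalizes squared second differences of each block's
#' coefficients; `"smoothing_spline"` uses the integrated squared second
#' derivative of the fitted coefficient curve, computed by composite Simpson
#' quadrature on 401 points over the grid range. The penalty acts only on the
#' theta blocks; baseline, time-independent and interaction coefficients are
#' unpenalized.
#'
#' @param basis A `time_basis`.
#' @param kind `"pspline"`, `"smoothing_spline"` or `"none"`.
#' @param lambda Smoothing parameter, `>= 0`.
#' @param structure Selected-terms list (see [structure_at()]).
#' @param S_times Number of distinct times (baseline parameters).
#' @return List of class `penalty_spec` with `kind`, `lambda` and `Smat`
#'   (full `p x p`, block-diagonal on the theta blocks, zero elsewhere).
#' @export
penalty_spec <- function(basis, kind = c("pspline", "smoothing_spline", "none"),
                         lambda = 0, structure, S_times) {
  kind <- match.arg(kind)
  stopifnot(lambda >= 0)
  lay <- refit_layout(S_times, structure, ncol(basis$Bmat))
  Smat <- matrix(0, lay$p, lay$p)
  if (kind != "none" && lay$nv > 0) {
    blk <- penalty_block(basis, kind)
    for (v in seq_len(lay$nv)) {
      it <- lay$idx_theta[(v - 1) * lay$q + seq_len(lay$q)]
      Smat[it, it] <- blk
    }
  }
  structure(list(kind = kind, lambda = lambda, Smat = Smat, lay = lay),
            class = "penalty_spec")
}

#' Per-block penalty matrix
#'
#' @inheritParams penalty_spec
#' @return A `(K-1) x (K-1)` symmetric positive semi-definite matrix.
#' @export
penalty_block <- function(basis, kind = c("pspline", "smoothing_spline")) {
  kind <- match.arg(kind)
  q <- ncol(basis$Bmat)
  if (kind == "pspline") {
    D <- diff(diag(q), differences = 2)
    return(crossprod(D))
  }
  # integrated squared second derivatives of the reduced basis functions
  npts <- 401
  x <- seq(basis$boundary[1], basis$boundary[2], length.out = npts)
  allknots <- c(rep(basis$boundary[1], basis$degree + 1), basis$knots,
                rep(basis$boundary[2], basis$degree + 1))
  D2 <- splines::splineDesign(allknots, x, ord = basis$degree + 1,
                              derivs = rep(2L, npts))[, -1, drop = FALSE]
  h <- (basis$boundary[2] - basis$boundary[1]) / (npts - 1)
  wq <- rep(c(2, 4), length.out = npts)
  wq[1] <- wq[npts] <- 1
  wq <- wq * h / 3
  crossprod(D2 * sqrt(wq))
}

#' Penalized log-likelihood
#'
#' @param omega Full parameter vector in the layout of [newton_fit()].
#' @param data A `dsurv` object.
#' @param basis A `time_basis`.
#' @param structure Selected-terms list.
#' @param pen A `penalty_spec`.
#' @return \eqn{\ell(\omega) - \tfrac{\lambda}{2}\,\theta^\top S\,\theta}.
#' @export
penalized_loglik <- function(omega, data, basis, structure, pen) {
  ctx <- refit_context(data, basis, structure)
  ctx_loglik(omega, ctx) - 0.5 * pen$lambda * drop(omega %*% pen$Smat %*% omega)
}

#' Score and information of the penalized log-likelihood
#'
#' @inheritParams penalized_loglik
#' @return List with `gradient` (of the penalized log-likelihood), `I0`
#'   (negative Hessian of the unpenalized log-likelihood) and
#'   `Ilambda = I0 + lambda * S`.
#' @export
score_and_information <- function(omega, data, basis, structure, pen) {
  ctx <- refit_context(data, basis, structure)
  g <- ctx_score(omega, ctx) - pen$lambda * drop(pen$Smat %*% omega)
  I0 <- ctx_information(omega, ctx)
  list(gradient = g, I0 = I0, Ilambda = I0 + pen$lambda * pen$Smat)
}

#' Penalized Newton fit of a selected model structure
#'
#' Maximizes the penalized log-likelihood by damped Newton iterations with an
#' Armijo backtracking line search on the step multiplier; convergence is
#' declared when the penalized score sup-norm falls below `tol`. A singular
#' information matrix receives a small ridge jitter (with a warning);
#' baseline parameters are clamped to [-30, 30], which absorbs time intervals
#' with no observed events (hazard below 1e-13, likelihood contribution
#' negligible).
#'
#' @param data A `dsurv` object.
#' @param basis A `time_basis` on the data grid.
#' @param structure List with `phi`, `theta` (integer covariate sets) and
#'   `alpha` (2-column pair matrix); see [structure_at()].
#' @param penalty Penalty kind (`"pspline"`, `"smoothing_spline"`, `"none"`).
#' @param lambda Smoothing parameter.
#' @param init Optional starting value for omega (default all zero).
#' @param tol Convergence tolerance on the penalized score sup-norm.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `disc_refit`: `omega`, `layout`, `structure`,
#'   `loglik`, `penalized_loglik`, `I0`, `Ilambda`, `converged`,
#'   `iterations`, `df_reest`, `bic_reest`, `tic`, `lambda`, `penalty`.
#' @export
newton_fit <- function(data, basis, structure, penalty = "none", lambda = 0,
                       init = NULL, tol = 1e-8, max_iter = 100) {
  if (penalty == "none") lambda <- 0
  pen <- penalty_spec(basis, if (lambda > 0) penalty else "none",
                      lambda = lambda, structure = structure, S_times = data$S)
  ctx <- refit_context(data, basis, structure)
  lay <- ctx$lay
  lamS <- pen$lambda * pen$Smat

  omega <- if (is.null(init)) numeric(lay$p) else init
  stopifnot(length(omega) == lay$p)
  pll <- ctx_loglik(omega, ctx) - 0.5 * drop(omega %*% lamS %*% omega)
  converged <- FALSE
  warned <- FALSE
  iter <- 0
  while (iter < max_iter) {
    g <- ctx_score(omega, ctx) - drop(lamS %*% omega)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    iter <- iter + 1
    I0 <- ctx_information(omega, ctx)
    Il <- I0 + lamS
    d <- tryCatch(solve(Il, g), error = function(e) NULL)
    if (is.null(d)) {
      if (!warned) {
        warning("singular information matrix; adding ridge jitter", call. = FALSE)
        warned <- TRUE
      }
      d <- solve(Il + diag(1e-8 * (1 + mean(diag(Il))), lay$p), g)
    }
    # Armijo backtracking on the step multiplier
    slope <- sum(g * d)
    step <- 1
    repeat {
      cand <- omega + step * d
      cand[lay$idx_gamma] <- pmin(pmax(cand[lay$idx_gamma], -30), 30)
      pll_new <- ctx_loglik(cand, ctx) - 0.5 * drop(cand %*% lamS %*% cand)
      if (is.finite(pll_new) && pll_new >= pll + 1e-4 * step * slope) break
      step <- step / 2
      if (step < 2^-30) break
    }
    if (pll_new <= pll && step < 2^-30) break  # no ascent possible
    omega <- cand
    pll <- pll_new
  }

  I0 <- ctx_information(omega, ctx)
  Il <- I0 + lamS
  ll <- ctx_loglik(omega, ctx)
  M <- tryCatch(solve(Il, I0), error = function(e)
    solve(Il + diag(1e-8 * (1 + mean(diag(Il))), lay$p), I0))
  df <- 2 * sum(diag(M)) - sum(M * t(M))
  structure(
    list(
      omega = omega, layout = lay, structure = structure, basis = basis,
      loglik = ll, penalized_loglik = pll, I0 = I0, Ilambda = Il,
      converged = converged, iterations = iter,
      df_reest = df, bic_reest = -2 * ll + log(data$n) * df,
      tic = -2 * ll + 2 * sum(diag(M)),
      lambda = lambda, penalty = penalty, n = data$n, P = data$P
    ),
    class = "disc_refit"
  )
}

#' @export
print.disc_refit <- function(x, ...) {
  cat("<disc_refit> penalized Newton fit\n")
  cat("  parameters:", x$layout$p, " loglik:", format(x$loglik), "\n")
  cat("  penalty:", x$penalty, " lambda:", x$lambda,
      " converged:", x$converged, "(", x$iterations, "iterations )\n")
  cat("  df:", format(x$df_reest), " BIC:", format(x$bic_reest), "\n")
  invisible(x)
}

#' Re-estimation degrees of freedom
#'
#' \eqn{\mathrm{df} = \mathrm{tr}(2 I_\lambda^{-1} I_0 -
#' I_0 I_\lambda^{-1} I_0 I_\lambda^{-1})}; equal to the parameter count at
#' \eqn{\lambda = 0}.
#'
#' @param I0 Negative Hessian of the unpenalized log-likelihood.
#' @param Ilambda `I0 + lambda * S`; must be invertible.
#' @export
reestimation_df <- function(I0, Ilambda) {
  M <- solve(Ilambda, I0)
  2 * sum(diag(M)) - sum(M * t(M))
}

#' Smoothing-parameter selection by TIC
#'
#' Fits the selected structure at every value of the grid and returns the
#' minimizer of \eqn{\mathrm{TIC} = -2\ell(\hat\omega_\lambda) +
#' 2\,\mathrm{tr}(I_\lambda^{-1} I_0)}; at \eqn{\lambda = 0} the trace term
#' is the parameter count. Fits are warm-started along the grid.
#'
#' @inheritParams newton_fit
#' @param lambda_grid Candidate smoothing values (default
#'   `c(0, 10^seq(-3, 3, by = 0.5))`).
#' @return List with `lambda`, `fit` (the selected `disc_refit`) and `path`
#'   (tibble of lambda, TIC, loglik).
#' @export
tic_select_lambda <- function(data, basis, structure, penalty = "pspline",
                              lambda_grid = c(0, 10^seq(-3, 3, by = 0.5)),
                              init = NULL) {
  stopifnot(length(lambda_grid) >= 1)
  if (length(structure$theta) == 0 || penalty == "none") lambda_grid <- 0
  fits <- vector("list", length(lambda_grid))
  last <- init
  for (i in seq_along(lambda_grid)) {
    fits[[i]] <- newton_fit(data, basis, structure, penalty = penalty,
                            lambda = lambda_grid[i], init = last)
    last <- fits[[i]]$omega
  }
  tics <- vapply(fits, function(f) f$tic, numeric(1))
  best <- which.min(tics)
  list(lambda = lambda_grid[best], fit = fits[[best]],
       path = tibble::tibble(lambda = lambda_grid, tic = tics,
                             loglik = vapply(fits, function(f) f$loglik, numeric(1))))
}

#' Re-estimation BIC stopping path
#'
#' Walks the boosting trace, refitting the structure selected by iteration
#' `m` for `m = every, 2*every, ..., m_max` (penalized Newton, smoothing by
#' TIC), and computes \eqn{-2\ell + \log(n)\,\mathrm{df}} with the
#' information-based degrees of freedom. Consecutive iterations with an
#' unchanged structure share one refit. Returns the BIC-minimizing iteration
#' and its fit.
#'
#' @param data A `dsurv` object.
#' @param boost_fit A `disc_boost` object (or its trace).
#' @param every Evaluation stride (default 5).
#' @param penalty Penalty kind for the refits.
#' @param lambda_grid Smoothing grid for TIC (default `c(0, 0.1, 1, 10, 100)`,
#'   a coarse grid that keeps the path cheap; pass the full grid for final
#'   estimates).
#' @return List with `path` (tibble `m`, `bic`, `df`, `lambda`, `p`),
#'   `m_stop`, `structure` and `fit` (the refit at `m_stop`).
#' @export
reestimation_bic_path <- function(data, boost_fit, every = 5,
                                  penalty = "pspline", lambda_grid = NULL) {
  if (is.null(lambda_grid)) lambda_grid <- c(0, 0.1, 1, 10, 100)
  m_max <- boost_fit$config$m_max
  basis <- boost_fit$basis
  ms <- unique(c(seq(every, m_max, by = every), m_max))
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(ms))
  for (i in seq_along(ms)) {
    st <- structure_at(boost_fit, ms[i])
    key <- paste(c(st$phi, -1, st$theta, -1, t(st$alpha)), collapse = ",")
    if (is.null(cache[[key]])) {
      sel <- tic_select_lambda(data, basis, st, penalty = penalty,
                               lambda_grid = lambda_grid)
      cache[[key]] <- sel
    }
    sel <- cache[[key]]
    rows[[i]] <- tibble::tibble(m = ms[i], bic = sel$fit$bic_reest,
                                df = sel$fit$df_reest, lambda = sel$lambda,
                                p = sel$fit$layout$p, key = key)
  }
  path <- dplyr::bind_rows(rows)
  best <- which.min(path$bic)
  st <- structure_at(boost_fit, path$m[best])
  list(path = dplyr::select(path, -"key"), m_stop = path$m[best],
       structure = st, fit = cache[[path$key[best]]]$fit,
       lambda = path$lambda[best])
}

#' Convert a penalized refit to a full model state
#'
#' @param fit A `disc_refit`.
#' @param P Total number of covariates.
#' @return A `model_state` with the refit coefficients placed in the selected
#'   positions and zeros elsewhere.
#' @export
refit_state <- function(fit, P = fit$P) {
  lay <- fit$layout
  st <- fit$structure
  state <- model_state(lay$S, P, lay$q)
  state$gamma <- fit$omega[lay$idx_gamma]
  if (lay$np > 0) state$phi[st$phi] <- fit$omega[lay$idx_phi]
  if (lay$nv > 0) {
    state$theta[st$theta, ] <- matrix(fit$omega[lay$idx_theta],
                                      lay$nv, lay$q, byrow = TRUE)
  }
  if (lay$na > 0) {
    state$alpha <- cbind(st$alpha, value = fit$omega[lay$idx_alpha])
    colnames(state$alpha) <- c("j", "jp", "value")
  }
  state
}

#' Hazard-ratio curve with delta-method confidence band
#'
#' Point estimate \eqn{\exp\{f(t_s; z_1) - f(t_s; z_0)\}} per grid time (the
#' covariate effects are log odds ratios under the logit link), with a
#' normal-theory interval from the contrast variance
#' \eqn{c_s^\top I_\lambda^{-1} c_s}. The interval is conditional on the
#' selected model.
#'
#' @param fit A `disc_refit`.
#' @param z1,z0 Full-length covariate vectors to contrast.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `time`, `estimate`, `lo`, `hi`, `se_log`.
#' @export
hazard_ratio_curve <- function(fit, z1, z0, level = 0.95) {
  lay <- fit$layout
  st <- fit$structure
  basis <- fit$basis
  stopifnot(length(z1) == fit$P, length(z0) == fit$P)
  Iinv <- robust_inverse(fit$Ilambda)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  S <- lay$S
  out <- matrix(0, S, 2)
  dz <- z1 - z0
  for (s in seq_len(S)) {
    cs <- numeric(lay$p)
    if (lay$np > 0) cs[lay$idx_phi] <- dz[st$phi]
    if (lay$nv > 0) {
      cs[lay$idx_theta] <- as.vector(t(outer(dz[st$theta], basis$Bmat[s, ])))
    }
    if (lay$na > 0) {
      cs[lay$idx_alpha] <- z1[st$alpha[, 1]] * z1[st$alpha[, 2]] -
        z0[st$alpha[, 1]] * z0[st$alpha[, 2]]
    }
    est <- sum(cs * fit$omega)
    se <- sqrt(pmax(drop(cs %*% Iinv %*% cs), 0))
    out[s, ] <- c(est, se)
  }
  tibble::tibble(time = basis$grid,
                 estimate = exp(out[, 1]),
                 lo = exp(out[, 1] - zq * out[, 2]),
                 hi = exp(out[, 1] + zq * out[, 2]),
                 se_log = out[, 2])
}


# inverse with a ridge fallback for information matrices whose baseline rows
# vanish (time intervals with empty risk sets)
robust_inverse <- function(A) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(out)) {
    out <- solve(A + diag(1e-8 * (1 + mean(diag(A))), nrow(A)))
  }
  out
}
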