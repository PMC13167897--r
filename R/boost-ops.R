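# Component operations of the boosting procedure. Each takes the masked
# n x S gradient matrix U (zero outside at-risk cells) and works in closed
# form; the main loop in disc_boost() uses vectorized equivalents of the same
# formulas, which the test suite cross-checks against these.

#' Least-squares baseline update
#'
#' The minimizer of \eqn{\sum_i \sum_{s \le T_i} (U_{is} - \gamma_s)^2} is the
#' per-time mean of the gradient over the risk set; times with an empty risk
#' set get 0.
#'
#' @param U Masked `n x S` gradient matrix.
#' @param data A `dsurv` object.
#' @return Length-`S` numeric vector of baseline increments.
#' @export
baseline_ls <- function(U, data) {
  r <- colSums(risk_mask(data))
  g <- colSums(U)
  ifelse(r > 0, g / pmax(r, 1), 0)
}

#' Apply a baseline increment to the state and gradient
#'
#' Adds `nu_gamma * gamma_tilde` to the baseline coefficients and subtracts
#' `gamma_tilde` from the gradient on at-risk cells, after which the per-time
#' risk-set means of `U` are zero.
#'
#' @param state A `model_state`.
#' @param U Masked gradient matrix.
#' @param gamma_tilde Output of [baseline_ls()].
#' @param nu_gamma Baseline step size (default 1).
#' @param data A `dsurv` object.
#' @return List with updated `state` and `U`.
#' @export
apply_baseline <- function(state, U, gamma_tilde, nu_gamma = 1, data) {
  state$gamma <- state$gamma + nu_gamma * gamma_tilde
  U <- U - risk_mask(data) * rep(gamma_tilde, each = nrow(U))
  list(state = state, U = U)
}

#' Closed-form least-squares fit of the gradient to one term
#'
#' For a time-independent or interaction term the design column is constant
#' over a subject's at-risk intervals and the fit is the univariate
#' least-squares slope; for a time-varying term the (K-1) spline-basis
#' columns scale the covariate and the fit solves the corresponding normal
#' equations.
#'
#' @param U Masked `n x S` gradient matrix.
#' @param data A `dsurv` object.
#' @param basis A `time_basis`.
#' @param term List with `type` in `"TI"`, `"TV"`, `"INT"`, covariate `j`
#'   (and `jp` for interactions).
#' @return List with `coef` (scalar, or length `K-1` for TV) and `rss`; for a
#'   singular time-varying cross-product the term is reported unusable
#'   (`rss = Inf`) with a warning.
#' @export
group_ls_fit <- function(U, data, basis, term) {
  Tidx <- data$time_index
  SSU <- sum(U * U)
  if (term$type %in% c("TI", "INT")) {
    x <- if (term$type == "TI") data$Z[, term$j] else data$Z[, term$j] * data$Z[, term$jp]
    den <- sum(Tidx * x^2)
    if (den <= 0) {
      warning("degenerate design column for term; skipped", call. = FALSE)
      return(list(coef = 0, rss = Inf))
    }
    num <- sum(x * rowSums(U))
    coef <- num / den
    return(list(coef = coef, rss = SSU - num^2 / den))
  }
  # TV: normal equations sum_i x_i^2 M_{T_i} theta = sum_i x_i B^T U_i
  x <- data$Z[, term$j]
  Bq <- basis$Bmat
  q <- ncol(Bq)
  A <- matrix(0, q, q)
  Mc <- matrix(0, q, q)
  x2T <- rowsum_by_time(x^2, Tidx, data$S)
  for (s in seq_len(data$S)) {
    Mc <- Mc + tcrossprod(Bq[s, ])
    A <- A + x2T[s] * Mc
  }
  b <- drop(crossprod(U %*% Bq, x))
  coef <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(coef)) {
    warning("singular time-varying cross-product for covariate ", term$j,
            "; term skipped", call. = FALSE)
    return(list(coef = rep(0, q), rss = Inf))
  }
  list(coef = coef, rss = SSU - sum(b * coef))
}

rowsum_by_time <- function(v, Tidx, S) {
  out <- numeric(S)
  agg <- rowsum(v, Tidx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Select the best-fitting term
#'
#' Computes the least-squares residual sum of squares of the gradient for
#' every eligible time-independent term, time-varying term (restricted to
#' covariates with a non-zero time-independent effect when `tv_hierarchy` is
#' set) and interaction pair in the eligible set, and returns the minimizer.
#' Exact ties are broken by category (TI before TV before INT), then lowest
#' index.
#'
#' @param U Masked gradient matrix.
#' @param data A `dsurv` object.
#' @param basis A `time_basis`.
#' @param sets A `candidate_sets` object.
#' @param state Current `model_state` (used by the time-varying hierarchy).
#' @param tv_hierarchy Logical; require `phi_j != 0` before the spline block
#'   of covariate `j` becomes eligible.
#' @param interactions Logical; include interaction candidates at all.
#' @return List with `type`, `j`, `jp` (NA unless interaction), `coef`,
#'   `rss`.
#' @export
select_term <- function(U, data, basis, sets, state = NULL,
                        tv_hierarchy = FALSE, interactions = TRUE) {
  pre <- boost_precompute(data, basis)
  rss <- rss_all(U, pre, data, basis, sets, state,
                 tv_hierarchy = tv_hierarchy, interactions = interactions)
  pick_term(rss, data$P)
}

# shared selection bookkeeping: rss is list(ti, tv, int, pairs, phi_t, theta_t, a_t)
pick_term <- function(rss, P) {
  allr <- unname(c(rss$ti, rss$tv, rss$int))
  if (all(!is.finite(allr))) stop("no eligible term has a usable fit", call. = FALSE)
  k <- which.min(allr)  # first minimum: TI block, then TV, then INT (lexicographic)
  if (k <= P) {
    list(type = "TI", j = k, jp = NA_integer_, coef = rss$phi_t[k], rss = rss$ti[k])
  } else if (k <= 2 * P) {
    j <- k - P
    list(type = "TV", j = j, jp = NA_integer_, coef = rss$theta_t[j, ], rss = rss$tv[j])
  } else {
    i <- k - 2 * P
    list(type = "INT", j = rss$pairs[i, 1], jp = rss$pairs[i, 2],
         coef = rss$a_t[i], rss = rss$int[i])
  }
}

#' Apply a selected term's increment to the model state
#'
#' Only the parameters of the selected term change, each moved by `nu` times
#' its least-squares estimate (the whole spline coefficient block for a
#' time-varying term).
#'
#' @param state A `model_state`.
#' @param term Output of [select_term()].
#' @param nu Step size in (0, 1].
#' @return The updated `model_state`.
#' @export
update_state <- function(state, term, nu) {
  if (term$type == "TI") {
    state$phi[term$j] <- state$phi[term$j] + nu * term$coef
  } else if (term$type == "TV") {
    state$theta[term$j, ] <- state$theta[term$j, ] + nu * term$coef
  } else {
    a <- state$alpha
    hit <- which(a[, "j"] == term$j & a[, "jp"] == term$jp)
    if (length(hit) == 1) {
      a[hit, "value"] <- a[hit, "value"] + nu * term$coef
    } else {
      a <- rbind(a, c(term$j, term$jp, nu * term$coef))
    }
    state$alpha <- a
  }
  state
}

#' Boosting BIC
#'
#' \eqn{-2\ell + \log(n)\,\mathrm{df}}, with `n` the number of subjects (not
#' pseudo-observations).
#'
#' @param loglik Log-likelihood at the current iteration.
#' @param df Degrees of freedom (trace of the approximate hat matrix, or the
#'   re-estimation degrees of freedom).
#' @param n Number of subjects.
#' @export
boosting_bic <- function(loglik, df, n) {
  stopifnot(df >= 0)
  -2 * loglik + log(n) * df
}
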