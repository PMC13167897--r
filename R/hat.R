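# Approximate hat-matrix recursion for the boosting degrees of freedom:
#   B_1 = nu W^{[0]} H^{g_1},
#   B_m = B_{m-1} + nu W^{[m-1]} H^{g_m} (I - B_{m-1}),
# with H^g the least-squares projection onto the pseudo-observation design
# columns of the selected term and W the diagonal logistic working weights
# lambda(1-lambda) at the current fit. df(m) = trace(B_m). Only the selected
# term's projection enters the recursion; composing the baseline step's
# projection (per-time indicator block) as well is available as an option.
# The reference implementation below is plain dense R; disc_boost() uses the
# C++ kernels in src/ that maintain the transposed matrix in single
# precision with cache-friendly column updates.

#' Initialize the hat-matrix state
#'
#' @param data A `dsurv` object.
#' @param cap Refuse the dense `N x N` computation when the pseudo-observation
#'   count exceeds this cap (default 20000); the re-estimation BIC stopping
#'   rule has no such limit.
#' @return List with `B` (`N x N` zero matrix), `grp` (time index per
#'   pseudo-observation, subject-major) and `N`.
#' @export
hat_state <- function(data, cap = 20000) {
  N <- sum(data$time_index)
  if (N > cap) {
    stop("pseudo-observation count N = ", N, " exceeds the hat-matrix cap (",
         cap, "); use the re-estimation BIC stopping rule instead",
         call. = FALSE)
  }
  list(B = matrix(0, N, N), grp = smaj_time(data$time_index), N = N,
       S = data$S)
}

#' One hat-matrix recursion step for a selected term
#'
#' @param hm Hat state from [hat_state()].
#' @param w Working weights per pseudo-observation (subject-major).
#' @param X Design column(s) of the selected term on the pseudo-observations
#'   (see the term design helper used by [disc_boost()]), `N x q`.
#' @param nu Step size.
#' @return Updated hat state with `df = trace(B)`.
#' @export
hat_matrix_update <- function(hm, w, X, nu) {
  X <- as.matrix(X)
  H_IB <- X %*% solve(crossprod(X), crossprod(X, diag(hm$N) - hm$B))
  hm$B <- hm$B + nu * (w * H_IB)
  hm$df <- sum(diag(hm$B))
  hm
}

#' One hat-matrix recursion step for the baseline update
#'
#' The baseline least-squares fit projects onto the per-time indicator
#' columns; its projection applied to a matrix takes risk-set means by time.
#'
#' @inheritParams hat_matrix_update
#' @param nu_gamma Baseline step size.
#' @export
hat_baseline_update <- function(hm, w, nu_gamma = 1) {
  M <- diag(hm$N) - hm$B
  G <- rowsum(M, hm$grp) / as.vector(table(factor(hm$grp, levels = seq_len(hm$S))))
  hm$B <- hm$B + nu_gamma * (w * G[hm$grp, , drop = FALSE])
  hm$df <- sum(diag(hm$B))
  hm
}

# --- fast path: transposed single-precision storage behind an external
# pointer, updated in place by the C++ kernels -----------------------------

fast_hat_init <- function(data, cap) {
  N <- sum(data$time_index)
  if (N > cap) {
    stop("pseudo-observation count N = ", N, " exceeds the hat-matrix cap (",
         cap, "); use the re-estimation BIC stopping rule instead",
         call. = FALSE)
  }
  list(ptr = hat_alloc_cpp(N),
       grp = as.integer(smaj_time(data$time_index)),
       N = N)
}

fast_hat_gamma <- function(fh, w, S, nu_gamma) {
  hat_gamma_cpp(fh$ptr, w, fh$grp, S, nu_gamma)
}

fast_hat_term <- function(fh, w, X, nu) {
  hat_term_cpp(fh$ptr, w, as.matrix(X), nu)
}
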