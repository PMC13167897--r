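#' Model state for the discrete logistic hazard model
#'
#' Holds the full coefficient set of the hazard
#' \deqn{\lambda(t_s; z) = \mathrm{expit}\{\gamma_s + \sum_j \phi_j z_j +
#'   \sum_j \theta_j^\top B(t_s) z_j + \sum_{j<j'} \alpha_{jj'} z_j z_{j'}\}}
#' with `gamma` the logit-scale baseline per time, `phi` time-independent
#' effects, `theta` the reduced-spline coefficient blocks (one row per
#' covariate), and `alpha` a sparse set of two-way interaction coefficients.
#'
#' @param S Number of distinct times.
#' @param P Number of covariates.
#' @param q Number of reduced-basis columns (`K - 1`).
#' @param gamma,phi,theta Optional initial values (default all zero).
#' @param alpha Optional interaction set: a 3-column matrix `(j, jp, value)`
#'   with `j < jp`, or NULL for none.
#' @return An object of class `model_state`.
#' @export
model_state <- function(S, P, q, gamma = NULL, phi = NULL, theta = NULL,
                        alpha = NULL) {
  if (is.null(gamma)) gamma <- numeric(S)
  if (is.null(phi)) phi <- numeric(P)
  if (is.null(theta)) theta <- matrix(0, P, q)
  if (is.null(alpha)) {
    alpha <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("j", "jp", "value")))
  } else {
    alpha <- as.matrix(alpha)
    colnames(alpha) <- c("j", "jp", "value")
    if (nrow(alpha) > 0 && any(alpha[, 1] >= alpha[, 2])) {
      stop("interaction keys must satisfy j < j'", call. = FALSE)
    }
  }
  stopifnot(length(gamma) == S, length(phi) == P,
            nrow(theta) == P, ncol(theta) == q)
  structure(list(gamma = gamma, phi = phi, theta = theta, alpha = alpha,
                 S = S, P = P, q = q),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  cat("<model_state>\n")
  cat("  baseline gamma: length", x$S, "\n")
  cat("  phi non-zero:", sum(x$phi != 0), "of", x$P, "\n")
  cat("  theta non-zero blocks:", sum(rowSums(x$theta != 0) > 0), "of", x$P, "\n")
  cat("  interactions:", if (nrow(x$alpha)) sum(x$alpha[, "value"] != 0) else 0, "\n")
  invisible(x)
}

# interaction coefficients as a dense lookup helper
alpha_pairs <- function(state) {
  a <- state$alpha
  a[a[, "value"] != 0, , drop = FALSE]
}

#' Linear predictor over the subject-by-interval array
#'
#' Returns the `n x S` matrix of \eqn{\eta_{is} = \gamma_s + f(t_s; Z_i)}
#' evaluated at every grid time (entries beyond a subject's observed time are
#' computed but ignored by all likelihood code, which applies the at-risk
#' mask).
#'
#' @param state A `model_state`.
#' @param data A `dsurv` object.
#' @param basis A `time_basis` whose grid matches `data$grid`.
#' @return Numeric `n x S` matrix.
#' @export
linear_predictor <- function(state, data, basis) {
  check_dims(state, data, basis)
  n <- data$n; S <- data$S
  eta <- matrix(state$gamma, n, S, byrow = TRUE)
  nz <- which(state$phi != 0)
  if (length(nz) > 0) {
    eta <- eta + drop(data$Z[, nz, drop = FALSE] %*% state$phi[nz])
  }
  tvrows <- which(rowSums(state$theta != 0) > 0)
  if (length(tvrows) > 0) {
    # beta_j(t_s) contribution: Z_tv %*% t(Bmat %*% t(theta_tv))
    curves <- basis$Bmat %*% t(state$theta[tvrows, , drop = FALSE]) # S x ntv
    eta <- eta + data$Z[, tvrows, drop = FALSE] %*% t(curves)
  }
  ap <- alpha_pairs(state)
  if (nrow(ap) > 0) {
    zz <- data$Z[, ap[, "j"], drop = FALSE] * data$Z[, ap[, "jp"], drop = FALSE]
    eta <- eta + drop(zz %*% ap[, "value"])
  }
  eta
}

check_dims <- function(state, data, basis) {
  if (state$S != data$S || state$P != data$P) {
    stop("model_state dimensions do not match the data", call. = FALSE)
  }
  if (state$q != ncol(basis$Bmat) || length(basis$grid) != data$S) {
    stop("basis dimensions do not match the data/state", call. = FALSE)
  }
  invisible(TRUE)
}

#' Discrete hazard (inverse logit), numerically stable
#'
#' @param eta Linear predictor value(s).
#' @return `expit(eta)` in (0, 1); saturates without overflow for large `|eta|`.
#' @examples
#' hazard(0)        # 0.5
#' hazard(log(3))   # 0.75
#' @export
hazard <- function(eta) stats::plogis(eta)

# stable log(1 + exp(x))
softplus <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

#' Log-likelihood of the discrete logistic hazard model
#'
#' Streams over subjects and at-risk intervals (the Bernoulli form of the
#' product likelihood): \eqn{\ell = \sum_i \sum_{s \le T_i} [y_{is}\eta_{is}
#' - \log(1 + e^{\eta_{is}})]}.
#'
#' @inheritParams linear_predictor
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(state, data, basis) {
  eta <- linear_predictor(state, data, basis)
  mask <- risk_mask(data)
  Y <- pseudo_response(data)
  sum((Y * eta - softplus(eta))[mask])
}

loglik_from_eta <- function(eta, mask, Y) {
  sum((Y * eta - softplus(eta))[mask])
}

#' Gradient of the log-likelihood in the linear predictor
#'
#' Returns the `n x S` matrix with entries \eqn{U_{is} = y_{is} -
#' \mathrm{expit}(\eta_{is})} on at-risk cells and 0 elsewhere.
#'
#' @inheritParams linear_predictor
#' @return Numeric `n x S` matrix (masked outside at-risk cells).
#' @export
gradient_eta <- function(state, data, basis) {
  eta <- linear_predictor(state, data, basis)
  mask <- risk_mask(data)
  Y <- pseudo_response(data)
  (Y - stats::plogis(eta)) * mask
}

#' Model-based survival curve for a covariate vector
#'
#' \eqn{S(t_s; z) = \prod_{\ell \le s} \{1 - \lambda(t_\ell; z)\}}.
#'
#' @param state A `model_state`.
#' @param z Numeric covariate vector of length `P`.
#' @param basis A `time_basis` on the model grid.
#' @return Tibble with columns `time`, `hazard`, `survival`.
#' @export
survival_curve <- function(state, z, basis) {
  stopifnot(length(z) == state$P)
  f <- covariate_effect(state, z, basis)
  lam <- stats::plogis(state$gamma + f)
  tibble::tibble(time = basis$grid, hazard = lam, survival = cumprod(1 - lam))
}

# f(t_s; z) over the grid for one covariate vector
covariate_effect <- function(state, z, basis) {
  f <- rep(sum(state$phi * z), state$S)
  tvrows <- which(rowSums(state$theta != 0) > 0)
  if (length(tvrows) > 0) {
    curves <- basis$Bmat %*% t(state$theta[tvrows, , drop = FALSE])
    f <- f + drop(curves %*% z[tvrows])
  }
  ap <- alpha_pairs(state)
  if (nrow(ap) > 0) {
    f <- f + sum(ap[, "value"] * z[ap[, "j"]] * z[ap[, "jp"]])
  }
  f
}
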