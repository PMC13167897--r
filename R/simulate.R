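#' Simulation scenario specification
#'
#' Describes a data-generating mechanism for discrete-time survival data:
#' AR(1) Gaussian covariates (optionally dichotomized), a discrete logistic
#' hazard with true coefficient functions evaluated at the grid times, and
#' discrete-uniform censoring.
#'
#' Two presets reproduce the package's reference experiments:
#' * `"highdim"`: S = 19 grid times, five non-zero coefficient functions
#'   `beta_1(t) = 1`, `beta_2(t) = cos(pi t / 50)`, `beta_3(t) = -1`,
#'   `beta_4(t) = sin(3 pi t / 80)`, `beta_5(t) = -1 + exp(-0.25 t)`, all
#'   remaining covariates null, no interactions; defaults n = 500, P = 100.
#' * `"interaction"`: S = 20 grid times, five time-varying coefficients
#'   `1 + cos(pi t/50)`, `-1 + exp(-0.25 t)`, `1 - cos(pi t/30)`,
#'   `sin(3 pi t/80)`, `-sin(pi t/30)`, ten time-independent effects
#'   `(-1,-1,-1,1,1,1,1,0,0,0)`, and interactions
#'   `z1 z2, z1 z3, z1 z9, z5 z10, z6 z7` with coefficients
#'   `(1, 1, 1, -1, -1)`; defaults n = 1000, P = 15.
#'
#' Grid times are `t_s = s`. Censoring is DiscreteUniform on `1..S` unless
#' `censor_support` says otherwise; subjects event-free at `S` are censored.
#'
#' @param name `"highdim"`, `"interaction"` or `"custom"`.
#' @param n,P Sample size and covariate count.
#' @param rho AR(1) autocorrelation of the latent Gaussian covariates
#'   (default 0.5).
#' @param binary If `TRUE`, covariate `j` is dichotomized at the
#'   `p0_j`-quantile of its latent Gaussian, with zero-probabilities `p0_j`
#'   equally spaced over \[0.05, 0.15\] across covariates.
#' @param gamma_true Length-`S` logit-scale baseline (presets supply theirs).
#' @param beta_funs List of `P` coefficient functions of time (constants
#'   allowed); presets supply theirs, padded with zero functions.
#' @param alpha_true 3-column matrix `(j, jp, value)` of true interactions.
#' @param censor_support Integer support of the censoring distribution
#'   (default `1:S`).
#' @param seed Integer seed (stored; [simulate_dsurv()] sets it).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("highdim", "interaction", "custom"),
                          n = NULL, P = NULL, rho = 0.5, binary = FALSE,
                          gamma_true = NULL, beta_funs = NULL,
                          alpha_true = NULL, censor_support = NULL,
                          seed = NULL) {
  name <- match.arg(name)
  if (name == "highdim") {
    if (is.null(n)) n <- 500
    if (is.null(P)) P <- 100
    if (is.null(gamma_true)) {
      gamma_true <- c(-4.00, -3.50, -3.20, -3.12, -3.08, -3.00, -2.95, -2.87,
                      -2.80, -2.69, -2.61, -2.49, -2.39, -2.25, -2.10, -1.90,
                      -1.70, -1.35, -1.00)
    }
    lib <- true_beta_library("highdim")
    if (is.null(beta_funs)) beta_funs <- pad_beta(lib$beta, P)
    if (is.null(alpha_true)) alpha_true <- empty_alpha()
  } else if (name == "interaction") {
    if (is.null(n)) n <- 1000
    if (is.null(P)) P <- 15
    if (is.null(gamma_true)) {
      gamma_true <- c(-4.3, -4.05, -3.8, -3.5, -3.12, -2.78, -2.32, -2.12,
                      -1.99, -1.8, -1.69, -1.61, -1.49, -1.39, -1.25, -1.1,
                      -0.9, -0.7, -0.35, 0)
    }
    lib <- true_beta_library("interaction")
    if (is.null(beta_funs)) beta_funs <- pad_beta(lib$beta, P)
    if (is.null(alpha_true)) {
      alpha_true <- lib$alpha[lib$alpha[, 2] <= P, , drop = FALSE]
    }
  } else {
    stopifnot(!is.null(n), !is.null(P), !is.null(gamma_true),
              !is.null(beta_funs))
    if (is.null(alpha_true)) alpha_true <- empty_alpha()
  }
  S <- length(gamma_true)
  stopifnot(length(beta_funs) == P, abs(rho) < 1, n >= 1, P >= 1)
  if (nrow(alpha_true) > 0 && any(alpha_true[, 1] >= alpha_true[, 2])) {
    stop("alpha_true keys must satisfy j < j'", call. = FALSE)
  }
  if (is.null(censor_support)) censor_support <- seq_len(S)
  structure(
    list(name = name, n = n, P = P, rho = rho, binary = binary,
         gamma_true = gamma_true, beta_funs = beta_funs,
         alpha_true = alpha_true, times = seq_len(S), S = S,
         censor_support = as.integer(censor_support), seed = seed),
    class = "scenario_spec"
  )
}

empty_alpha <- function() {
  matrix(numeric(0), 0, 3, dimnames = list(NULL, c("j", "jp", "value")))
}

pad_beta <- function(beta, P) {
  if (P <= length(beta)) return(beta[seq_len(P)])
  c(beta, rep(list(function(t) rep(0, length(t))), P - length(beta)))
}

#' Reference libraries of true coefficient functions
#'
#' @param name `"highdim"` or `"interaction"`.
#' @return List with `beta` (list of functions of time) and, for the
#'   interaction design, `alpha` (3-column matrix of true pairs).
#' @export
true_beta_library <- function(name = c("highdim", "interaction")) {
  name <- match.arg(name)
  if (name == "highdim") {
    list(beta = list(
      function(t) rep(1, length(t)),
      function(t) cos(pi * t / 50),
      function(t) rep(-1, length(t)),
      function(t) sin(3 * pi * t / 80),
      function(t) -1 + exp(-0.25 * t)
    ), alpha = empty_alpha())
  } else {
    beta_tv <- list(
      function(t) 1 + cos(pi * t / 50),
      function(t) -1 + exp(-0.25 * t),
      function(t) 1 - cos(pi * t / 30),
      function(t) sin(3 * pi * t / 80),
      function(t) -sin(pi * t / 30)
    )
    ti <- c(-1, -1, -1, 1, 1, 1, 1, 0, 0, 0)
    beta_ti <- lapply(ti, function(v) {
      force(v)
      function(t) rep(v, length(t))
    })
    alpha <- cbind(j = c(1, 1, 1, 5, 6), jp = c(2, 3, 9, 10, 7),
                   value = c(1, 1, 1, -1, -1))
    list(beta = c(beta_tv, beta_ti), alpha = alpha)
  }
}

#' Generate AR(1) covariates
#'
#' Rows are i.i.d. `N(0, Sigma)` with `Sigma_jk = rho^|j-k|`, built by the
#' exact autoregressive recursion. With `binary = TRUE`, covariate `j` is
#' dichotomized at the `p0_j` quantile of the latent Gaussian (preserving the
#' dependence), with `p0_j` equally spaced over \[0.05, 0.15\].
#'
#' @param n,P Dimensions.
#' @param rho AR(1) parameter, `|rho| < 1`.
#' @param binary Dichotomize (0/1 coding)?
#' @return `n x P` numeric matrix with columns `z1..zP`.
#' @export
gen_covariates <- function(n, P, rho = 0.5, binary = FALSE) {
  Z <- matrix(stats::rnorm(n * P), n, P)
  if (P > 1 && rho != 0) {
    sc <- sqrt(1 - rho^2)
    for (j in 2:P) Z[, j] <- rho * Z[, j - 1] + sc * Z[, j]
  }
  if (binary) {
    p0 <- if (P == 1) 0.10 else seq(0.05, 0.15, length.out = P)
    thr <- stats::qnorm(p0)
    Z <- sweep(Z, 2, thr, ">") + 0
  }
  colnames(Z) <- paste0("z", seq_len(P))
  Z
}

#' True hazard matrix under a scenario
#'
#' \eqn{\lambda_{is} = \mathrm{expit}\{\gamma_s + \sum_j \beta_j(t_s) z_{ij}
#' + \sum \alpha_{jj'} z_{ij} z_{ij'}\}}, with the exact coefficient
#' functions (the fitted model's spline basis never enters generation).
#'
#' @param Z Covariate matrix.
#' @param spec A `scenario_spec`.
#' @return `n x S` hazard matrix.
#' @export
true_hazard_matrix <- function(Z, spec) {
  Bt <- vapply(spec$beta_funs, function(f) f(spec$times), numeric(spec$S)) # S x P
  eta <- matrix(spec$gamma_true, nrow(Z), spec$S, byrow = TRUE) +
    Z %*% t(Bt)
  if (nrow(spec$alpha_true) > 0) {
    zz <- Z[, spec$alpha_true[, 1], drop = FALSE] *
      Z[, spec$alpha_true[, 2], drop = FALSE]
    eta <- eta + drop(zz %*% spec$alpha_true[, 3])
  }
  stats::plogis(eta)
}

#' Draw discrete event times
#'
#' Sequential Bernoulli draws over the grid: the first success gives the
#' event time index; subjects with no success by `S` have no event (handled
#' by the censoring step).
#'
#' @param Z Covariate matrix.
#' @param spec A `scenario_spec`.
#' @return Numeric vector of event-time indices, `Inf` when no event by `S`.
#' @export
gen_event_times <- function(Z, spec) {
  lam <- true_hazard_matrix(Z, spec)
  n <- nrow(Z)
  hit <- matrix(stats::runif(n * spec$S), n, spec$S) < lam
  any_hit <- rowSums(hit) > 0
  D <- rep(Inf, n)
  D[any_hit] <- max.col(hit[any_hit, , drop = FALSE], ties.method = "first")
  D
}

#' Censor and assemble a discrete survival dataset
#'
#' Censoring times are drawn DiscreteUniform on `spec$censor_support`;
#' `T = min(D, C)`, `delta = 1{D <= C}`. Subjects event-free at `S` are
#' censored at `min(C, S)`.
#'
#' @param D Event-time indices from [gen_event_times()] (`Inf` = no event).
#' @param Z Covariate matrix.
#' @param spec A `scenario_spec`.
#' @return A `dsurv` object on the full grid `1..S`.
#' @export
gen_censoring_and_assemble <- function(D, Z, spec) {
  n <- length(D)
  C <- spec$censor_support[sample.int(length(spec$censor_support), n,
                                      replace = TRUE)]
  Tobs <- pmin(D, C)
  delta <- as.integer(D <= C)
  df <- data.frame(time = as.integer(Tobs), event = delta, Z,
                   check.names = FALSE)
  as_dsurv(df, time = "time", event = "event", grid = spec$times,
           time_mode = "index")
}

#' Simulate a discrete-time survival dataset with its truth record
#'
#' Seeded, fully reproducible: covariates, event times and censoring are
#' drawn under `spec`, and the truth (selection sets, coefficient curves on
#' the grid, interaction values) is returned alongside for evaluation.
#'
#' @param spec A `scenario_spec`.
#' @return Object of class `dsurv_sim`: list with `data` (tibble, one row per
#'   subject), `dsurv` (the internal container) and `truth` (list with
#'   `ti_or_tv`, `tv`, `int`, `beta_grid` (`S x P`), `gamma`, `alpha`).
#' @examples
#' sim <- simulate_dsurv(scenario_spec("highdim", n = 100, P = 10, seed = 42))
#' sim$truth$ti_or_tv  # 1..5
#' @export
simulate_dsurv <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  Z <- gen_covariates(spec$n, spec$P, spec$rho, spec$binary)
  D <- gen_event_times(Z, spec)
  ds <- gen_censoring_and_assemble(D, Z, spec)

  Bt <- vapply(spec$beta_funs, function(f) f(spec$times), numeric(spec$S))
  nonconst <- vapply(seq_len(spec$P), function(j) {
    diff(range(Bt[, j])) > 1e-12
  }, logical(1))
  nonzero <- colSums(abs(Bt)) > 1e-12
  truth <- list(
    ti_or_tv = which(nonzero),
    tv = which(nonconst),
    int = spec$alpha_true[, 1:2, drop = FALSE],
    beta_grid = Bt,
    gamma = spec$gamma_true,
    alpha = spec$alpha_true
  )
  structure(list(data = as_tibble.dsurv(ds), dsurv = ds, truth = truth,
                 spec = spec),
            class = "dsurv_sim")
}

#' @export
print.dsurv_sim <- function(x, ...) {
  cat("<dsurv_sim> scenario '", x$spec$name, "'\n", sep = "")
  print(x$dsurv)
  cat("  true signals:", length(x$truth$ti_or_tv), "covariates (",
      length(x$truth$tv), "time-varying ),", nrow(x$truth$int),
      "interactions\n")
  invisible(x)
}

#' Oracle (benchmark) structure of a simulation truth
#'
#' The structure containing exactly the true-signal terms: a
#' time-independent effect for every non-null covariate, a spline block for
#' every covariate with a non-constant coefficient function, and the true
#' interaction pairs. An idealized comparator unavailable in real data.
#'
#' @param truth Truth record from [simulate_dsurv()].
#' @return Structure list usable by [newton_fit()].
#' @export
oracle_structure <- function(truth) {
  ints <- truth$int
  if (nrow(ints) > 0) ints <- ints[order(ints[, 1], ints[, 2]), , drop = FALSE]
  list(phi = as.integer(truth$ti_or_tv), theta = as.integer(truth$tv),
       alpha = ints)
}
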