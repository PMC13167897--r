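#' Selection accuracy metrics
#'
#' Classifies candidate terms as selected/ignored against the simulation
#' truth and reports FP, FN, TP, TN and the derived proportions (sensitivity,
#' specificity, positive and negative predictive value; undefined ratios are
#' `NA`).
#'
#' Scopes:
#' * `"ti_or_tv"` — a covariate is selected iff its time-independent or
#'   spline coefficients are non-zero; truth is the set of non-null
#'   covariates.
#' * `"tv"` — a covariate is selected iff its spline block is non-zero;
#'   truth is the set of covariates with non-constant coefficient functions.
#' * `"interactions"` — pairs with non-zero interaction coefficients against
#'   the true pairs.
#'
#' With `include_interactions = TRUE` (the convention for designs where
#' interactions are candidate terms) the `"ti_or_tv"` and `"tv"` scopes also
#' count every interaction pair as a candidate item. In the `"ti_or_tv"`
#' scope selected pairs join the positives and true pairs belong to the
#' positive truth (an interaction is a time-independent term). In the `"tv"`
#' scope an interaction can never be selected as time-varying, so every pair
#' counts as correctly ignored noise (a true negative).
#'
#' @param selection List with `ti_or_tv`, `tv` (integer covariate sets) and
#'   `int` (2-column pair matrix), e.g. from [selected_sets()].
#' @param truth Truth record from [simulate_dsurv()] (uses `ti_or_tv`, `tv`,
#'   `int`).
#' @param P Number of candidate covariates.
#' @param scope One of `"ti_or_tv"`, `"tv"`, `"interactions"`.
#' @param include_interactions Count interaction pairs inside the covariate
#'   scopes (see above).
#' @return One-row tibble: `scope`, `TP`, `FP`, `FN`, `TN`, `SE`, `SP`,
#'   `PPV`, `NPV`.
#' @export
selection_metrics <- function(selection, truth, P,
                              scope = c("ti_or_tv", "tv", "interactions"),
                              include_interactions = FALSE) {
  scope <- match.arg(scope)
  pair_id <- function(m) {
    if (is.null(m) || nrow(m) == 0) return(character(0))
    paste(m[, 1], m[, 2], sep = ":")
  }
  sel_pairs <- pair_id(selection$int)
  true_pairs <- pair_id(truth$int)
  n_pairs <- P * (P - 1) / 2

  if (scope == "interactions") {
    n_items <- n_pairs
    tp <- sum(sel_pairs %in% true_pairs)
    fp <- length(sel_pairs) - tp
    fn <- length(true_pairs) - tp
  } else {
    sel_cov <- if (scope == "ti_or_tv") selection$ti_or_tv else selection$tv
    true_cov <- if (scope == "ti_or_tv") truth$ti_or_tv else truth$tv
    tp <- sum(sel_cov %in% true_cov)
    fp <- length(sel_cov) - tp
    fn <- length(true_cov) - tp
    n_items <- P
    if (include_interactions) {
      n_items <- n_items + n_pairs
      if (scope == "ti_or_tv") {
        tp_i <- sum(sel_pairs %in% true_pairs)
        tp <- tp + tp_i
        fp <- fp + length(sel_pairs) - tp_i
        fn <- fn + length(true_pairs) - tp_i
      }
      # tv scope: pairs are not selectable as time-varying; all count as TN
    }
  }
  tn <- n_items - tp - fp - fn
  ratio <- function(a, b) if (b > 0) a / b else NA_real_
  tibble::tibble(
    scope = scope, TP = tp, FP = fp, FN = fn, TN = tn,
    SE = ratio(tp, tp + fn), SP = ratio(tn, tn + fp),
    PPV = ratio(tp, tp + fp), NPV = ratio(tn, tn + fn)
  )
}

#' Estimation accuracy over replicated fits
#'
#' For a matrix of replicate estimates of a set of quantities (grid points of
#' coefficient curves, interaction scalars, or baseline parameters), reports
#' * `bias` — magnitude of the signed estimation error `replicate mean -
#'   truth` averaged over quantities (systematic errors of opposite sign
#'   cancel, as in the reference tables; see the methods vignette),
#' * `sd` — mean over quantities of the replicate standard deviation,
#' * `imse` — mean over quantities of the replicate mean squared error.
#'
#' Values are returned unscaled; multiply by 100 for tabulation.
#'
#' @param est `R x M` matrix (replicates by quantities).
#' @param truth Length-`M` vector of true values.
#' @return One-row tibble with `bias`, `sd`, `imse`.
#' @export
curve_accuracy <- function(est, truth) {
  est <- as.matrix(est)
  stopifnot(ncol(est) == length(truth), nrow(est) >= 2)
  bias <- abs(mean(colMeans(est) - truth))
  sdv <- mean(apply(est, 2, stats::sd))
  imse <- mean(colMeans(sweep(est, 2, truth)^2))
  tibble::tibble(bias = bias, sd = sdv, imse = imse)
}

#' Replicated selection experiment
#'
#' Runs simulate -> boost (-> re-estimation stopping) -> selection metrics
#' over `R` replicates with seeds `base_seed + 1..R`, and aggregates each
#' metric as mean (sd). Failed replicates are dropped with a count reported.
#'
#' @param spec A `scenario_spec` (its `seed` is overridden per replicate).
#' @param R Number of replicates.
#' @param base_seed Integer; replicate `r` uses seed `base_seed + r`.
#' @param scopes Metric scopes to evaluate.
#' @param include_interactions Passed to [selection_metrics()].
#' @param both_rules If `TRUE`, run the boosting-BIC hat-matrix rule and the
#'   re-estimation BIC rule on the same boosting path per replicate and
#'   report both (one boosting run per replicate).
#' @param ... Passed to [disc_boost()] (`hierarchy`, `interactions`, `m_max`,
#'   `stopping`, ...).
#' @return List with `summary` (tibble of mean/sd per rule and scope) and
#'   `replicates` (per-replicate metric rows), plus `n_failed`.
#' @export
replicate_experiment <- function(spec, R, base_seed = 0,
                                 scopes = c("ti_or_tv", "tv"),
                                 include_interactions = FALSE,
                                 both_rules = FALSE, ...) {
  stopifnot(R >= 1)
  rows <- vector("list", R)
  n_failed <- 0
  for (r in seq_len(R)) {
    spec$seed <- base_seed + r
    res <- tryCatch(
      one_selection_replicate(spec, scopes, include_interactions,
                              both_rules, ...),
      error = function(e) {
        message("replicate ", r, " failed: ", conditionMessage(e))
        NULL
      }
    )
    if (is.null(res)) { n_failed <- n_failed + 1; next }
    res$replicate <- r
    rows[[r]] <- res
  }
  reps <- dplyr::bind_rows(rows)
  summary <- reps |>
    dplyr::group_by(.data$rule, .data$scope) |>
    dplyr::summarise(dplyr::across(
      c("FP", "FN", "SE", "SP", "PPV", "NPV"),
      list(mean = ~mean(.x, na.rm = TRUE), sd = ~stats::sd(.x, na.rm = TRUE))
    ), .groups = "drop")
  list(summary = summary, replicates = reps, n_failed = n_failed)
}

one_selection_replicate <- function(spec, scopes, include_interactions,
                                    both_rules, ...) {
  sim <- simulate_dsurv(spec)
  args <- list(...)
  if (both_rules) {
    args$stopping <- "boosting_bic"
    fit <- do.call(disc_boost, c(list(sim$dsurv), args))
    re <- reestimation_bic_path(sim$dsurv, fit,
                                every = fit$config$every,
                                penalty = fit$config$penalty)
    picks <- list(boosting_bic = selected_sets(fit, fit$m_stop),
                  reestimation_bic = selected_sets(fit, re$m_stop))
  } else {
    fit <- do.call(disc_boost, c(list(sim$dsurv), args))
    picks <- stats::setNames(list(selected_sets(fit)),
                             fit$config$stopping)
  }
  purrr::imap_dfr(picks, function(sel, rule) {
    purrr::map_dfr(scopes, function(sc) {
      selection_metrics(sel, sim$truth, spec$P, scope = sc,
                        include_interactions = include_interactions)
    }) |> dplyr::mutate(rule = rule, .before = 1)
  })
}

#' Replicated estimation experiment on a fixed structure
#'
#' Fits the given structure (typically the oracle/benchmark structure) by
#' penalized Newton on each of `R` simulated datasets and returns estimation
#' accuracy for the main-effect curves (phi_j + beta_j(t) on the grid, over
#' the true-signal covariates), the interaction coefficients, and the
#' baseline parameters.
#'
#' @param spec A `scenario_spec`.
#' @param structure Structure list (default the oracle structure implied by
#'   the scenario truth).
#' @param R Number of replicates.
#' @param base_seed Replicate `r` uses seed `base_seed + r`.
#' @param penalty,lambda Penalty kind and smoothing value; with
#'   `lambda = "tic"` the smoothing parameter is selected by TIC per
#'   replicate.
#' @param lambda_grid Grid for TIC when `lambda = "tic"`.
#' @return List with `accuracy` (tibble: one row per evaluation scope) and
#'   the raw replicate estimate matrices.
#' @export
estimation_experiment <- function(spec, structure = NULL, R, base_seed = 0,
                                  penalty = "none", lambda = 0,
                                  lambda_grid = c(0, 0.1, 1, 10, 100)) {
  if (is.null(structure)) {
    spec$seed <- base_seed
    structure <- oracle_structure(simulate_dsurv(spec)$truth)
  }
  basis <- time_basis(spec$times)
  q <- ncol(basis$Bmat)
  lay <- refit_layout(spec$S, structure, q)

  main_cov <- structure$phi
  est_main <- matrix(NA_real_, R, spec$S * length(main_cov))
  est_alpha <- matrix(NA_real_, R, lay$na)
  est_gamma <- matrix(NA_real_, R, spec$S)
  ok <- logical(R)
  for (r in seq_len(R)) {
    spec$seed <- base_seed + r
    sim <- simulate_dsurv(spec)
    fit <- tryCatch({
      if (identical(lambda, "tic")) {
        tic_select_lambda(sim$dsurv, basis, structure, penalty = penalty,
                          lambda_grid = lambda_grid)$fit
      } else {
        newton_fit(sim$dsurv, basis, structure, penalty = penalty,
                   lambda = lambda)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    ok[r] <- TRUE
    state <- refit_state(fit, P = spec$P)
    curves <- vapply(main_cov, function(j) {
      state$phi[j] + drop(basis$Bmat %*% state$theta[j, ])
    }, numeric(spec$S))
    est_main[r, ] <- as.vector(curves)
    est_gamma[r, ] <- state$gamma
    if (lay$na > 0) est_alpha[r, ] <- fit$omega[lay$idx_alpha]
  }
  if (sum(ok) < 2) stop("fewer than two successful replicates", call. = FALSE)

  Bt <- vapply(spec$beta_funs, function(f) f(spec$times), numeric(spec$S))
  truth_main <- as.vector(Bt[, main_cov, drop = FALSE])
  acc <- dplyr::bind_rows(
    dplyr::mutate(curve_accuracy(est_main[ok, , drop = FALSE], truth_main),
                  scope = "main_effects", .before = 1),
    if (lay$na > 0) {
      truth_alpha <- apply(structure$alpha, 1, function(pr) {
        hit <- which(spec$alpha_true[, 1] == pr[1] &
                       spec$alpha_true[, 2] == pr[2])
        if (length(hit) == 1) spec$alpha_true[hit, 3] else 0
      })
      dplyr::mutate(curve_accuracy(est_alpha[ok, , drop = FALSE], truth_alpha),
                    scope = "interactions", .before = 1)
    },
    dplyr::mutate(curve_accuracy(est_gamma[ok, , drop = FALSE],
                                 spec$gamma_true),
                  scope = "baseline", .before = 1)
  )
  list(accuracy = acc, est_main = est_main[ok, , drop = FALSE],
       est_alpha = est_alpha[ok, , drop = FALSE],
       est_gamma = est_gamma[ok, , drop = FALSE],
       structure = structure, n_failed = R - sum(ok))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
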