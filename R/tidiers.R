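#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

state_terms_tibble <- function(state, names) {
  rows <- list(
    tibble::tibble(term = paste0("gamma[", seq_len(state$S), "]"),
                   type = "baseline", estimate = state$gamma)
  )
  nz <- which(state$phi != 0)
  if (length(nz)) {
    rows <- c(rows, list(tibble::tibble(
      term = names[nz], type = "TI", estimate = state$phi[nz])))
  }
  tvr <- which(rowSums(state$theta != 0) > 0)
  for (j in tvr) {
    rows <- c(rows, list(tibble::tibble(
      term = paste0(names[j], ":B", seq_len(state$q) + 1),
      type = "TV", estimate = state$theta[j, ])))
  }
  ap <- alpha_pairs(state)
  if (nrow(ap)) {
    rows <- c(rows, list(tibble::tibble(
      term = paste0(names[ap[, "j"]], ":", names[ap[, "jp"]]),
      type = "INT", estimate = ap[, "value"])))
  }
  dplyr::bind_rows(rows)
}

#' Tidy a boosting fit
#'
#' One row per non-zero coefficient of the model state at the stopping
#' iteration (baseline, time-independent, spline-block and interaction
#' terms).
#'
#' @param x A `disc_boost` object.
#' @param m Iteration at which to read the state (default `m_stop`).
#' @param ... Unused.
#' @export
tidy.disc_boost <- function(x, m = x$m_stop, ...) {
  state_terms_tibble(state_at(x, m), x$covariate_names)
}

#' Glance at a boosting fit
#'
#' @param x A `disc_boost` object.
#' @param ... Unused.
#' @export
glance.disc_boost <- function(x, ...) {
  sel <- selected_sets(x)
  tibble::tibble(
    n = x$n, P = x$P, S = x$S,
    hierarchy = x$config$hierarchy, stopping = x$config$stopping,
    m_stop = x$m_stop, m_max = x$config$m_max,
    loglik = x$trace$loglik[x$m_stop],
    df = x$trace$df[x$m_stop],
    bic = x$trace$bic[x$m_stop],
    n_selected = length(sel$ti_or_tv),
    n_tv = length(sel$tv),
    n_interactions = nrow(sel$int)
  )
}

#' Tidy a penalized refit
#'
#' One row per parameter with delta-method standard errors from the inverse
#' penalized information.
#'
#' @param x A `disc_refit` object.
#' @param names Covariate names (default `z1..zP`).
#' @param ... Unused.
#' @export
tidy.disc_refit <- function(x, names = NULL, ...) {
  if (is.null(names)) names <- paste0("z", seq_len(x$P))
  lay <- x$layout
  st <- x$structure
  term <- c(paste0("gamma[", seq_len(lay$S), "]"),
            names[st$phi],
            unlist(lapply(st$theta, function(j)
              paste0(names[j], ":B", seq_len(lay$q) + 1))),
            if (lay$na > 0) paste0(names[st$alpha[, 1]], ":",
                                   names[st$alpha[, 2]]))
  type <- c(rep("baseline", lay$S), rep("TI", lay$np),
            rep("TV", lay$nv * lay$q), rep("INT", lay$na))
  se <- sqrt(pmax(diag(robust_inverse(x$Ilambda)), 0))
  tibble::tibble(term = term, type = type, estimate = x$omega, std.error = se)
}

#' Glance at a penalized refit
#'
#' @param x A `disc_refit` object.
#' @param ... Unused.
#' @export
glance.disc_refit <- function(x, ...) {
  tibble::tibble(
    p = x$layout$p, loglik = x$loglik,
    penalized_loglik = x$penalized_loglik,
    penalty = x$penalty, lambda = x$lambda,
    df = x$df_reest, bic = x$bic_reest, tic = x$tic,
    converged = x$converged, iterations = x$iterations
  )
}

#' Plot the boosting path
#'
#' Log-likelihood and (when tracked) BIC against the iteration number, with
#' the stopping iteration marked.
#'
#' @param object A `disc_boost` object.
#' @param ... Unused.
#' @export
autoplot.disc_boost <- function(object, ...) {
  tr <- object$trace
  long <- dplyr::bind_rows(
    tibble::tibble(m = tr$m, value = tr$loglik, what = "log-likelihood"),
    if (!all(is.na(tr$bic)))
      tibble::tibble(m = tr$m, value = tr$bic, what = "boosting BIC")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$m, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$m_stop, linetype = 2) +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "boosting iteration", y = NULL,
                  title = "Boosting path",
                  subtitle = paste0("m_stop = ", object$m_stop)) +
    ggplot2::theme_minimal()
}

#' Plot fitted time-varying effect curves of a refit
#'
#' Shows `phi_j + beta_j(t)` over the grid for each covariate with a spline
#' block in the structure.
#'
#' @param object A `disc_refit` object.
#' @param names Covariate names.
#' @param ... Unused.
#' @export
autoplot.disc_refit <- function(object, names = NULL, ...) {
  if (is.null(names)) names <- paste0("z", seq_len(object$P))
  state <- refit_state(object)
  tv <- object$structure$theta
  if (length(tv) == 0) {
    stop("no time-varying blocks in this fit", call. = FALSE)
  }
  curves <- purrr::map_dfr(tv, function(j) {
    tibble::tibble(
      time = object$basis$grid,
      covariate = names[j],
      effect = state$phi[j] + drop(object$basis$Bmat %*% state$theta[j, ])
    )
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$effect)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~covariate) +
    ggplot2::labs(x = "time", y = "log odds ratio",
                  title = "Fitted time-varying effects") +
    ggplot2::theme_minimal()
}
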