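# Small fixtures built in code; the N-row long-format expansion appears only
# here, as the independent oracle representation the package itself avoids.

toy_dsurv <- function(n = 20, S = 5, P = 3, seed = 1, p_event = 0.6) {
  set.seed(seed)
  df <- data.frame(
    time = sample.int(S, n, replace = TRUE),
    event = rbinom(n, 1, p_event),
    matrix(rnorm(n * P), n, P, dimnames = list(NULL, paste0("z", seq_len(P))))
  )
  as_dsurv(df, grid = seq_len(S), time_mode = "index")
}

# subject-major (i, s <= T_i) index pairs
long_index <- function(ds) {
  i <- rep(seq_len(ds$n), ds$time_index)
  s <- sequence(ds$time_index)
  cbind(i = i, s = s)
}

# pseudo-response vector in subject-major order
long_y <- function(ds) {
  li <- long_index(ds)
  as.numeric(ds$event[li[, "i"]] == 1 & li[, "s"] == ds$time_index[li[, "i"]])
}

random_state <- function(S, P, q, seed = 1, scale = 0.3, n_alpha = 0) {
  set.seed(seed)
  alpha <- NULL
  if (n_alpha > 0 && P >= 2) {
    prs <- t(utils::combn(P, 2))
    prs <- prs[sample.int(nrow(prs), n_alpha), , drop = FALSE]
    alpha <- cbind(prs, stats::rnorm(n_alpha, 0, scale))
  }
  model_state(S, P, q,
              gamma = stats::rnorm(S, -1, scale),
              phi = stats::rnorm(P, 0, scale),
              theta = matrix(stats::rnorm(P * q, 0, scale), P, q),
              alpha = alpha)
}

# beta function list with one constant signal in front, zeros elsewhere
pad_beta_test <- function(value, P) {
  c(list(function(t) rep(value, length(t))),
    rep(list(function(t) rep(0, length(t))), P - 1))
}

# Monte-Carlo tolerance for scaled replicate checks: three standard errors
# of the mean at the replicate count actually run
mc_tol <- function(printed_sd, R) 3 * printed_sd / sqrt(R)
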