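# Vectorized least-squares machinery shared by select_term() and the main
# boosting loop. All quantities live on the n x S subject-by-interval arrays;
# the N-row long-format expansion is never built.

boost_precompute <- function(data, basis) {
  Z <- data$Z
  Tidx <- data$time_index
  S <- data$S
  Bq <- basis$Bmat
  q <- ncol(Bq)
  P <- ncol(Z)

  dTI <- unname(colSums(Tidx * Z^2))

  # cumulative basis cross-products M_s = sum_{l<=s} B_l B_l^T, flattened S x q^2
  Mflat <- matrix(0, S, q * q)
  Mc <- matrix(0, q, q)
  for (s in seq_len(S)) {
    Mc <- Mc + tcrossprod(Bq[s, ])
    Mflat[s, ] <- as.vector(Mc)
  }
  # per-covariate TV normal-equation matrices A_j = sum_s (sum_{T_i=s} z_ij^2) M_s
  z2T <- matrix(0, S, P)
  agg <- rowsum(Z^2, Tidx)
  z2T[as.integer(rownames(agg)), ] <- agg
  Aflat <- crossprod(z2T, Mflat)          # P x q^2
  Ainv <- array(NA_real_, c(q, q, P))
  tv_ok <- rep(TRUE, P)
  for (j in seq_len(P)) {
    Aj <- matrix(Aflat[j, ], q, q)
    inv <- tryCatch(solve(Aj), error = function(e) NULL)
    if (is.null(inv)) tv_ok[j] <- FALSE else Ainv[, , j] <- inv
  }
  if (any(!tv_ok)) {
    warning(sum(!tv_ok), " covariate(s) have singular time-varying designs; ",
            "their spline terms are skipped", call. = FALSE)
  }

  list(Z = Z, Bq = Bq, q = q, P = P, dTI = dTI, Ainv = Ainv, tv_ok = tv_ok,
       pair_cache = new.env(parent = emptyenv()))
}

# design columns for eligible pairs, cached and rebuilt only when the pair
# set changes
pair_design <- function(pre, data, pairs) {
  key <- paste(pairs[, 1], pairs[, 2], collapse = ";")
  pc <- pre$pair_cache
  if (!identical(pc$key, key)) {
    if (nrow(pairs) == 0) {
      pc$X2 <- matrix(0, data$n, 0); pc$d2 <- numeric(0)
    } else {
      pc$X2 <- data$Z[, pairs[, 1], drop = FALSE] * data$Z[, pairs[, 2], drop = FALSE]
      pc$d2 <- unname(colSums(data$time_index * pc$X2^2))
    }
    pc$key <- key
  }
  pc
}

# RSS (and tilde coefficients) of the gradient fit for every candidate term
rss_all <- function(U, pre, data, basis, sets, state = NULL,
                    tv_hierarchy = FALSE, interactions = TRUE) {
  P <- pre$P
  q <- pre$q
  SSU <- sum(U * U)
  Usum <- rowSums(U)

  cTI <- unname(drop(crossprod(pre$Z, Usum)))
  phi_t <- ifelse(pre$dTI > 0, cTI / pmax(pre$dTI, .Machine$double.eps), 0)
  ti <- ifelse(pre$dTI > 0, SSU - cTI * phi_t, Inf)

  UB <- U %*% pre$Bq                        # n x q
  bmat <- crossprod(pre$Z, UB)              # P x q
  theta_t <- matrix(0, P, q)
  for (k in seq_len(q)) {
    acc <- numeric(P)
    for (l in seq_len(q)) acc <- acc + pre$Ainv[k, l, ] * bmat[, l]
    theta_t[, k] <- acc
  }
  tv <- SSU - rowSums(bmat * theta_t)
  tv[!pre$tv_ok] <- Inf
  if (tv_hierarchy) {
    if (is.null(state)) stop("tv_hierarchy requires the current state", call. = FALSE)
    tv[state$phi == 0] <- Inf
  }

  if (interactions) {
    pairs <- eligible_pairs(sets)
  } else {
    pairs <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("j", "jp")))
  }
  if (nrow(pairs) > 0) {
    pc <- pair_design(pre, data, pairs)
    cI <- unname(drop(crossprod(pc$X2, Usum)))
    a_t <- ifelse(pc$d2 > 0, cI / pmax(pc$d2, .Machine$double.eps), 0)
    int <- ifelse(pc$d2 > 0, SSU - cI * a_t, Inf)
  } else {
    a_t <- numeric(0); int <- numeric(0)
  }

  list(ti = ti, tv = tv, int = int, pairs = pairs,
       phi_t = phi_t, theta_t = theta_t, a_t = a_t, SSU = SSU)
}

# subject-major pseudo-observation helpers (order: subject i, then s = 1..T_i)
smaj_time <- function(Tidx) sequence(Tidx)
smaj_expand <- function(v, Tidx) rep(v, Tidx)
smaj_vec <- function(M, tmask) t(M)[tmask]

# pseudo-observation design columns of a term, subject-major
term_design_columns <- function(data, basis, term) {
  Tidx <- data$time_index
  if (term$type %in% c("TI", "INT")) {
    x <- if (term$type == "TI") data$Z[, term$j] else data$Z[, term$j] * data$Z[, term$jp]
    return(matrix(smaj_expand(x, Tidx), ncol = 1))
  }
  basis$Bmat[smaj_time(Tidx), , drop = FALSE] * smaj_expand(data$Z[, term$j], Tidx)
}
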