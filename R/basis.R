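#' Reduced B-spline basis on the time grid
#'
#' Constructs the cubic B-spline basis with `K` functions on the grid
#' `t_1..t_S` (boundary knots at the grid extremes, interior knots at equally
#' spaced quantiles of the grid times) and drops the first basis function.
#' With the first function removed the constant is no longer in the column
#' span, so a covariate has a time-varying effect if and only if its spline
#' coefficient block is non-zero: the time-independent part of an effect is
#' carried entirely by the separate scalar coefficient.
#'
#' @param grid Numeric vector of strictly increasing grid times (length >= 2).
#' @param K Number of basis functions in the full basis before the first is
#'   dropped (default 7); must be at least `degree + 1`.
#' @param degree Spline polynomial degree (default 3, cubic).
#' @return An object of class `time_basis`: list with `Bmat` (`S x (K-1)`
#'   reduced basis values), `K`, `degree`, `knots` (interior),
#'   `boundary` and `grid`.
#' @examples
#' b <- time_basis(1:19, K = 7)
#' dim(b$Bmat)  # 19 x 6
#' @export
time_basis <- function(grid, K = 7, degree = 3) {
  grid <- as.numeric(grid)
  if (length(grid) < 2) stop("at least two grid times are required", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid times must be strictly increasing", call. = FALSE)
  }
  if (K < degree + 1) {
    stop("K must be at least degree + 1 (need K >= 4 for cubic splines)",
         call. = FALSE)
  }
  n_interior <- K - degree - 1
  boundary <- range(grid)
  knots <- if (n_interior > 0) {
    probs <- seq(0, 1, length.out = n_interior + 2)[-c(1, n_interior + 2)]
    as.numeric(stats::quantile(grid, probs = probs, names = FALSE))
  } else {
    numeric(0)
  }
  Bfull <- splines::bs(grid, knots = knots, degree = degree,
                       intercept = TRUE, Boundary.knots = boundary)
  Bfull <- unclass(Bfull)[, , drop = FALSE]
  stopifnot(ncol(Bfull) == K)
  structure(
    list(
      Bmat = unname(Bfull[, -1, drop = FALSE]),
      Bfull = unname(Bfull),
      K = K,
      degree = degree,
      knots = knots,
      boundary = boundary,
      grid = grid
    ),
    class = "time_basis"
  )
}

#' Evaluate the reduced basis at arbitrary times
#'
#' @param basis A `time_basis` object.
#' @param t Numeric times inside the boundary interval.
#' @return A `length(t) x (K-1)` matrix.
#' @export
eval_basis <- function(basis, t) {
  B <- splines::bs(t, knots = basis$knots, degree = basis$degree,
                   intercept = TRUE, Boundary.knots = basis$boundary)
  unname(unclass(B)[, -1, drop = FALSE])
}

#' @export
print.time_basis <- function(x, ...) {
  cat("<time_basis> reduced cubic B-spline basis\n")
  cat("  K =", x$K, "(", x$K - 1, "columns after dropping the first function )\n")
  cat("  interior knots:", paste(signif(x$knots, 4), collapse = ", "), "\n")
  invisible(x)
}
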