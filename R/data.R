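#' Discrete-time survival data
#'
#' Builds the internal representation of right-censored discrete failure time
#' data: an `n x P` baseline covariate matrix, a per-subject observed time
#' index on the ordered grid of distinct times `t_1 < ... < t_S`, and an
#' event indicator (1 = failure, 0 = censored). Competing events must be
#' pre-coded as censored by the caller (cause-specific, one-vs-all analysis).
#'
#' @param data A data frame with one row per subject.
#' @param time Name of the column holding observed times. With
#'   `time_mode = "value"` these are raw times mapped onto the ordered grid of
#'   distinct observed values (or onto `grid` when supplied); with
#'   `time_mode = "index"` they must already be integer indices in `1..S`.
#' @param event Name of the 0/1 event indicator column.
#' @param covariates Character vector of covariate column names; defaults to
#'   every column other than `time`, `event` and `id`.
#' @param id Optional name of a subject identifier column (kept for output).
#' @param grid Optional numeric vector of grid times `t_1..t_S`. Required when
#'   observed times do not cover the full grid you intend to model.
#' @param time_mode `"value"` or `"index"` (see `time`).
#' @return An object of class `dsurv`: a list with elements `Z` (numeric
#'   matrix), `time_index` (integer), `event` (integer), `grid` (numeric),
#'   `id`, and `n`, `P`, `S` counts.
#' @examples
#' d <- data.frame(id = 1:3, time = c(2, 5, 5), event = c(1, 0, 1), x = c(.1, -.2, .3))
#' ds <- as_dsurv(d)
#' ds$grid        # c(2, 5)
#' ds$time_index  # c(1, 2, 2)
#' @export
as_dsurv <- function(data, time = "time", event = "event", covariates = NULL,
                     id = NULL, grid = NULL, time_mode = c("value", "index")) {
  time_mode <- match.arg(time_mode)
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  for (col in c(time, event)) {
    if (!col %in% names(data)) stop("column '", col, "' not found", call. = FALSE)
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c(time, event, id))
  }
  if (length(covariates) < 1) stop("at least one covariate column is required", call. = FALSE)

  ev <- data[[event]]
  bad <- which(!(ev %in% c(0, 1)))
  if (length(bad) > 0) {
    stop("event column must be coded 0/1; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  Z <- as.matrix(data[covariates])
  storage.mode(Z) <- "double"
  if (anyNA(Z)) {
    bad <- which(rowSums(is.na(Z)) > 0)
    stop("missing covariate values are not allowed; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  tv <- data[[time]]
  if (anyNA(tv)) stop("missing times are not allowed", call. = FALSE)
  if (time_mode == "index") {
    if (any(tv != round(tv)) || any(tv < 1)) {
      stop("time_mode='index' requires positive integer indices", call. = FALSE)
    }
    S <- if (is.null(grid)) max(tv) else length(grid)
    if (any(tv > S)) stop("time index exceeds grid length", call. = FALSE)
    tidx <- as.integer(tv)
    if (is.null(grid)) grid <- seq_len(S)
  } else {
    if (is.null(grid)) grid <- sort(unique(tv))
    tidx <- match(tv, grid)
    if (anyNA(tidx)) {
      bad <- which(is.na(tidx))
      stop("observed times not on the grid; offending rows: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid times must be strictly increasing", call. = FALSE)
  }

  structure(
    list(
      Z = Z,
      time_index = tidx,
      event = as.integer(ev),
      grid = grid,
      id = if (is.null(id)) seq_len(nrow(Z)) else data[[id]],
      n = nrow(Z),
      P = ncol(Z),
      S = length(grid)
    ),
    class = "dsurv"
  )
}

#' @export
print.dsurv <- function(x, ...) {
  cat("<dsurv> discrete-time survival data\n")
  cat("  subjects:", x$n, "  covariates:", x$P,
      "  distinct times:", x$S, "\n")
  cat("  events:", sum(x$event), sprintf("(%.1f%%)", 100 * mean(x$event)), "\n")
  cat("  pseudo-observations N = sum T_i:", sum(x$time_index), "\n")
  invisible(x)
}

#' @export
as.data.frame.dsurv <- function(x, ...) {
  data.frame(id = x$id,
             time = x$grid[x$time_index],
             event = x$event,
             x$Z,
             check.names = FALSE)
}

#' Convert discrete survival data to a tibble
#'
#' One row per subject: `id`, `time` (grid value), `event`, covariates.
#' @param x A `dsurv` object.
#' @param ... Unused.
#' @export
as_tibble.dsurv <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

# at-risk mask: n x S, TRUE where s <= T_i  (the virtual pseudo-observation
# layout; the N-row long format is never materialized)
risk_mask <- function(data) {
  outer(data$time_index, seq_len(data$S), ">=")
}

# pseudo-response matrix: y_is = 1 iff delta_i = 1 and s = T_i
pseudo_response <- function(data) {
  Y <- matrix(0, data$n, data$S)
  ev <- which(data$event == 1L)
  Y[cbind(ev, data$time_index[ev])] <- 1
  Y
}
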