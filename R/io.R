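# File interchange: survival data CSV and model-state JSON.

#' Read discrete survival data from CSV
#'
#' Expects columns `id` (optional), `time`, `event` (0/1), then covariates.
#' Raw time values are mapped onto the ordered distinct-time grid (or onto a
#' separately supplied grid); validation errors name the offending rows.
#'
#' @param path CSV file path.
#' @param grid Optional grid times; with `grid_path` set, read from a
#'   two-column CSV `index,time` instead.
#' @param grid_path Optional path of a grid CSV.
#' @param time_mode `"value"` (map raw times to the grid) or `"index"`.
#' @return A `dsurv` object.
#' @export
read_dsurv_csv <- function(path, grid = NULL, grid_path = NULL,
                           time_mode = "value") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(grid_path)) {
    g <- utils::read.csv(grid_path)
    grid <- g$time[order(g$index)]
  }
  id <- if ("id" %in% names(df)) "id" else NULL
  as_dsurv(df, time = "time", event = "event", id = id, grid = grid,
           time_mode = time_mode)
}

#' Write discrete survival data to CSV
#'
#' @param data A `dsurv` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dsurv_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

MODEL_SCHEMA <- "discboost-model/1"

#' Serialize a model state to JSON
#'
#' Lossless, schema-versioned round-trip of the baseline, main-effect,
#' spline-block and interaction coefficients, keyed by covariate names.
#'
#' @param state A `model_state`.
#' @param names Covariate names (default `z1..zP`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(state, names = NULL, path) {
  if (is.null(names)) names <- paste0("z", seq_len(state$P))
  stopifnot(length(names) == state$P)
  obj <- list(
    schema = MODEL_SCHEMA,
    S = state$S, P = state$P, q = state$q,
    covariates = names,
    gamma = state$gamma,
    phi = as.list(stats::setNames(state$phi, names)),
    theta = stats::setNames(lapply(seq_len(state$P), function(j) state$theta[j, ]),
                            names),
    alpha = apply(state$alpha, 1, function(r) {
      list(j = names[r[1]], jp = names[r[2]], value = r[3])
    }, simplify = FALSE)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model state from JSON
#'
#' @param path JSON path written by [write_model_json()].
#' @return List with `state` (a `model_state`) and `covariates` (names).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, MODEL_SCHEMA)) {
    stop("unknown model schema version: ", obj$schema %||% "<missing>",
         call. = FALSE)
  }
  nms <- obj$covariates
  theta <- do.call(rbind, obj$theta[nms])
  a <- obj$alpha
  alpha <- if (length(a) > 0) {
    if (!is.data.frame(a)) a <- do.call(rbind.data.frame, a)
    cbind(j = match(a$j, nms), jp = match(a$jp, nms), value = a$value)
  } else NULL
  state <- model_state(obj$S, obj$P, obj$q,
                       gamma = obj$gamma,
                       phi = unlist(obj$phi[nms], use.names = FALSE),
                       theta = theta, alpha = alpha)
  list(state = state, covariates = nms)
}
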