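#' End-to-end prediction configuration
#'
#' Bundles every stage of the forecasting pipeline: row standardization,
#' optional mutual-information variable selection, the reservoir
#' specification and the solver options.  A single `seed` fixes all
#' randomness (reservoir weights and dropout masks derive sub-seeds from
#' it).
#'
#' @param target_index row of the target variable in the input matrix.
#' @param horizon number of future steps to predict (`L - 1 >= 1`).
#' @param m expected number of known time points (`NULL` = use all columns
#'   of the input).
#' @param select logical; apply mutual-information variable selection?
#' @param keep number of variables to keep when `select = TRUE`.
#' @param n_bins histogram bins for the MI estimator (`NULL` = default).
#' @param reservoir a [reservoir_net], the string `"identity"` for the
#'   linear baseline, or `NULL` to build the default architecture.
#' @param widths layer widths for the default reservoir (`NULL` = default).
#' @param solver a [solver_options()].
#' @param standardize z-score each row over the known window before the
#'   reservoir (recommended; heterogeneous scales saturate tanh).
#' @param seed master seed.
#' @return an object of class `predict_config`.
#' @export
predict_config <- function(target_index, horizon, m = NULL,
                           select = FALSE, keep = NULL, n_bins = NULL,
                           reservoir = NULL, widths = NULL,
                           solver = solver_options(),
                           standardize = TRUE, seed = 1L) {
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  if (select && is.null(keep)) stop("selection requires `keep`", call. = FALSE)
  structure(list(target_index = as.integer(target_index),
                 horizon = as.integer(horizon), m = m,
                 select = isTRUE(select), keep = keep, n_bins = n_bins,
                 reservoir = reservoir, widths = widths,
                 solver = solver, standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "predict_config")
}

#' Multistep-ahead prediction of a target variable
#'
#' Runs the full pipeline on a known window of a multivariate series:
#' z-score each variable over the known window, optionally keep only the
#' variables most informative about the target (mutual information, target
#' always retained), lift the snapshots through the fixed random tanh
#' reservoir, jointly solve the primary/conjugate STI equations for the
#' readouts and the unknown tail, and map the forecast back to the
#' target's original units using the known-window mean and standard
#' deviation.
#'
#' @param X numeric matrix, `n` variables x `m` known time points.
#' @param config a [predict_config()].
#' @return an object of class `arnn_prediction`: a list with `forecast`
#'   (length `horizon`, original units), `solution` (the [solve_arnn()]
#'   result on the standardized scale) and `provenance` (seeds, selected
#'   variable indices, reservoir spec, solver options).
#' @export
#' @examples
#' cfg <- lorenz_config(n_subsystems = 4, n_samples = 60, seed = 3)
#' traj <- simulate_coupled_lorenz(cfg)
#' pred <- predict_target(traj$values[, 1:50],
#'                        predict_config(target_index = 1, horizon = 10,
#'                                       solver = solver_options(max_iter = 50),
#'                                       seed = 3))
#' pred$forecast
predict_target <- function(X, config) {
  stopifnot(inherits(config, "predict_config"))
  X <- as.matrix(X)
  m <- ncol(X)
  if (!is.null(config$m) && config$m != m) {
    stop(sprintf("config$m = %d but X has %d columns", config$m, m), call. = FALSE)
  }
  if (config$target_index < 1 || config$target_index > nrow(X)) {
    stop("target_index out of range", call. = FALSE)
  }
  L <- config$horizon + 1L
  seeds <- derive_seeds(config$seed, 2L)

  std <- if (config$standardize) {
    standardize_rows(X)
  } else {
    list(X = X, mean = rep(0, nrow(X)), sd = rep(1, nrow(X)))
  }
  Z <- std$X
  target <- config$target_index

  selected <- seq_len(nrow(X))
  if (config$select) {
    selected <- as.integer(select_variables(Z, target, config$keep, config$n_bins))
    Z <- Z[selected, , drop = FALSE]
  }
  target_pos <- match(target, selected)

  net <- config$reservoir
  if (is.null(net)) {
    net <- init_reservoir(nrow(Z), widths = config$widths, seed = seeds[1L],
                          L_hint = L)
  } else if (identical(net, "identity")) {
    net <- identity_reservoir(nrow(Z))
  }
  if (reservoir_dim(net) <= L) {
    stop(sprintf("reservoir output dimension (%d) must exceed L = %d",
                 reservoir_dim(net), L), call. = FALSE)
  }
  FX <- reservoir_transform(net, Z)

  opts <- config$solver
  opts$seed <- seeds[2L]
  sol <- solve_arnn(FX, Z[target_pos, ], L, opts)

  forecast <- sol$forecast * std$sd[target] + std$mean[target]
  structure(list(forecast = forecast,
                 solution = sol,
                 provenance = list(master_seed = config$seed,
                                   reservoir_seed = seeds[1L],
                                   solver_seed = seeds[2L],
                                   selected = selected,
                                   target_index = target,
                                   m = m, horizon = config$horizon,
                                   reservoir = reservoir_to_json(net),
                                   standardize = config$standardize,
                                   solver_options = unclass(opts))),
            class = "arnn_prediction")
}

#' @export
print.arnn_prediction <- function(x, ...) {
  d <- x$solution$diagnostics
  cat(sprintf("%d-step-ahead prediction (m = %d known points) | %d iterations (%s)\n",
              x$provenance$horizon, x$provenance$m, d$iterations,
              if (d$converged) "converged" else "max_iter reached"))
  cat("forecast: ", paste(signif(x$forecast, 4), collapse = " "), "\n")
  invisible(x)
}

#' Rolling multi-window prediction over a long series
#'
#' Convenience loop for whole-series evaluation: slide a known window of
#' `m` points forward by `horizon` (no overlap between consecutive
#' forecast segments), predict each segment and concatenate.  Positions
#' `1..m` of the returned series are `NA` (never predicted).
#'
#' @param X numeric matrix, `n` variables x total time points
#'   (`> m + horizon`).
#' @param config a [predict_config()]; its `horizon` sets the stride.
#' @param m known-window length.
#' @return list with `predicted` (length `ncol(X)`, `NA` before the first
#'   forecast), and `windows` (data frame of window start/end columns).
#' @export
rolling_predict <- function(X, config, m) {
  X <- as.matrix(X)
  total <- ncol(X)
  h <- config$horizon
  if (total < m + h) stop("series too short for one window", call. = FALSE)
  starts <- seq.int(1L, total - m - h + 1L, by = h)
  predicted <- rep(NA_real_, total)
  for (s in starts) {
    cfg <- config
    cfg$m <- NULL
    pred <- predict_target(X[, s:(s + m - 1L), drop = FALSE], cfg)
    predicted[(s + m):(s + m + h - 1L)] <- pred$forecast
  }
  list(predicted = predicted,
       windows = data.frame(known_start = starts, known_end = starts + m - 1L,
                            forecast_end = starts + m + h - 1L))
}
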