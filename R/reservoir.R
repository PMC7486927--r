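#' Fixed random multilayer tanh reservoir
#'
#' Builds the nonlinear map `F` that lifts each spatial snapshot (a
#' `d_in`-vector) to a feature vector.  Weights are drawn once, i.i.d.
#' uniform on `[-s, s]`, from the given seed and are never trained; every
#' layer applies an elementwise `tanh`.  The default architecture has four
#' weight layers of widths `c(1.5 d, 1.5 d, 1.5 d, d_out)` (rounded up)
#' with `d_out = max(d_in, 3 * L_hint)`, which keeps the feature dimension
#' comfortably above the embedding dimension required by the solver.
#'
#' The default scale `s = 1/sqrt(fan_in)` per layer keeps pre-activations
#' of order one for z-scored inputs, so `tanh` stays informative rather
#' than saturating.  Biases are zero by default.
#'
#' @param d_in input dimension `D`.
#' @param widths integer vector of layer output widths; the last entry is
#'   the feature dimension.  `NULL` gives the default architecture.
#' @param seed integer seed for the weight draw.
#' @param weight_scale single positive scale for all layers, or `NULL`
#'   (default) for per-layer `1/sqrt(fan_in)`.
#' @param L_hint intended embedding dimension, used only to size the
#'   default output width.
#' @param biases `"zero"` (default) or `"uniform"` (drawn like weights).
#' @return an object of class `reservoir_net`.
#' @export
#' @examples
#' net <- init_reservoir(6, widths = c(9, 9, 9, 12), seed = 1)
#' Fx <- reservoir_transform(net, matrix(rnorm(60), 6))
#' range(Fx)   # strictly inside (-1, 1)
init_reservoir <- function(d_in, widths = NULL, seed = 1L,
                           weight_scale = NULL, L_hint = 2L,
                           biases = c("zero", "uniform")) {
  biases <- match.arg(biases)
  if (d_in < 1) stop("d_in must be >= 1", call. = FALSE)
  if (is.null(widths)) {
    w <- as.integer(ceiling(1.5 * d_in))
    widths <- c(w, w, w, max(d_in, 3L * as.integer(L_hint)))
  }
  widths <- as.integer(widths)
  if (length(widths) < 1 || any(widths < 1)) {
    stop("widths must be a non-empty vector of positive integers", call. = FALSE)
  }
  fan_in <- c(d_in, widths[-length(widths)])
  scales <- if (is.null(weight_scale)) 1 / sqrt(fan_in) else rep(weight_scale, length(widths))
  if (any(scales < 0)) stop("weight_scale must be >= 0", call. = FALSE)
  layers <- with_seed(seed, {
    lapply(seq_along(widths), function(k) {
      W <- matrix(stats::runif(widths[k] * fan_in[k], -scales[k], scales[k]),
                  nrow = widths[k])
      b <- if (biases == "uniform") {
        stats::runif(widths[k], -scales[k], scales[k])
      } else {
        rep(0, widths[k])
      }
      list(W = W, b = b)
    })
  })
  structure(list(d_in = as.integer(d_in), widths = widths,
                 layers = layers, seed = as.integer(seed),
                 weight_scale = weight_scale, biases = biases,
                 identity = FALSE),
            class = "reservoir_net")
}

#' Identity reservoir (bypass)
#'
#' A degenerate reservoir whose transform returns its input unchanged.
#' Feeding it to the ARNN solver reduces the method exactly to the
#' linearized-STI baseline, which is used as a cross-check.
#'
#' @param d_in input dimension.
#' @return a `reservoir_net` with `identity = TRUE`.
#' @export
identity_reservoir <- function(d_in) {
  structure(list(d_in = as.integer(d_in), widths = as.integer(d_in),
                 layers = list(), seed = NA_integer_,
                 weight_scale = NULL, biases = "zero", identity = TRUE),
            class = "reservoir_net")
}

#' Apply the reservoir map columnwise
#'
#' Column `t` of the result is `F(X[, t])`; there is no temporal mixing, so
#' permuting input columns permutes output columns identically.  Outputs of
#' a non-identity reservoir lie strictly inside `(-1, 1)` (tanh range).
#'
#' @param net a `reservoir_net`.
#' @param X numeric matrix `D x m` (rows must match `net$d_in`).
#' @return numeric matrix `d_out x m`.
#' @export
reservoir_transform <- function(net, X) {
  stopifnot(inherits(net, "reservoir_net"))
  X <- as.matrix(X)
  if (nrow(X) != net$d_in) {
    stop(sprintf("input has %d rows; reservoir expects %d", nrow(X), net$d_in),
         call. = FALSE)
  }
  assert_finite(X, "reservoir input")
  if (net$identity) return(X)
  H <- X
  for (layer in net$layers) {
    H <- tanh(layer$W %*% H + layer$b)
  }
  H
}

#' Output dimension of a reservoir
#' @param net a `reservoir_net`.
#' @return integer feature dimension.
#' @export
reservoir_dim <- function(net) {
  stopifnot(inherits(net, "reservoir_net"))
  as.integer(net$widths[length(net$widths)])
}

#' Serialize / restore a reservoir specification as JSON
#'
#' Only the generating specification (shapes, seed, scale, bias mode) is
#' stored; weights are regenerated deterministically on load.
#'
#' @param net a `reservoir_net`.
#' @param file optional path; if `NULL` the JSON string is returned.
#' @return `reservoir_to_json` returns the path or JSON string;
#'   `reservoir_from_json` returns a `reservoir_net`.
#' @export
reservoir_to_json <- function(net, file = NULL) {
  stopifnot(inherits(net, "reservoir_net"))
  spec <- list(d_in = net$d_in, widths = net$widths, seed = net$seed,
               weight_scale = net$weight_scale, biases = net$biases,
               identity = net$identity)
  if (is.null(file)) {
    as.character(jsonlite::toJSON(spec, auto_unbox = TRUE, null = "null", digits = NA))
  } else {
    jsonlite::write_json(spec, file, auto_unbox = TRUE, null = "null", digits = NA)
    invisible(file)
  }
}

#' @rdname reservoir_to_json
#' @param json JSON string or path produced by `reservoir_to_json`.
#' @export
reservoir_from_json <- function(json) {
  spec <- jsonlite::fromJSON(json)
  if (isTRUE(spec$identity)) {
    identity_reservoir(spec$d_in)
  } else {
    init_reservoir(spec$d_in, widths = spec$widths, seed = spec$seed,
                   weight_scale = spec$weight_scale, biases = spec$biases)
  }
}

#' @export
print.reservoir_net <- function(x, ...) {
  if (x$identity) {
    cat(sprintf("Identity reservoir (d = %d)\n", x$d_in))
  } else {
    cat(sprintf("Random tanh reservoir: %d -> %s (seed %d)\n",
                x$d_in, paste(x$widths, collapse = " -> "), x$seed))
  }
  invisible(x)
}
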