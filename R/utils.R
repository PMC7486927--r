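# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions never disturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive reproducible sub-seeds from a master seed
#'
#' All stochastic stages (simulation, reservoir weights, dropout masks,
#' per-case benchmark draws) derive their seeds through this helper so a
#' single master seed fixes the whole computation.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(length(master) == 1, is.finite(master), n >= 1)
  with_seed(master, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Row-wise z-scoring over the known window; zero-variance rows are centred
# but not scaled (scale 1) so constant inputs stay finite.
standardize_rows <- function(X) {
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(X = (X - mu) / sdv, mean = mu, sd = sdv)
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}
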