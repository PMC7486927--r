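#' Delay-coordinate (Hankel) representation of a target series
#'
#' For a target series of known length `m` and embedding dimension `L`, the
#' delay matrix `Y` is `L x m` with column `t` equal to
#' `(y[t], y[t+1], ..., y[t+L-1])`.  Its anti-diagonals are constant (Hankel
#' structure), and the lower-right triangle refers to the `L - 1` future
#' values `y[m+1], ..., y[m+L-1]`, unknown before solving.
#'
#' The object stores the series once, as a vector of length `m + L - 1`
#' with a `known` mask; the matrix is always *derived* from that vector
#' (see [hankel_matrix()]), so cells sharing a future value can never
#' drift apart.
#'
#' @param y_known numeric vector of the `m` known target values.
#' @param L embedding dimension (`2 <= L <= m`); the prediction horizon is
#'   `L - 1`.
#' @return an object of class `delay_hankel` with fields `L`, `m`, `series`
#'   (length `m + L - 1`; unknown tail initialised to `NA`) and `known`
#'   (logical mask).
#' @export
#' @examples
#' h <- build_hankel(c(1, 2, 3), L = 2)
#' hankel_matrix(h)
build_hankel <- function(y_known, L) {
  m <- length(y_known)
  if (L < 2) stop("L must be >= 2: with L = 1 there is nothing to predict", call. = FALSE)
  if (L > m) stop(sprintf("embedding dimension L = %d exceeds known length m = %d", L, m),
                  call. = FALSE)
  assert_finite(y_known, "y_known")
  n <- m + L - 1L
  series <- c(as.numeric(y_known), rep(NA_real_, L - 1L))
  known <- c(rep(TRUE, m), rep(FALSE, L - 1L))
  structure(list(L = as.integer(L), m = as.integer(m),
                 series = series, known = known),
            class = "delay_hankel")
}

#' Materialise the L x m delay matrix of a `delay_hankel`
#'
#' Cell `(i, t)` equals `series[t + i - 1]`; unknown cells read `NA` until
#' the tail is filled.
#'
#' @param h a `delay_hankel`.
#' @return numeric `L x m` matrix.
#' @export
hankel_matrix <- function(h) {
  stopifnot(inherits(h, "delay_hankel"))
  idx <- outer(seq_len(h$L), seq_len(h$m) - 1L, `+`)
  matrix(h$series[idx], nrow = h$L)
}

#' Fill the unknown future tail of a delay structure
#'
#' @param h a `delay_hankel`.
#' @param tail numeric vector of length `L - 1`: values for
#'   `y[m+1], ..., y[m+L-1]`.  Refilling overwrites any previous tail.
#' @return the updated `delay_hankel` (all positions known).
#' @export
fill_unknowns <- function(h, tail) {
  stopifnot(inherits(h, "delay_hankel"))
  if (length(tail) != h$L - 1L) {
    stop(sprintf("tail must have length L - 1 = %d, got %d", h$L - 1L, length(tail)),
         call. = FALSE)
  }
  assert_finite(tail, "tail")
  h$series[h$m + seq_len(h$L - 1L)] <- as.numeric(tail)
  h$known[] <- TRUE
  h
}

#' Extract the future tail of a delay structure
#'
#' @param h a `delay_hankel`.
#' @return numeric vector of length `L - 1` (may contain `NA` if unfilled).
#' @export
extract_tail <- function(h) {
  stopifnot(inherits(h, "delay_hankel"))
  h$series[h$m + seq_len(h$L - 1L)]
}

# Logical L x m mask of cells that refer to future values (t + i - 1 > m).
# There are exactly L * (L - 1) / 2 such cells.
hankel_unknown_cells <- function(h) {
  outer(seq_len(h$L), seq_len(h$m) - 1L, `+`) > h$m
}

#' @export
print.delay_hankel <- function(x, ...) {
  cat(sprintf("Delay embedding: L = %d, m = %d, %d of %d tail values filled\n",
              x$L, x$m, sum(x$known[x$m + seq_len(x$L - 1L)]), x$L - 1L))
  invisible(x)
}
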