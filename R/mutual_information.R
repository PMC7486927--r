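#' Plug-in mutual information between two series
#'
#' Histogram (plug-in) estimate of the mutual information, in nats, from a
#' 2-D equal-width histogram with `n_bins` bins per axis over each
#' variable's observed range.  Deterministic, symmetric in its arguments,
#' and invariant to any common reordering of the two series (MI ignores
#' temporal order).
#'
#' @param x,y numeric vectors of equal length `m >= 8`.
#' @param n_bins bins per axis; default `ceiling(sqrt(m / 5))`.
#' @return nonnegative MI estimate in nats.  A constant input gives 0 with
#'   a warning (degenerate marginal).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(1000)
#' mutual_information(x, x) > mutual_information(x, rnorm(1000))
mutual_information <- function(x, y, n_bins = NULL) {
  m <- length(x)
  if (length(y) != m) stop("x and y must have equal length", call. = FALSE)
  if (m < 8) stop("need at least 8 observations", call. = FALSE)
  assert_finite(x, "x"); assert_finite(y, "y")
  if (is.null(n_bins)) n_bins <- ceiling(sqrt(m / 5))
  n_bins <- max(2L, as.integer(n_bins))
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    warning("constant input series: mutual information is 0", call. = FALSE)
    return(0)
  }
  bin <- function(v) {
    br <- seq(min(v), max(v), length.out = n_bins + 1L)
    findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  joint <- table(factor(bin(x), levels = seq_len(n_bins)),
                 factor(bin(y), levels = seq_len(n_bins))) / m
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  max(mi, 0)
}

#' Select the most informative variables for a target
#'
#' Ranks every row of `X` by plug-in mutual information with the target row
#' and returns the indices of the `D` highest, sorted by MI descending with
#' ties broken by ascending row index.  The target row is always part of
#' the selection (its own dynamics must reach the reservoir), forced in if
#' it would not rank in the top `D`.
#'
#' @param X numeric matrix, `n` variables x `m` time points.
#' @param target_row index of the target variable in `X`.
#' @param D number of variables to keep (`1 <= D <= n`).
#' @param n_bins bins per axis for [mutual_information()].
#' @return integer vector of `D` row indices; the MI values are attached as
#'   the `"mi"` attribute (named by row index).
#' @export
select_variables <- function(X, target_row, D, n_bins = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (target_row < 1 || target_row > n) stop("invalid target_row", call. = FALSE)
  if (D < 1 || D > n) {
    stop(sprintf("D must be between 1 and the number of variables (%d)", n), call. = FALSE)
  }
  y <- X[target_row, ]
  mi <- vapply(seq_len(n), function(i) {
    suppressWarnings(mutual_information(X[i, ], y, n_bins))
  }, numeric(1))
  ord <- order(-mi, seq_len(n))
  sel <- ord[seq_len(D)]
  if (!(target_row %in% sel)) {
    sel <- c(sel[seq_len(D - 1L)], target_row)
    sel <- sel[order(-mi[sel], sel)]
  }
  structure(sel, mi = stats::setNames(mi[sel], sel))
}
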