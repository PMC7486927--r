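no_dropout <- function(...) {
  solver_options(dropout_rate = 0, ...)
}

test_that("sti_weights marks future cells and their columns", {
  W <- arnn:::sti_weights(L = 4, m = 6, unknown_weight = 0.25)
  expect_equal(dim(W$cell), c(4, 6))
  expect_equal(sum(W$cell == 0.25), 4 * 3 / 2)
  expect_identical(W$cell == 0.25, outer(1:4, 0:5, `+`) > 6)
  expect_equal(W$col, c(1, 1, 1, 0.25, 0.25, 0.25))
  W1 <- arnn:::sti_weights(4, 6, 1)
  expect_true(all(W1$cell == 1) && all(W1$col == 1))
})

test_that("update_readout returns the exact block minimisers (perturbation test)", {
  set.seed(5)
  L <- 3; Dt <- 5; m <- 9
  FX <- matrix(rnorm(Dt * m), Dt)
  Y <- matrix(rnorm(L * m), L)
  for (wu in c(1, 0.3)) {
    opts <- no_dropout(ridge = 0.05, unknown_weight = wu, consistency_weight = 0.7)
    B0 <- matrix(rnorm(Dt * L, sd = 0.2), Dt)
    fit <- update_readout(FX, Y, ridge = 0.05, consistency_weight = 0.7,
                          B_init = B0, unknown_weight = wu)
    # the objective restricted to each block is strictly convex quadratic,
    # so any perturbation of the exact minimiser must increase it
    jA <- function(A) sti_obj_blocks(A, B0, FX, Y, opts)["A"]
    jB <- function(B) sti_obj_blocks(fit$A, B, FX, Y, opts)["B"]
    for (k in 1:5) {
      dA <- matrix(rnorm(L * Dt, sd = 1e-3), L)
      dB <- matrix(rnorm(Dt * L, sd = 1e-3), Dt)
      expect_gt(jA(fit$A + dA), jA(fit$A))
      expect_gt(jB(fit$B + dB), jB(fit$B))
    }
  }
})

test_that("update_tail matches the closed-form single-unknown solution at L = 2", {
  set.seed(6)
  Dt <- 4; m <- 7; L <- 2
  FX <- matrix(rnorm(Dt * m), Dt)
  A <- matrix(rnorm(L * Dt), L)
  B <- matrix(rnorm(Dt * L), Dt)
  y <- rnorm(m)
  h <- fill_unknowns(build_hankel(y, L), 0)
  got <- update_tail(FX, A, B, h, unknown_weight = 0.5)
  # only cell (2, m) and conjugate column m involve theta = y[m+1]:
  # minimise (theta - P[2, m])^2 + || FX[, m] - B[, 1] y[m] - B[, 2] theta ||^2
  P <- A %*% FX
  r <- FX[, m] - B[, 1] * y[m]
  theta <- (P[2, m] + sum(B[, 2] * r)) / (1 + sum(B[, 2]^2))
  expect_equal(got, theta, tolerance = 1e-12)
})

test_that("objective is non-increasing without dropout and is recorded per iteration", {
  set.seed(7)
  FX <- matrix(rnorm(8 * 20), 8)
  y <- as.numeric(arima.sim(list(ar = 0.8), 20))
  sol <- solve_arnn(FX, y, L = 4, no_dropout(max_iter = 100, tol = 1e-10, seed = 2))
  obj <- sol$diagnostics$objective
  expect_length(obj, sol$diagnostics$iterations)
  expect_true(all(diff(obj) <= 1e-8 * abs(obj[-length(obj)])))
})

test_that("alternating solver reaches the brute-force global minimum on tiny instances", {
  set.seed(2)
  FX <- matrix(rnorm(6 * 8), 6)
  y <- as.numeric(arima.sim(list(ar = 0.7), 8))
  opts <- no_dropout(max_iter = 1000, tol = 1e-12, ridge = 1e-2, seed = 1)
  sol <- solve_arnn(FX, y, L = 3, opts)
  solver_obj <- tail(sol$diagnostics$objective, 1)
  brute <- brute_minimum(FX, y, L = 3, opts)
  expect_lt(abs(solver_obj - brute), 1e-6 * brute)
})

test_that("final objective equals an independent evaluation of the reported solution", {
  set.seed(12)
  FX <- matrix(rnorm(7 * 15), 7)
  y <- rnorm(15)
  opts <- no_dropout(max_iter = 50, seed = 3)
  sol <- solve_arnn(FX, y, L = 3, opts)
  expect_equal(tail(sol$diagnostics$objective, 1),
               brute_objective(sol$A, sol$B, sol$forecast, FX, y, 3, opts),
               tolerance = 1e-10)
})

test_that("exactly representable latent-rotation dynamics are recovered", {
  # Construct D-dimensional data confined to a rank-L rotating subspace:
  # X^t = Q z^t with z advancing by a block rotation R, target y^t = c'z^t.
  # Then A = [c'R^(i-1)Q']_i and B = Q M^{-1} solve both STI equations
  # exactly with A B = I, so the solver must recover the true future tail.
  L <- 4; D <- 12; m <- 40
  th <- c(0.7, 1.3)
  rot <- function(a) rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
  R <- matrix(0, 4, 4); R[1:2, 1:2] <- rot(th[1]); R[3:4, 3:4] <- rot(th[2])
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(D * 4), D)))
  z0 <- rnorm(4)
  Z <- vapply(0:(m + L - 2), function(k) {
    v <- z0; for (i in seq_len(k)) v <- R %*% v; v
  }, numeric(4))
  yfull <- colSums(Z)
  X <- Q %*% Z[, 1:m]
  sol <- solve_linear_sti(X, yfull[1:m], L,
                          no_dropout(max_iter = 2000, tol = 1e-13, ridge = 1e-8, seed = 1))
  expect_lt(max(abs(sol$forecast - yfull[m + 1:(L - 1)])), 1e-3)
  expect_lt(sol$diagnostics$ab_identity_gap, 1e-3)
})

test_that("solve_arnn and solve_linear_sti share one bit-identical contract", {
  set.seed(8)
  X <- matrix(rnorm(9 * 14), 9)
  y <- rnorm(14)
  o <- solver_options(seed = 5)
  expect_identical(solve_arnn(X, y, L = 3, o), solve_linear_sti(X, y, L = 3, o))
})

test_that("solver is deterministic in the seed; dropout masks depend on it", {
  set.seed(9)
  FX <- matrix(rnorm(10 * 18), 10)
  y <- rnorm(18)
  o <- solver_options(dropout_rate = 0.3, max_iter = 20, seed = 4)
  s1 <- solve_arnn(FX, y, L = 4, o)
  s2 <- solve_arnn(FX, y, L = 4, o)
  expect_identical(s1$forecast, s2$forecast)
  o2 <- o; o2$seed <- 5L
  expect_false(identical(solve_arnn(FX, y, L = 4, o2)$forecast, s1$forecast))
})

test_that("dropped features get exactly zero readout columns/rows when gamma = 0", {
  set.seed(10)
  FX <- matrix(rnorm(6 * 12), 6)
  Y <- matrix(rnorm(3 * 12), 3)
  mask <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  fit <- update_readout(FX, Y, ridge = 0.01, consistency_weight = 0,
                        dropout_mask = mask)
  expect_equal(fit$A[, !mask], matrix(0, 3, 2))
  expect_equal(fit$B[!mask, ], matrix(0, 2, 3))
})

test_that("ridge shrinkage drives readouts to zero in the large-penalty limit", {
  set.seed(11)
  FX <- matrix(rnorm(6 * 12), 6)
  y <- rnorm(12)
  small <- solve_arnn(FX, y, L = 3, no_dropout(ridge = 1e-2, max_iter = 5, seed = 1))
  big <- solve_arnn(FX, y, L = 3, no_dropout(ridge = 1e6, max_iter = 5, seed = 1))
  expect_lt(sqrt(sum(big$A^2)), 1e-2)
  expect_lt(sqrt(sum(big$A^2)), sqrt(sum(small$A^2)) * 1e-3)
})

test_that("completed series preserves the known window exactly", {
  set.seed(13)
  FX <- matrix(rnorm(8 * 16), 8)
  y <- rnorm(16)
  sol <- solve_arnn(FX, y, L = 5, solver_options(seed = 6))
  expect_identical(sol$completed_series[1:16], y)
  expect_identical(sol$completed_series[17:20], sol$forecast)
  expect_length(sol$forecast, 4)
})

test_that("invalid solver inputs and options are rejected", {
  FX <- matrix(rnorm(4 * 10), 4)
  expect_error(solve_arnn(FX, rnorm(10), L = 4), "must exceed")
  expect_error(solve_arnn(FX, rnorm(9), L = 2), "m columns")
  expect_error(solver_options(dropout_rate = 1), "dropout_rate")
  expect_error(solver_options(unknown_weight = 0), "unknown_weight")
  expect_error(solver_options(ridge = -1), "ridge")
  expect_error(solver_options(max_iter = 0), "max_iter")
  # rank-deficient features with no ridge: informative singularity error
  FXr <- matrix(1, 5, 8)
  expect_error(solve_arnn(FXr, rnorm(8), L = 2,
                          no_dropout(ridge = 0, consistency_weight = 0, seed = 1)),
               "ridge")
})

test_that("forecast and diagnostics exports round-trip", {
  set.seed(14)
  sol <- solve_arnn(matrix(rnorm(6 * 12), 6), rnorm(12), L = 3, solver_options(seed = 1))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".json")
  write_forecast(sol, f1); write_diagnostics(sol, f2)
  back <- utils::read.csv(f1)
  expect_equal(back$value, sol$forecast, tolerance = 1e-12)
  d <- jsonlite::fromJSON(f2)
  expect_equal(d$iterations, sol$diagnostics$iterations)
  expect_equal(d$ab_identity_gap, sol$diagnostics$ab_identity_gap, tolerance = 1e-12)
})
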