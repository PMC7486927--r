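# Independent oracles used across the suite.

# Hand-rolled fixed-step RK4 for a single classic Lorenz system; written
# directly from the equations, independent of the package's integrator.
reference_lorenz_rk4 <- function(y0, n_steps, dt, sigma = 10, rho = 28, beta = 8 / 3) {
  rhs <- function(s) {
    c(sigma * (s[2] - s[1]),
      s[1] * (rho - s[3]) - s[2],
      s[1] * s[2] - beta * s[3])
  }
  out <- matrix(NA_real_, 3, n_steps + 1)
  out[, 1] <- y0
  s <- y0
  for (k in seq_len(n_steps)) {
    k1 <- rhs(s)
    k2 <- rhs(s + dt / 2 * k1)
    k3 <- rhs(s + dt / 2 * k2)
    k4 <- rhs(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[, k + 1] <- s
  }
  out
}

# Brute-force evaluation of the solver objective for arbitrary (A, B, tail),
# written from the objective definition (weighted primary + conjugate
# residuals, consistency and ridge penalties) without reusing solver code
# beyond the public weight convention.
brute_objective <- function(A, B, tail, FX, y_known, L, opts) {
  m <- length(y_known)
  series <- c(y_known, tail)
  idx <- outer(seq_len(L), seq_len(m) - 1L, `+`)
  Y <- matrix(series[idx], nrow = L)
  fut <- idx > m
  Wc <- matrix(1, L, m); Wc[fut] <- opts$unknown_weight
  wcol <- ifelse(colSums(fut) > 0, opts$unknown_weight, 1)
  opts$primary_weight * sum(Wc * (A %*% FX - Y)^2) +
    opts$conjugate_weight * sum(rep(wcol, each = nrow(FX)) * (FX - B %*% Y)^2) +
    opts$consistency_weight * sum((A %*% B - diag(L))^2) +
    opts$ridge * (sum(A^2) + sum(B^2))
}

# Block objectives for verifying exact block minimisers: the terms of the
# full objective that depend on A (given B) and on B (given A).
sti_obj_blocks <- function(A, B, FX, Y, opts) {
  L <- nrow(Y); m <- ncol(Y)
  idx <- outer(seq_len(L), seq_len(m) - 1L, `+`)
  Wc <- matrix(1, L, m); Wc[idx > m] <- opts$unknown_weight
  wcol <- ifelse(colSums(idx > m) > 0, opts$unknown_weight, 1)
  consist <- opts$consistency_weight * sum((A %*% B - diag(L))^2)
  c(A = opts$primary_weight * sum(Wc * (A %*% FX - Y)^2) + consist +
      opts$ridge * sum(A^2),
    B = opts$conjugate_weight * sum(rep(wcol, each = nrow(FX)) * (FX - B %*% Y)^2) +
      consist + opts$ridge * sum(B^2))
}

# Multi-start quasi-Newton minimisation of the objective over all free
# parameters (A, B, tail) on tiny instances; the independent optimum the
# alternating solver is checked against.
brute_minimum <- function(FX, y_known, L, opts, n_starts = 12, seed = 1) {
  Dt <- nrow(FX); m <- length(y_known)
  nA <- L * Dt; nB <- Dt * L; nT <- L - 1
  fn <- function(par) {
    A <- matrix(par[seq_len(nA)], L, Dt)
    B <- matrix(par[nA + seq_len(nB)], Dt, L)
    tail <- par[nA + nB + seq_len(nT)]
    brute_objective(A, B, tail, FX, y_known, L, opts)
  }
  best <- Inf
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    par0 <- stats::rnorm(nA + nB + nT, sd = if (s == 1) 1e-3 else 0.5)
    res <- stats::optim(par0, fn, method = "BFGS",
                        control = list(maxit = 3000, reltol = 1e-14))
    res <- stats::optim(res$par, fn, method = "BFGS",
                        control = list(maxit = 3000, reltol = 1e-14))
    if (res$value < best) best <- res$value
  }
  best
}

# A small deterministic Lorenz-like test matrix is expensive to simulate in
# every file; memoise the common fixture.
local_fixture_env <- new.env()
fixture_trajectory <- function(seed = 101, n_samples = 68, n_subsystems = 30) {
  key <- paste(seed, n_samples, n_subsystems, sep = "_")
  if (is.null(local_fixture_env[[key]])) {
    local_fixture_env[[key]] <- simulate_coupled_lorenz(
      lorenz_config(n_subsystems = n_subsystems, n_samples = n_samples, seed = seed))
  }
  local_fixture_env[[key]]
}
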