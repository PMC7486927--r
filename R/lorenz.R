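#' Configuration for the coupled-Lorenz benchmark simulator
#'
#' Describes a ring of `n_subsystems` Lorenz oscillators used to generate
#' short-term high-dimensional benchmark series.  Subsystem `j` follows the
#' classic Lorenz equations with an additive unidirectional coupling term in
#' its x-equation:
#'
#' \deqn{\dot x_j = \sigma (y_j - x_j) + c\, x_{j-1}, \quad
#'       \dot y_j = x_j (\rho - z_j) - y_j, \quad
#'       \dot z_j = x_j y_j - \beta z_j,}
#'
#' with indices taken modulo `n_subsystems` (a ring) and coupling strength
#' `c = coupling`.  The observed state stacks the subsystem coordinates as
#' rows `(x_1, y_1, z_1, x_2, ...)`, giving `D = 3 * n_subsystems` variables
#' (the default 30 subsystems give the 90-variable benchmark).
#'
#' In the time-varying regime each of (`sigma`, `rho`, `beta`) is redrawn
#' uniformly from `param_ranges` every `switch_period` time units (default
#' 10), producing a piecewise-constant non-stationary system.
#'
#' @param n_subsystems number of coupled Lorenz subsystems (default 30).
#' @param sigma,rho,beta Lorenz parameters (defaults 10, 28, 8/3).
#' @param coupling coupling strength between adjacent subsystems.  The
#'   default 6 is the smallest ring coupling at which the collective
#'   attractor becomes low-dimensional (estimated correlation dimension
#'   about 7), so the delay-embedding condition `L > 2d` holds for the
#'   benchmark embedding dimensions while every subsystem keeps
#'   Lorenz-like oscillations.  Much weaker coupling leaves the
#'   subsystems nearly independent (attractor dimension far above any
#'   usable `L`, violating the method's working assumption); much
#'   stronger coupling freezes subsystems into long quiescent phases and
#'   diverges under fixed-step integration from about 10 upwards.
#' @param dt integration step for the fixed-step fourth-order Runge-Kutta
#'   integrator (time units).
#' @param sample_every observations are every `sample_every`-th integration
#'   step, so consecutive samples are `dt * sample_every` apart.
#' @param n_samples number of observations to return.
#' @param transient_steps integration steps discarded as burn-in.
#' @param noise_strength standard deviation of additive Gaussian observation
#'   noise applied to the sampled values (0 = noise free).
#' @param time_varying logical; redraw parameters every `switch_period`?
#' @param switch_period time between parameter redraws (time units).
#' @param param_ranges named list with elements `sigma`, `rho`, `beta`, each
#'   a length-2 numeric range; defaults to +/-20% around the classic values.
#' @param seed integer seed fixing the initial condition, the parameter
#'   schedule and the observation noise.
#' @return an object of class `lorenz_config`.
#' @export
#' @examples
#' cfg <- lorenz_config(n_subsystems = 2, n_samples = 20, seed = 1)
#' traj <- simulate_coupled_lorenz(cfg)
#' dim(traj$values)
lorenz_config <- function(n_subsystems = 30,
                          sigma = 10, rho = 28, beta = 8 / 3,
                          coupling = 6,
                          dt = 0.01,
                          sample_every = 5L,
                          n_samples = 100L,
                          transient_steps = 1000L,
                          noise_strength = 0,
                          time_varying = FALSE,
                          switch_period = 10,
                          param_ranges = NULL,
                          seed = 1L) {
  if (n_subsystems < 1) stop("n_subsystems must be >= 1", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (sample_every < 1) stop("sample_every must be >= 1", call. = FALSE)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (noise_strength < 0) stop("noise_strength must be >= 0", call. = FALSE)
  if (time_varying && switch_period <= 0) {
    stop("switch_period must be > 0 when time_varying", call. = FALSE)
  }
  if (is.null(param_ranges)) {
    param_ranges <- list(sigma = sigma * c(0.8, 1.2),
                         rho   = rho   * c(0.8, 1.2),
                         beta  = beta  * c(0.8, 1.2))
  }
  structure(list(n_subsystems = as.integer(n_subsystems),
                 sigma = sigma, rho = rho, beta = beta,
                 coupling = coupling, dt = dt,
                 sample_every = as.integer(sample_every),
                 n_samples = as.integer(n_samples),
                 transient_steps = as.integer(transient_steps),
                 noise_strength = noise_strength,
                 time_varying = isTRUE(time_varying),
                 switch_period = switch_period,
                 param_ranges = param_ranges,
                 seed = as.integer(seed)),
            class = "lorenz_config")
}

# Right-hand side for deSolve: state is the stacked (x, y, z) triples.
# parms carries the piecewise-constant parameter schedule; the active set is
# looked up from the integration time.
lorenz_rhs <- function(t, state, parms) {
  n <- parms$n
  idx <- if (parms$time_varying) {
    min(floor(t / parms$switch_period) + 1, nrow(parms$schedule))
  } else {
    1L
  }
  sg <- parms$schedule[idx, "sigma"]
  rh <- parms$schedule[idx, "rho"]
  bt <- parms$schedule[idx, "beta"]
  s <- matrix(state, nrow = 3L)
  x <- s[1L, ]; y <- s[2L, ]; z <- s[3L, ]
  xprev <- if (n > 1L) x[c(n, seq_len(n - 1L))] else x
  dx <- sg * (y - x) + parms$coupling * xprev
  dy <- x * (rh - z) - y
  dz <- x * y - bt * z
  list(as.vector(rbind(dx, dy, dz)))
}

#' Simulate a coupled-Lorenz trajectory
#'
#' Integrates the ring of Lorenz subsystems described by `config` with a
#' fixed-step fourth-order Runge-Kutta scheme, discards the burn-in, samples
#' every `sample_every`-th step and (optionally) adds observation noise.
#' Identical configurations (including `seed`) give bit-identical output.
#'
#' @param config a [lorenz_config()].
#' @return an object of class `arnn_trajectory`: a list with `values`
#'   (`D x n_samples` numeric matrix), `times` (observation times, burn-in
#'   time included in the clock) and `config`.
#' @export
simulate_coupled_lorenz <- function(config) {
  stopifnot(inherits(config, "lorenz_config"))
  n <- config$n_subsystems
  D <- 3L * n
  seeds <- derive_seeds(config$seed, 3L)

  total_steps <- config$transient_steps + config$n_samples * config$sample_every
  total_time <- total_steps * config$dt

  n_seg <- if (config$time_varying) {
    as.integer(ceiling(total_time / config$switch_period)) + 1L
  } else {
    1L
  }
  schedule <- if (config$time_varying) {
    with_seed(seeds[2L], {
      cbind(sigma = stats::runif(n_seg, config$param_ranges$sigma[1], config$param_ranges$sigma[2]),
            rho   = stats::runif(n_seg, config$param_ranges$rho[1],   config$param_ranges$rho[2]),
            beta  = stats::runif(n_seg, config$param_ranges$beta[1],  config$param_ranges$beta[2]))
    })
  } else {
    cbind(sigma = config$sigma, rho = config$rho, beta = config$beta)
  }

  y0 <- with_seed(seeds[1L], stats::runif(D, -10, 10))
  times <- seq(0, by = config$dt, length.out = total_steps + 1L)
  parms <- list(n = n, coupling = config$coupling,
                time_varying = config$time_varying,
                switch_period = config$switch_period,
                schedule = schedule)
  sol <- deSolve::ode(y = y0, times = times, func = lorenz_rhs,
                      parms = parms, method = "rk4")
  states <- t(unname(sol[, -1L, drop = FALSE]))  # D x (total_steps + 1)

  bad <- which(!apply(is.finite(states), 2L, all))
  if (length(bad)) {
    stop(sprintf("integration diverged at step %d (of %d)", bad[1L] - 1L, total_steps),
         call. = FALSE)
  }

  keep <- config$transient_steps + config$sample_every * seq_len(config$n_samples) + 1L
  values <- states[, keep, drop = FALSE]
  rownames(values) <- paste0(rep(c("x", "y", "z"), n), rep(seq_len(n), each = 3L))
  traj <- structure(list(values = values,
                         times = times[keep],
                         config = config),
                    class = "arnn_trajectory")
  if (config$noise_strength > 0) {
    traj <- add_observation_noise(traj, config$noise_strength, seeds[3L])
  }
  traj
}

#' Add Gaussian observation noise to a trajectory
#'
#' Adds independent zero-mean Gaussian noise of standard deviation
#' `strength` to every sampled value.  This models measurement noise on the
#' observations; the underlying dynamics are untouched.
#'
#' @param traj an `arnn_trajectory`.
#' @param strength noise standard deviation (>= 0; 0 returns the input).
#' @param seed integer seed for the noise draw.
#' @return a new `arnn_trajectory` with perturbed `values`.
#' @export
add_observation_noise <- function(traj, strength, seed = 1L) {
  stopifnot(inherits(traj, "arnn_trajectory"))
  if (strength < 0) stop("noise strength must be >= 0", call. = FALSE)
  assert_finite(traj$values, "trajectory values")
  if (strength == 0) return(traj)
  noisy <- traj
  noisy$values <- traj$values +
    with_seed(seed, matrix(stats::rnorm(length(traj$values), sd = strength),
                           nrow = nrow(traj$values)))
  noisy
}

#' @export
print.arnn_trajectory <- function(x, ...) {
  cat(sprintf("Coupled-Lorenz trajectory: %d variables x %d samples (dt_obs = %g)\n",
              nrow(x$values), ncol(x$values),
              x$config$dt * x$config$sample_every))
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' The CSV layout is rows = variables, columns = time points, with a header
#' row of observation times.  `write_trajectory` also writes the generating
#' configuration as a JSON file alongside (same path with extension
#' `.json`) so benchmark fixtures are self-describing.
#'
#' @param traj an `arnn_trajectory`.
#' @param file path to the CSV file.
#' @param config_json logical; also write `<file>.json` with the config?
#' @return `write_trajectory` returns `file` invisibly; `read_trajectory`
#'   returns a `D x m` numeric matrix with a `times` attribute.
#' @export
write_trajectory <- function(traj, file, config_json = TRUE) {
  stopifnot(inherits(traj, "arnn_trajectory"))
  df <- as.data.frame(traj$values)
  names(df) <- format(traj$times, digits = 10)
  utils::write.csv(cbind(variable = rownames(traj$values), df), file,
                   row.names = FALSE)
  if (config_json) {
    cfg <- traj$config
    cfg_path <- paste0(sub("\\.csv$", "", file), ".json")
    jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df[[1L]]
  attr(vals, "times") <- as.numeric(colnames(vals))
  vals
}
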