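#' Langevin dynamics configuration
#'
#' @param temperature bath temperature in K
#' @param friction friction coefficient in ps^-1
#' @param timestep integration timestep in ps
#' @param mass particle mass per coordinate (amu-like units; recycled)
#' @param scheme "underdamped" (BAOAB splitting) or "overdamped"
#'   (Euler-Maruyama on positions, mobility 1/(mass*friction))
#' @param guard divergence guard: error if |x| or the energy exceeds this value
#' @return an object of class `langevin_config`
#' @export
langevin_config <- function(temperature = 300, friction = 1, timestep = 0.01,
                            mass = 1, scheme = c("underdamped", "overdamped"),
                            guard = 1e6) {
  scheme <- match.arg(scheme)
  stopifnot(temperature > 0, friction > 0, timestep > 0, all(mass > 0))
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, mass = mass, scheme = scheme,
                 guard = guard),
            class = "langevin_config")
}

#' Simulate Langevin dynamics on a model potential
#'
#' Underdamped dynamics uses the BAOAB splitting (kick / drift / Ornstein-
#' Uhlenbeck velocity update / drift / kick), which is stable and reproduces
#' Gaussian equilibrium statistics on harmonic wells essentially exactly.
#' With `friction = 0` one may pass a `langevin_config` built with a tiny
#' positive friction; use [simulate_nve()] for strict energy-conservation
#' checks. Overdamped dynamics uses Euler-Maruyama with mobility
#' 1/(mass*friction): dx = -grad U/(m*gamma) dt + sqrt(2 kT dt/(m*gamma)) xi.
#'
#' Identical (potential, config, start, n_steps, seed) give a bit-identical
#' trajectory.
#'
#' @param potential a [model_potential()]
#' @param config a [langevin_config()]
#' @param start numeric start coordinates
#' @param n_steps number of steps (>= 1)
#' @param seed integer RNG seed
#' @param return_velocities if TRUE also return the velocity series
#'   (underdamped only)
#' @param force_fn optional replacement force function `function(x) vector`
#'   (defaults to `-potential$gradient(x)`); used internally for restrained
#'   and biased sampling
#' @param callback optional `function(step, x, v)` invoked after every step;
#'   a non-NULL return value replaces nothing but can record state by closure
#' @return matrix `n_steps x dimension` of sampled coordinates (after each
#'   step); attribute `"final_velocity"` holds the final velocity
#' @export
simulate_langevin <- function(potential, config, start, n_steps, seed,
                              return_velocities = FALSE, force_fn = NULL,
                              callback = NULL) {
  stopifnot(n_steps >= 1)
  d <- potential$dimension
  start <- as.numeric(start)
  stopifnot(length(start) == d)
  set.seed(as.integer(seed))
  kbt <- kT(config$temperature)
  m <- rep_len(config$mass, d)
  dt <- config$timestep
  gam <- config$friction
  guard <- config$guard
  force <- if (is.null(force_fn)) function(x) -potential$gradient(x) else force_fn
  out <- matrix(NA_real_, n_steps, d)
  vel <- if (return_velocities) matrix(NA_real_, n_steps, d) else NULL
  x <- start
  if (config$scheme == "overdamped") {
    mob <- 1 / (m * gam)
    sd_step <- sqrt(2 * kbt * dt * mob)
    for (i in seq_len(n_steps)) {
      x <- x + force(x) * mob * dt + stats::rnorm(d, 0, sd_step)
      if (any(!is.finite(x)) || any(abs(x) > guard))
        stop(sprintf("integrator instability at step %d", i))
      out[i, ] <- x
      if (!is.null(callback)) callback(i, x, NULL)
    }
    attr(out, "final_velocity") <- rep(0, d)
  } else {
    c1 <- exp(-gam * dt)
    c2 <- sqrt(kbt * (1 - c1^2) / m)
    v <- stats::rnorm(d, 0, sqrt(kbt / m))   # Maxwell-Boltzmann start
    f <- force(x)
    for (i in seq_len(n_steps)) {
      v <- v + 0.5 * dt * f / m
      x <- x + 0.5 * dt * v
      v <- c1 * v + c2 * stats::rnorm(d)
      x <- x + 0.5 * dt * v
      f <- force(x)
      v_half <- v + 0.5 * dt * f / m
      v <- v_half
      if (any(!is.finite(x)) || any(abs(x) > guard) ||
          !is.finite(potential$energy(x)) || abs(potential$energy(x)) > guard)
        stop(sprintf("integrator instability at step %d", i))
      out[i, ] <- x
      if (return_velocities) vel[i, ] <- v
      if (!is.null(callback)) callback(i, x, v)
    }
    attr(out, "final_velocity") <- v
  }
  if (return_velocities) attr(out, "velocities") <- vel
  out
}

#' Microcanonical (velocity-Verlet) integration for energy-drift checks
#'
#' @param potential a [model_potential()]
#' @param start start coordinates
#' @param v0 start velocities
#' @param mass mass per coordinate
#' @param timestep timestep
#' @param n_steps number of steps
#' @return list with `positions`, `velocities`, `total_energy` per step
#' @export
simulate_nve <- function(potential, start, v0, mass = 1, timestep = 0.01, n_steps = 1000) {
  d <- potential$dimension
  m <- rep_len(mass, d)
  x <- as.numeric(start); v <- as.numeric(v0)
  pos <- matrix(NA_real_, n_steps, d); velm <- matrix(NA_real_, n_steps, d)
  etot <- numeric(n_steps)
  f <- -potential$gradient(x)
  for (i in seq_len(n_steps)) {
    v <- v + 0.5 * timestep * f / m
    x <- x + timestep * v
    f <- -potential$gradient(x)
    v <- v + 0.5 * timestep * f / m
    pos[i, ] <- x; velm[i, ] <- v
    etot[i] <- potential$energy(x) + 0.5 * sum(m * v^2)
  }
  list(positions = pos, velocities = velm, total_energy = etot)
}
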