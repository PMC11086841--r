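#' Construct a model potential
#'
#' A `model_potential` bundles an energy function on a low-dimensional
#' configuration space with its analytic gradient, a rectangular domain box,
#' and an optional catalogue of labelled stationary points. These analytically
#' tractable surfaces stand in for the free-energy landscape of a solvated
#' macromolecule when exercising the sampling estimators at desk scale.
#'
#' @param dimension integer number of coordinates
#' @param energy function of a numeric vector of length `dimension`, returning
#'   energy in kcal/mol
#' @param gradient function returning the gradient vector (kcal/mol per unit)
#' @param domain 2 x dimension matrix of lower/upper box bounds
#' @param features optional list of labelled stationary points, each a list
#'   with elements `kind` ("minimum"/"saddle"), `x` (coordinates) and
#'   `energy`
#' @return an object of class `model_potential`
#' @export
model_potential <- function(dimension, energy, gradient, domain, features = list()) {
  stopifnot(dimension >= 1, is.function(energy), is.function(gradient))
  domain <- matrix(as.numeric(domain), nrow = 2)
  stopifnot(ncol(domain) == dimension, all(domain[1, ] < domain[2, ]))
  structure(list(dimension = as.integer(dimension), energy = energy,
                 gradient = gradient, domain = domain, features = features),
            class = "model_potential")
}

#' @export
print.model_potential <- function(x, ...) {
  cat(sprintf("model_potential: %dD, %d labelled stationary points\n",
              x$dimension, length(x$features)))
  for (f in x$features)
    cat(sprintf("  %-8s at (%s)  E = %.4f kcal/mol\n", f$kind,
                paste(sprintf("%.3f", f$x), collapse = ", "), f$energy))
  invisible(x)
}

#' Verify an analytic gradient against finite differences
#'
#' Compares `gradient` to centred finite differences of `energy` at random
#' points inside the domain box.
#'
#' @param pot a [model_potential()]
#' @param n_points number of random test points
#' @param h finite-difference step
#' @param seed RNG seed
#' @return maximum relative deviation over test points (invisibly); errors if
#'   it exceeds `tol`
#' @param tol relative tolerance
#' @export
check_gradient <- function(pot, n_points = 25, h = 1e-5, tol = 1e-5, seed = 1) {
  set.seed(seed)
  worst <- 0
  for (i in seq_len(n_points)) {
    x <- stats::runif(pot$dimension, pot$domain[1, ], pot$domain[2, ])
    g <- pot$gradient(x)
    fd <- vapply(seq_len(pot$dimension), function(j) {
      e <- rep(0, pot$dimension); e[j] <- h
      (pot$energy(x + e) - pot$energy(x - e)) / (2 * h)
    }, numeric(1))
    rel <- sqrt(sum((g - fd)^2)) / max(1, sqrt(sum(fd^2)))
    worst <- max(worst, rel)
  }
  if (worst > tol)
    stop(sprintf("analytic gradient deviates from finite differences (rel %.2e)", worst))
  invisible(worst)
}

#' Two-basin model potential with controlled barrier and asymmetry
#'
#' Builds a 2D double-well surface with minima at (-a, 0) and (+a, 0),
#' a = `basin_separation`/2, and a single saddle at the origin. The energy is
#' a quartic double well along x plus a transverse harmonic term; an optional
#' quintic tilt (stationary at all three stationary points) lowers the right
#' basin by exactly `asymmetry` kcal/mol relative to the left one. By
#' construction the saddle lies `barrier_height` kcal/mol above the lower
#' minimum.
#'
#' @param barrier_height saddle energy minus lower-minimum energy, kcal/mol
#' @param basin_separation distance between the two minima (length units)
#' @param asymmetry energy difference between the two minima, kcal/mol
#'   (must satisfy `asymmetry < barrier_height` for the tilt not to create
#'   spurious stationary points inside the domain)
#' @return a [model_potential()] with labelled minima and saddle
#' @export
make_two_basin_potential <- function(barrier_height, basin_separation, asymmetry = 0) {
  if (!is.numeric(barrier_height) || barrier_height <= 0)
    stop("barrier_height must be positive")
  if (!is.numeric(basin_separation) || basin_separation <= 0)
    stop("basin_separation must be positive")
  if (asymmetry < 0 || asymmetry >= barrier_height)
    stop("asymmetry must lie in [0, barrier_height)")
  a <- basin_separation / 2
  h <- barrier_height - asymmetry / 2       # quartic barrier above the (tilted) wells
  ky <- 8 * h / a^2                          # transverse curvature ~ in-well curvature
  # tilt g with g' = kq x^2 (x^2 - a^2): stationary at -a, 0, +a; g(+/-a) = -/+ asym/2
  kq <- 15 * asymmetry / (4 * a^5)
  energy <- function(x) {
    u <- x[1]; v <- x[2]
    h * ((u / a)^2 - 1)^2 + kq * (u^5 / 5 - a^2 * u^3 / 3) + 0.5 * ky * v^2
  }
  gradient <- function(x) {
    u <- x[1]; v <- x[2]
    c(4 * h * u * (u^2 - a^2) / a^4 + kq * u^2 * (u^2 - a^2), ky * v)
  }
  e_left <- kq * (-a^5 / 5 + a^5 / 3)        # = + asymmetry/2
  e_right <- kq * (a^5 / 5 - a^5 / 3)        # = - asymmetry/2
  feats <- list(
    list(kind = "minimum", x = c(-a, 0), energy = e_left),
    list(kind = "minimum", x = c(a, 0), energy = e_right),
    list(kind = "saddle", x = c(0, 0), energy = h))
  model_potential(2, energy, gradient,
                  domain = rbind(c(-2 * a, -2 * a), c(2 * a, 2 * a)),
                  features = feats)
}

#' Mueller-Brown potential
#'
#' The standard four-Gaussian-term benchmark surface, optionally scaled. Its
#' three minima and two saddles are well separated, making it a common test
#' bed for path-finding and free-energy estimators.
#'
#' @param scale multiplicative energy scale (default 0.05 brings barriers to a
#'   few kcal/mol, comparable to thermally accessible protein transitions)
#' @return a [model_potential()] (stationary points are not pre-labelled; use
#'   [find_stationary_points()])
#' @export
muller_brown_potential <- function(scale = 0.05) {
  A <- c(-200, -100, -170, 15)
  aa <- c(-1, -1, -6.5, 0.7)
  bb <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  energy <- function(x) {
    dx <- x[1] - x0; dy <- x[2] - y0
    scale * sum(A * exp(aa * dx^2 + bb * dx * dy + cc * dy^2))
  }
  gradient <- function(x) {
    dx <- x[1] - x0; dy <- x[2] - y0
    e <- A * exp(aa * dx^2 + bb * dx * dy + cc * dy^2)
    c(scale * sum(e * (2 * aa * dx + bb * dy)),
      scale * sum(e * (2 * cc * dy + bb * dx)))
  }
  model_potential(2, energy, gradient,
                  domain = rbind(c(-1.8, -0.5), c(1.2, 2.2)))
}

#' Isotropic/diagonal harmonic potential
#'
#' @param kappa per-coordinate force constants, kcal/mol/U^2 (recycled)
#' @param dimension number of coordinates
#' @param center well centre
#' @param half_width domain half width per coordinate
#' @return a [model_potential()]
#' @export
harmonic_potential <- function(kappa, dimension = length(kappa), center = rep(0, dimension),
                               half_width = 6) {
  kappa <- rep_len(kappa, dimension)
  energy <- function(x) 0.5 * sum(kappa * (x - center)^2)
  gradient <- function(x) kappa * (x - center)
  model_potential(dimension, energy, gradient,
                  domain = rbind(center - half_width, center + half_width),
                  features = list(list(kind = "minimum", x = center, energy = 0)))
}

#' Locate stationary points of a model potential
#'
#' Multi-start quasi-Newton minimisation of |grad U|^2 over a grid of starting
#' points, followed by de-duplication and classification by the Hessian sign
#' pattern (finite differences of the analytic gradient).
#'
#' @param pot a [model_potential()]
#' @param n_starts starts per dimension (total `n_starts^dimension`)
#' @param grad_tol gradient-norm threshold for acceptance
#' @return list of stationary points, each with `kind`, `x`, `energy`,
#'   `grad_norm`
#' @export
find_stationary_points <- function(pot, n_starts = 8, grad_tol = 1e-8) {
  d <- pot$dimension
  gsq <- function(x) sum(pot$gradient(x)^2)
  grids <- lapply(seq_len(d), function(j)
    seq(pot$domain[1, j], pot$domain[2, j], length.out = n_starts))
  starts <- as.matrix(expand.grid(grids))
  found <- list()
  for (i in seq_len(nrow(starts))) {
    res <- try(stats::optim(starts[i, ], gsq, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-16)), silent = TRUE)
    if (inherits(res, "try-error")) next
    x <- res$par
    # Newton polish on the gradient (finite-difference Hessian)
    for (nw in 1:8) {
      g <- pot$gradient(x)
      if (sqrt(sum(g^2)) < grad_tol / 10) break
      hN <- 1e-6
      Hn <- matrix(0, d, d)
      for (j in seq_len(d)) {
        e <- rep(0, d); e[j] <- hN
        Hn[, j] <- (pot$gradient(x + e) - pot$gradient(x - e)) / (2 * hN)
      }
      step <- try(solve(Hn, g), silent = TRUE)
      if (inherits(step, "try-error") || any(!is.finite(step))) break
      x <- x - step
    }
    if (any(x < pot$domain[1, ] - 1e-9) || any(x > pot$domain[2, ] + 1e-9)) next
    gn <- sqrt(gsq(x))
    if (gn > grad_tol) next
    dup <- any(vapply(found, function(f) sqrt(sum((f$x - x)^2)) < 1e-4, logical(1)))
    if (dup) next
    # Hessian from finite differences of the analytic gradient
    hH <- 1e-5
    H <- matrix(0, d, d)
    for (j in seq_len(d)) {
      e <- rep(0, d); e[j] <- hH
      H[, j] <- (pot$gradient(x + e) - pot$gradient(x - e)) / (2 * hH)
    }
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
    kind <- if (all(ev > 0)) "minimum" else if (all(ev < 0)) "maximum" else "saddle"
    found[[length(found) + 1]] <- list(kind = kind, x = unname(x),
                                       energy = pot$energy(x), grad_norm = gn)
  }
  found[order(vapply(found, `[[`, numeric(1), "energy"))]
}
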