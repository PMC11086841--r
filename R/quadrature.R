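#' Free-energy surface container
#'
#' A regular grid over one or two observables with free energies (kcal/mol,
#' gauged so the minimum over defined bins is 0), per-bin sample counts and
#' optional error estimates.
#'
#' @param midpoints list of per-axis bin midpoints
#' @param values numeric vector (1D) or matrix (2D) of free energies; `NA`
#'   marks undefined bins
#' @param counts per-bin (effective) sample counts, same shape as `values`
#' @param errors per-bin error estimates, same shape (optional)
#' @param axis_names names of the observables
#' @return object of class `fes`
#' @export
fes <- function(midpoints, values, counts = NULL, errors = NULL,
                axis_names = paste0("cv", seq_along(midpoints))) {
  if (!is.list(midpoints)) midpoints <- list(midpoints)
  v <- values
  if (any(is.finite(v))) v <- v - min(v, na.rm = TRUE)
  structure(list(midpoints = midpoints, values = v, counts = counts,
                 errors = errors, axis_names = axis_names,
                 ndim = length(midpoints)),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("free-energy surface: %dD over %s; %d bins, range %.3f..%.3f kcal/mol, %d undefined\n",
              x$ndim, paste(x$axis_names, collapse = " x "),
              length(x$values), rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
plot.fes <- function(x, ...) {
  if (x$ndim == 1) {
    graphics::plot(x$midpoints[[1]], x$values, type = "l",
                   xlab = x$axis_names[1], ylab = "F (kcal/mol)", ...)
  } else {
    graphics::image(x$midpoints[[1]], x$midpoints[[2]], x$values,
                    xlab = x$axis_names[1], ylab = x$axis_names[2], ...)
    graphics::contour(x$midpoints[[1]], x$midpoints[[2]], x$values, add = TRUE)
  }
  invisible(x)
}

#' Interpolate a free-energy surface at arbitrary points
#'
#' Bilinear (2D) or linear (1D) interpolation; points outside the defined grid
#' return `NA`.
#'
#' @param surface a [fes()]
#' @param points numeric vector (1D) or matrix with one row per point
#' @return numeric vector of free energies
#' @export
fes_interpolate <- function(surface, points) {
  if (surface$ndim == 1) {
    pts <- as.numeric(points)
    stats::approx(surface$midpoints[[1]], surface$values, xout = pts, rule = 1)$y
  } else {
    pts <- if (is.matrix(points)) points else matrix(points, ncol = 2)
    mx <- surface$midpoints[[1]]; my <- surface$midpoints[[2]]
    vapply(seq_len(nrow(pts)), function(i) {
      px <- pts[i, 1]; py <- pts[i, 2]
      ix <- findInterval(px, mx); iy <- findInterval(py, my)
      if (ix < 1 || ix >= length(mx) || iy < 1 || iy >= length(my)) return(NA_real_)
      tx <- (px - mx[ix]) / (mx[ix + 1] - mx[ix])
      ty <- (py - my[iy]) / (my[iy + 1] - my[iy])
      v <- surface$values
      (1 - tx) * (1 - ty) * v[ix, iy] + tx * (1 - ty) * v[ix + 1, iy] +
        (1 - tx) * ty * v[ix, iy + 1] + tx * ty * v[ix + 1, iy + 1]
    }, numeric(1))
  }
}

#' Reference PMF by dense quadrature
#'
#' Brute-force oracle for all free-energy estimators in the package:
#' F(z) = -kT ln Integral exp(-U(x)/kT) delta(cv(x) - z) dx, evaluated by a
#' dense midpoint quadrature over the potential's domain box, binning the
#' Boltzmann weight of each quadrature cell by its collective-variable value.
#' Gauged so min F = 0.
#'
#' @param potential a [model_potential()] (1D or 2D)
#' @param cv_map function mapping a coordinate vector to 1 or 2 CV values
#' @param grid_spec list with `min`, `max`, `nbins` per CV axis (vectors of
#'   length 1 or 2)
#' @param temperature temperature in K
#' @param n_quad quadrature points per coordinate axis
#' @param domain optional 2 x d matrix restricting the integration box
#'   (defaults to the potential's domain); the CV grid must cover the image
#'   of this box
#' @return a [fes()]; errors if CV values fall outside the grid
#' @export
reference_pmf_quadrature <- function(potential, cv_map, grid_spec,
                                     temperature = 300, n_quad = 400,
                                     domain = NULL) {
  beta <- 1 / kT(temperature)
  d <- potential$dimension
  if (is.null(domain)) domain <- potential$domain
  axes <- lapply(seq_len(d), function(j) {
    e <- seq(domain[1, j], domain[2, j], length.out = n_quad + 1)
    (e[-1] + e[-length(e)]) / 2
  })
  cell <- prod(vapply(seq_len(d), function(j)
    diff(domain[, j]) / n_quad, numeric(1)))
  pts <- as.matrix(expand.grid(axes))
  w <- exp(-beta * apply(pts, 1, potential$energy)) * cell
  # cv_map may be vectorised (accepting the full point matrix); fall back to
  # row-wise application otherwise
  cvs <- tryCatch({
    v <- cv_map(pts)
    if (is.matrix(v) && nrow(v) == nrow(pts)) v
    else if (length(v) == nrow(pts)) matrix(v, ncol = 1)
    else stop("not vectorised")
  }, error = function(e) {
    v <- t(apply(pts, 1, cv_map))
    if (ncol(v) == nrow(pts)) t(v) else v
  })
  ncv <- ncol(cvs)
  nb <- rep_len(grid_spec$nbins, ncv)
  lo <- rep_len(grid_spec$min, ncv); hi <- rep_len(grid_spec$max, ncv)
  if (any(apply(cvs, 2, min) < lo - 1e-9) || any(apply(cvs, 2, max) > hi + 1e-9))
    stop("CV grid does not cover the image of the domain (coverage error)")
  idx <- vapply(seq_len(ncv), function(j) {
    i <- findInterval(cvs[, j], seq(lo[j], hi[j], length.out = nb[j] + 1),
                      rightmost.closed = TRUE, all.inside = TRUE)
    i
  }, integer(nrow(cvs)))
  mids <- lapply(seq_len(ncv), function(j) {
    e <- seq(lo[j], hi[j], length.out = nb[j] + 1)
    (e[-1] + e[-length(e)]) / 2
  })
  if (ncv == 1) {
    z <- vapply(seq_len(nb[1]), function(b) sum(w[idx[, 1] == b]), numeric(1))
    vals <- ifelse(z > 0, -log(z) / beta, NA_real_)
    fes(mids, vals, counts = as.numeric(tabulate(idx[, 1], nb[1])),
        axis_names = "cv1")
  } else {
    flat <- (idx[, 2] - 1L) * nb[1] + idx[, 1]
    z <- numeric(nb[1] * nb[2])
    agg <- rowsum(w, flat)
    z[as.integer(rownames(agg))] <- agg[, 1]
    vals <- matrix(ifelse(z > 0, -log(z) / beta, NA_real_), nb[1], nb[2])
    fes(mids, vals, counts = matrix(tabulate(flat, nb[1] * nb[2]), nb[1], nb[2]),
        axis_names = c("cv1", "cv2"))
  }
}
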