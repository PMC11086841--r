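#' Collective-variable maps for model potentials
#'
#' A `cv_map` couples the sampling engines to a differentiable map from
#' configuration space to 1-2 collective variables: `value(x)` returns the CV
#' vector, `jacobian(x)` the ncv x d Jacobian.
#'
#' `cv_identity()` uses all coordinates as CVs; `cv_components()` selects a
#' subset of coordinates.
#'
#' @param d configuration-space dimension
#' @return object of class `cv_map`
#' @export
cv_identity <- function(d) {
  J <- diag(d)
  structure(list(ncv = d, value = function(x) x, jacobian = function(x) J),
            class = "cv_map")
}

#' @rdname cv_identity
#' @param idx indices of the coordinates used as CVs
#' @export
cv_components <- function(idx, d) {
  J <- matrix(0, length(idx), d)
  for (r in seq_along(idx)) J[r, idx[r]] <- 1
  structure(list(ncv = length(idx), value = function(x) x[idx],
                 jacobian = function(x) J),
            class = "cv_map")
}

#' Extended-coordinate (fictitious particle) parameters for eABF
#'
#' Each CV is harmonically tethered to an auxiliary dynamical coordinate
#' lambda that carries the adaptive bias. Typical settings follow NAMD-style
#' eABF: a coupling strong enough to drag the CV yet soft enough for smooth
#' exploration, and a Langevin-thermostatted fictitious particle.
#'
#' @param k per-CV coupling force constants, kcal/mol/U^2
#' @param mass fictitious mass per CV
#' @param friction extended-thermostat friction, ps^-1
#' @param temperature extended-thermostat temperature, K
#' @return object of class `extended_state`
#' @export
extended_state <- function(k, mass = 20, friction = 10, temperature = 300) {
  stopifnot(all(k > 0), all(mass > 0), friction > 0, temperature > 0)
  structure(list(k = k, mass = mass, friction = friction,
                 temperature = temperature),
            class = "extended_state")
}

#' Bias grid for (e)ABF accumulation
#'
#' A regular grid over 1-2 CVs holding two sets of statistics: binned by the
#' true CV z (sample count and running sum of the extended coordinate lambda,
#' consumed by the CZAR estimator) and binned by lambda (sample count and
#' running sum of the coupling force, which drives the adaptive bias).
#'
#' @param lower,upper per-CV grid bounds
#' @param nbins per-CV bin counts
#' @param k per-CV coupling force constants (kcal/mol/U^2)
#' @param full_samples ramp threshold: the applied bias is scaled by
#'   min(1, N/full_samples) to limit non-equilibrium effects early on
#' @param clamp if TRUE, samples outside the grid are accumulated in the
#'   boundary bin; if FALSE they raise an error
#' @return object of class `bias_grid`
#' @export
bias_grid <- function(lower, upper, nbins, k, full_samples = 2000, clamp = TRUE) {
  ncv <- length(nbins)
  stopifnot(length(lower) == ncv, length(upper) == ncv, all(lower < upper),
            all(nbins >= 2), length(k) == ncv, all(k > 0), full_samples >= 1)
  edges <- lapply(seq_len(ncv), function(j) seq(lower[j], upper[j], length.out = nbins[j] + 1))
  mids <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  nb <- prod(nbins)
  structure(list(ncv = ncv, nbins = as.integer(nbins),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 width = (upper - lower) / nbins,
                 edges = edges, mids = mids, k = as.numeric(k),
                 full_samples = full_samples, clamp = clamp,
                 count_z = numeric(nb), sum_lambda = matrix(0, nb, ncv),
                 sum_z = matrix(0, nb, ncv),
                 count_l = numeric(nb), sum_force = matrix(0, nb, ncv)),
            class = "bias_grid")
}

#' @export
print.bias_grid <- function(x, ...) {
  cat(sprintf("bias_grid: %dD, %s bins, %g samples, %.0f%% bins at full_samples\n",
              x$ncv, paste(x$nbins, collapse = " x "), sum(x$count_z),
              100 * mean(x$count_l >= x$full_samples)))
  invisible(x)
}

# flat bin index for a CV vector; clamped to the grid
grid_bin <- function(grid, z) {
  i <- floor((z - grid$lower) / grid$width) + 1
  i[i < 1] <- 1
  i[i > grid$nbins] <- grid$nbins[i > grid$nbins]
  if (grid$ncv == 1) i[1] else i[1] + (i[2] - 1) * grid$nbins[1]
}

#' Run extended-system ABF sampling
#'
#' Samples `potential` with underdamped Langevin dynamics while each CV is
#' harmonically coupled (force constant `extended$k`) to a fictitious
#' Langevin-thermostatted particle lambda. The instantaneous coupling force
#' on lambda, k(z - lambda), is accumulated in lambda's bin; the adaptive
#' bias opposes the running mean of that force, scaled per bin by the ramp
#' factor min(1, N/full_samples). Statistics binned by the true CV z
#' (counts and running lambda sums) feed the CZAR estimator.
#'
#' The bias is applied as the gradient of a piecewise-interpolated bias
#' potential rebuilt from the ramped mean-force field every `bias_update`
#' steps, rather than as the raw per-bin constant force: in two dimensions a
#' binned force field is not curl-free, and applying it directly drives
#' steady-state probability currents that bias the accumulated statistics,
#' whereas any conservative bias leaves the CZAR identity intact.
#'
#' @param potential a [model_potential()]
#' @param config a [langevin_config()] for the physical coordinates
#' @param cvs a `cv_map` (see [cv_identity()])
#' @param grid a [bias_grid()]; statistics already in it are inherited (the
#'   bias starts from them) and the returned grid contains the running totals
#' @param extended an [extended_state()]
#' @param n_steps number of MD steps
#' @param seed RNG seed
#' @param start start coordinates (defaults to domain centre)
#' @param window list(lo, hi): one-sided harmonic walls confining lambda to
#'   the window. Defaults to the grid boundaries, which keeps the
#'   freely-diffusing extended coordinate on the grid once the bias flattens
#'   the landscape. Walls are deliberately soft (see `wall_k`) and
#'   accumulation is NOT gated on the window: a sharp statistical cut at the
#'   boundary would imprint a thin boundary layer of strong log-density
#'   curvature on the CV histogram that the finite-difference step of the
#'   CZAR estimator cannot resolve, whereas a soft lambda-only wall is just
#'   another bias the estimator deconvolves exactly.
#' @param wall_k one-sided wall force constant, kcal/mol/U^2
#' @param record_every thinning interval for the returned (z, lambda) series
#' @param bias_update interval (steps) between rebuilds of the applied bias
#'   potential from the accumulated mean-force field
#' @return list with elements `grid` (updated [bias_grid()]) and `traj`
#'   (matrix with columns z1[,z2],l1[,l2])
#' @export
run_eabf <- function(potential, config, cvs, grid, extended, n_steps, seed,
                     start = NULL, window = NULL, wall_k = 10,
                     record_every = 10, bias_update = 1000) {
  d <- potential$dimension
  ncv <- cvs$ncv
  stopifnot(grid$ncv == ncv, length(extended$k) == ncv)
  if (is.null(start)) start <- colMeans(potential$domain)
  if (is.null(window)) window <- list(lo = grid$lower, hi = grid$upper)
  set.seed(as.integer(seed))
  kbt <- kT(config$temperature)
  kbt_ext <- kT(extended$temperature)
  m <- rep_len(config$mass, d)
  mL <- rep_len(extended$mass, ncv)
  dt <- config$timestep
  kcpl <- extended$k
  c1 <- exp(-config$friction * dt)
  c2 <- sqrt(kbt * (1 - c1^2) / m)
  c1L <- exp(-extended$friction * dt)
  c2L <- sqrt(kbt_ext * (1 - c1L^2) / mL)
  full <- grid$full_samples
  count_l <- grid$count_l; sum_force <- grid$sum_force
  count_z <- grid$count_z; sum_lambda <- grid$sum_lambda
  sum_z <- grid$sum_z
  lower <- grid$lower; width <- grid$width; nbins <- grid$nbins
  clamp <- grid$clamp
  n1 <- nbins[1]
  x <- as.numeric(start)
  z <- cvs$value(x)
  lam <- z
  v <- stats::rnorm(d, 0, sqrt(kbt / m))
  vL <- stats::rnorm(ncv, 0, sqrt(kbt_ext / mL))
  nrec <- n_steps %/% record_every
  traj <- matrix(NA_real_, nrec, 2 * ncv)
  irec <- 0L
  sys_force <- function(x, lam, z, J) -potential$gradient(x) + as.numeric(t(J) %*% (kcpl * (lam - z)))
  J <- cvs$jacobian(x)
  f <- sys_force(x, lam, z, J)
  fcoup <- kcpl * (z - lam)
  fL <- fcoup   # bias added below in loop
  # bias potential at bin centres (rebuilt every bias_update steps)
  mids1 <- grid$mids[[1]]
  mids2 <- if (ncv == 2) grid$mids[[2]] else NULL
  Vnode <- if (ncv == 1) numeric(n1) else matrix(0, n1, nbins[2])
  rebuild_bias <- function() {
    ramp <- pmin(1, count_l / full)
    gfield <- -ramp * sum_force / pmax(count_l, 1)   # ramped A' estimate
    if (ncv == 1) {
      g1 <- gfield[, 1]
      v <- numeric(n1)
      for (i in 2:n1) v[i] <- v[i - 1] + 0.5 * (g1[i] + g1[i - 1]) * width[1]
      v
    } else {
      n2 <- nbins[2]
      gx <- matrix(gfield[, 1], n1, n2)
      gy <- matrix(gfield[, 2], n1, n2)
      V <- matrix(0, n1, n2)
      for (i in 2:n1)
        V[i, ] <- V[i - 1, ] + 0.5 * (gx[i, ] + gx[i - 1, ]) * width[1]
      off <- numeric(n2)
      my <- colMeans(gy)
      for (j in 2:n2) off[j] <- off[j - 1] + 0.5 * (my[j] + my[j - 1]) * width[2]
      sweep(V, 2, off, `+`)
    }
  }
  for (step in seq_len(n_steps)) {
    # --- physical coordinates (BAOAB) ---
    v <- v + 0.5 * dt * f / m
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * stats::rnorm(d)
    x <- x + 0.5 * dt * v
    # --- extended coordinates (BAOAB) ---
    vL <- vL + 0.5 * dt * fL / mL
    lam <- lam + 0.5 * dt * vL
    vL <- c1L * vL + c2L * stats::rnorm(ncv)
    lam <- lam + 0.5 * dt * vL
    # --- forces at new state ---
    z <- cvs$value(x)
    J <- cvs$jacobian(x)
    fcoup <- kcpl * (z - lam)        # coupling force felt by lambda
    # bins (clamped); error if outside and clamping disabled
    il <- floor((lam - lower) / width) + 1
    if (!clamp && (any(il < 1) || any(il > nbins)))
      stop(sprintf("extended coordinate left the grid at step %d", step))
    il[il < 1] <- 1; il[il > nbins] <- nbins[il > nbins]
    bl <- if (ncv == 1) il[1] else il[1] + (il[2] - 1) * n1
    iz <- floor((z - lower) / width) + 1
    z_in_grid <- all(iz >= 1) && all(iz <= nbins)
    bz <- if (!z_in_grid) NA_integer_
    else if (ncv == 1) iz[1] else iz[1] + (iz[2] - 1) * n1
    fwall <- numeric(ncv)
    below <- lam < window$lo; above <- lam > window$hi
    fwall[below] <- wall_k * (window$lo[below] - lam[below])
    fwall[above] <- wall_k * (window$hi[above] - lam[above])
    count_l[bl] <- count_l[bl] + 1
    sum_force[bl, ] <- sum_force[bl, ] + fcoup
    if (z_in_grid) {
      count_z[bz] <- count_z[bz] + 1
      sum_lambda[bz, ] <- sum_lambda[bz, ] + lam
      sum_z[bz, ] <- sum_z[bz, ] + z
    }
    # adaptive bias on lambda: gradient of the interpolated bias potential
    if (step == 1 || step %% bias_update == 0) Vnode <- rebuild_bias()
    if (ncv == 1) {
      t1 <- (lam[1] - mids1[1]) / width[1]
      i1 <- min(max(floor(t1) + 1, 1), n1 - 1)
      fbias <- (Vnode[i1 + 1] - Vnode[i1]) / width[1]
    } else {
      t1 <- (lam[1] - mids1[1]) / width[1]
      t2 <- (lam[2] - mids2[1]) / width[2]
      i1 <- min(max(floor(t1) + 1, 1), n1 - 1)
      i2 <- min(max(floor(t2) + 1, 1), nbins[2] - 1)
      u1 <- min(max(t1 - (i1 - 1), 0), 1)
      u2 <- min(max(t2 - (i2 - 1), 0), 1)
      v00 <- Vnode[i1, i2]; v10 <- Vnode[i1 + 1, i2]
      v01 <- Vnode[i1, i2 + 1]; v11 <- Vnode[i1 + 1, i2 + 1]
      fbias <- c(((1 - u2) * (v10 - v00) + u2 * (v11 - v01)) / width[1],
                 ((1 - u1) * (v01 - v00) + u1 * (v11 - v10)) / width[2])
    }
    fL <- fcoup + fbias + fwall
    f <- sys_force(x, lam, z, J)
    # final B kicks
    v <- v + 0.5 * dt * f / m
    vL <- vL + 0.5 * dt * fL / mL
    if (any(!is.finite(x)) || any(abs(x) > config$guard))
      stop(sprintf("integrator instability at step %d", step))
    if (step %% record_every == 0) {
      irec <- irec + 1L
      traj[irec, ] <- c(z, lam)
    }
  }
  grid$count_l <- count_l; grid$sum_force <- sum_force
  grid$count_z <- count_z; grid$sum_lambda <- sum_lambda
  grid$sum_z <- sum_z
  colnames(traj) <- c(paste0("z", seq_len(ncv)), paste0("lambda", seq_len(ncv)))
  list(grid = grid, traj = traj)
}

#' CZAR free-energy gradient estimator
#'
#' Deconvolves the true free-energy gradient from extended-system sampling:
#' per bin centred at z,
#' `grad A(z) = -kT d/dz ln rho(z) + k (<lambda>_z - z)`,
#' where rho is the histogram density of the true CV and `<lambda>_z` the
#' per-bin mean extended coordinate. The log-density derivative uses centred
#' finite differences over bins (one-sided at the edges of the occupied
#' region); bins with fewer than `min_count` samples are excluded and
#' reported as `NA`. In the correction term, z is evaluated as the within-bin
#' sample mean of the true CV rather than the bin midpoint: with a stiff
#' coupling, k times the within-bin offset between the density-weighted mean
#' and the midpoint is a first-order discretisation bias that the sample
#' mean removes.
#'
#' @param grid a [bias_grid()] with accumulated statistics
#' @param temperature temperature in K
#' @param min_count minimum bin count entering the differentiation
#' @return matrix (nbins-flat x ncv) of gradient estimates with `NA` for
#'   missing bins; attribute `"mids"` carries bin midpoints
#' @export
czar_gradient <- function(grid, temperature = 300, min_count = 5) {
  if (all(grid$count_z == 0)) stop("empty grid: no samples to estimate from")
  kbt <- kT(temperature)
  ncv <- grid$ncv
  nb <- grid$nbins
  cnt <- grid$count_z
  ok <- cnt >= min_count
  lnr <- ifelse(ok, log(pmax(cnt, 1)), NA_real_)
  meanl <- grid$sum_lambda / ifelse(cnt > 0, cnt, NA)
  meanz <- grid$sum_z / ifelse(cnt > 0, cnt, NA)
  # fall back to bin midpoints when mean-z sums were not accumulated
  if (all(grid$sum_z == 0)) {
    if (ncv == 1) meanz[, 1] <- grid$mids[[1]]
    else {
      meanz[, 1] <- rep(grid$mids[[1]], nb[2])
      meanz[, 2] <- rep(grid$mids[[2]], each = nb[1])
    }
  }
  g <- matrix(NA_real_, length(cnt), ncv)
  if (ncv == 1) {
    dldz <- fd_derivative(lnr, grid$width[1], pos = meanz[, 1])
    g[, 1] <- -kbt * dldz + grid$k[1] * (meanl[, 1] - meanz[, 1])
  } else {
    L <- matrix(lnr, nb[1], nb[2])
    P1 <- matrix(meanz[, 1], nb[1], nb[2])
    P2 <- matrix(meanz[, 2], nb[1], nb[2])
    d1 <- vapply(seq_len(nb[2]), function(j)
      fd_derivative(L[, j], grid$width[1], pos = P1[, j]), numeric(nb[1]))
    d2 <- t(vapply(seq_len(nb[1]), function(i)
      fd_derivative(L[i, ], grid$width[2], pos = P2[i, ]), numeric(nb[2])))
    g[, 1] <- -kbt * as.vector(d1) + grid$k[1] * (meanl[, 1] - meanz[, 1])
    g[, 2] <- -kbt * as.vector(d2) + grid$k[2] * (meanl[, 2] - meanz[, 2])
  }
  g[!ok, ] <- NA_real_
  attr(g, "mids") <- grid$mids
  attr(g, "nbins") <- nb
  g
}

# centred finite differences with one-sided stencils at the edges of each
# contiguous non-NA run; `pos` supplies the effective abscissa of each bin
# (the within-bin sample mean), which corrects the spacing where the density
# is skewed inside its bins
fd_derivative <- function(y, h, pos = NULL) {
  n <- length(y)
  if (is.null(pos) || any(!is.finite(pos[is.finite(y)])))
    pos <- seq_len(n) * h
  d <- rep(NA_real_, n)
  ok <- is.finite(y)
  for (i in seq_len(n)) {
    if (!ok[i]) next
    lm <- i > 1 && ok[i - 1]
    rp <- i < n && ok[i + 1]
    if (lm && rp) {
      d[i] <- (y[i + 1] - y[i - 1]) / (pos[i + 1] - pos[i - 1])
    } else if (rp) {
      d[i] <- (y[i + 1] - y[i]) / (pos[i + 1] - pos[i])
    } else if (lm) {
      d[i] <- (y[i] - y[i - 1]) / (pos[i] - pos[i - 1])
    }
  }
  d
}

#' Integrate a free-energy gradient field
#'
#' 1D: cumulative trapezoid over the contiguous non-missing range. 2D:
#' least-squares solution of the discrete `grad F = g` system over
#' non-missing bins (the curl-inconsistent part of the field is projected
#' out by the least-squares fit); each connected component is integrated
#' separately and gauged independently, with cross-component offsets
#' undefined. Gauge: min F = 0 over defined bins.
#'
#' @param gradient output of [czar_gradient()] (or any matrix with the same
#'   attributes)
#' @param grid the [bias_grid()] the gradient lives on (for geometry)
#' @param pos_min_count bins with at least this many samples use their
#'   within-bin mean CV value as the node position for the trapezoid
#'   spacing (midpoint otherwise); the returned object carries the
#'   effective positions in `$positions`
#' @return a [fes()]; `$positions` holds the effective node positions
#'   (flattened bins x ncv)
#' @export
integrate_gradient <- function(gradient, grid, pos_min_count = 200) {
  nb <- grid$nbins
  ncv <- grid$ncv
  # effective node positions: within-bin mean of the true CV where reliable
  mids_flat <- if (ncv == 1) matrix(grid$mids[[1]], ncol = 1)
  else cbind(rep(grid$mids[[1]], nb[2]), rep(grid$mids[[2]], each = nb[1]))
  pos <- mids_flat
  if (!is.null(grid$sum_z) && any(grid$sum_z != 0)) {
    okc <- grid$count_z >= pos_min_count
    for (j in seq_len(ncv))
      pos[okc, j] <- grid$sum_z[okc, j] / grid$count_z[okc]
  }
  if (ncv == 1) {
    g <- gradient[, 1]
    p <- pos[, 1]
    F <- rep(NA_real_, length(g))
    ok <- which(is.finite(g))
    if (length(ok) == 0) stop("no defined bins to integrate")
    runs <- split(ok, cumsum(c(1, diff(ok) != 1)))
    for (r in runs) {
      acc <- 0
      F[r[1]] <- 0
      if (length(r) > 1)
        for (j in 2:length(r)) {
          acc <- acc + 0.5 * (g[r[j]] + g[r[j - 1]]) * (p[r[j]] - p[r[j - 1]])
          F[r[j]] <- acc
        }
      F[r] <- F[r] - min(F[r])
    }
    out <- fes(grid$mids, F, counts = grid$count_z)
    out$positions <- pos
    out
  } else {
    n1 <- nb[1]; n2 <- nb[2]
    h1 <- grid$width[1]; h2 <- grid$width[2]
    gx <- matrix(gradient[, 1], n1, n2)
    gy <- matrix(gradient[, 2], n1, n2)
    defined <- is.finite(gx) & is.finite(gy)
    comp <- label_components(defined)
    Fout <- matrix(NA_real_, n1, n2)
    for (cc in seq_len(max(comp, 0))) {
      cells <- which(comp == cc)
      if (length(cells) < 2) { Fout[cells] <- 0; next }
      id <- match(seq_len(n1 * n2), cells)  # bin -> unknown index or NA
      rows <- list(); rhs <- numeric(0)
      add_eq <- function(i1, i2, w, b) {
        rows[[length(rows) + 1]] <<- c(i1, i2, w)
        rhs[length(rhs) + 1] <<- b
      }
      for (j2 in seq_len(n2)) for (j1 in seq_len(n1)) {
        b <- (j2 - 1) * n1 + j1
        if (is.na(id[b])) next
        if (j1 < n1) {
          bn <- b + 1
          if (!is.na(id[bn]))
            add_eq(id[b], id[bn], 1, 0.5 * (gx[b] + gx[bn]) * (pos[bn, 1] - pos[b, 1]))
        }
        if (j2 < n2) {
          bn <- b + n1
          if (!is.na(id[bn]))
            add_eq(id[b], id[bn], 1, 0.5 * (gy[b] + gy[bn]) * (pos[bn, 2] - pos[b, 2]))
        }
      }
      ne <- length(rows); nu <- length(cells)
      A <- matrix(0, ne + 1, nu)
      bvec <- c(rhs, 0)
      for (e in seq_len(ne)) {
        A[e, rows[[e]][1]] <- -1
        A[e, rows[[e]][2]] <- 1
      }
      A[ne + 1, 1] <- 1   # gauge row
      sol <- qr.solve(A, bvec)
      Fout[cells] <- sol - min(sol)
    }
    if (any(is.finite(Fout))) Fout <- Fout - min(Fout, na.rm = TRUE)
    out <- fes(grid$mids, Fout, counts = matrix(grid$count_z, n1, n2))
    out$positions <- pos
    out
  }
}

# 4-connected component labelling of a logical matrix
label_components <- function(defined) {
  n1 <- nrow(defined); n2 <- ncol(defined)
  comp <- matrix(0L, n1, n2)
  cur <- 0L
  for (start in which(defined)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      b <- queue[1]; queue <- queue[-1]
      j1 <- (b - 1) %% n1 + 1; j2 <- (b - 1) %/% n1 + 1
      for (nb in c(if (j1 > 1) b - 1, if (j1 < n1) b + 1,
                   if (j2 > 1) b - n1, if (j2 < n2) b + n1)) {
        if (defined[nb] && comp[nb] == 0L) {
          comp[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  comp
}

#' Stratification plan for windowed eABF
#'
#' Splits the CV domain into non-overlapping windows separated by harmonic
#' walls, each with its own start configuration and duration.
#'
#' @param breaks for 1D stratification along CV 1: vector of interior break
#'   points; windows tile `[lower, upper]`
#' @param grid the [bias_grid()] being stratified
#' @param starts list of per-window start coordinates (configuration space)
#' @param n_steps per-window step count (recycled)
#' @return object of class `stratification_plan`
#' @export
stratification_plan <- function(breaks, grid, starts, n_steps) {
  bounds <- c(grid$lower[1], sort(breaks), grid$upper[1])
  if (any(duplicated(bounds))) stop("overlapping or duplicate window bounds")
  nw <- length(bounds) - 1
  stopifnot(length(starts) == nw)
  windows <- lapply(seq_len(nw), function(w) {
    lo <- grid$lower; hi <- grid$upper
    lo[1] <- bounds[w]; hi[1] <- bounds[w + 1]
    list(lo = lo, hi = hi)
  })
  structure(list(windows = windows, starts = starts,
                 n_steps = rep_len(n_steps, nw)),
            class = "stratification_plan")
}

#' Stratified eABF: windowed runs merged bin-wise
#'
#' Each window run starts from the inherited grid statistics (so the bias is
#' warm-started from an exploratory run) and confines lambda with soft
#' one-sided harmonic walls; adjacent windows therefore overlap over the
#' wall skirt. The merged grid is the inherited grid plus the bin-wise sum
#' of every window's new counts and force sums.
#'
#' @param potential,config,cvs,extended as in [run_eabf()]
#' @param plan a [stratification_plan()]
#' @param inherited a [bias_grid()] with exploratory statistics (or a fresh
#'   grid)
#' @param seed master seed; window w uses a deterministic sub-seed
#' @param wall_k wall force constant
#' @return merged [bias_grid()]
#' @export
stratified_eabf <- function(potential, config, cvs, plan, inherited, extended,
                            seed, wall_k = 100) {
  merged <- inherited
  for (w in seq_along(plan$windows)) {
    res <- run_eabf(potential, config, cvs, inherited, extended,
                    n_steps = plan$n_steps[w],
                    seed = substream_seed(seed, paste0("window", w)),
                    start = plan$starts[[w]], window = plan$windows[[w]],
                    wall_k = wall_k)
    merged$count_z <- merged$count_z + (res$grid$count_z - inherited$count_z)
    merged$sum_lambda <- merged$sum_lambda + (res$grid$sum_lambda - inherited$sum_lambda)
    merged$sum_z <- merged$sum_z + (res$grid$sum_z - inherited$sum_z)
    merged$count_l <- merged$count_l + (res$grid$count_l - inherited$count_l)
    merged$sum_force <- merged$sum_force + (res$grid$sum_force - inherited$sum_force)
  }
  merged
}

#' Convergence report over grid snapshots
#'
#' @param snapshots list of [bias_grid()]s taken at increasing simulation
#'   time
#' @param temperature temperature for the CZAR gradient
#' @return data.frame with per-snapshot RMS gradient change vs the previous
#'   snapshot, fraction of bins at full_samples, and min/median bin counts
#' @export
convergence_report <- function(snapshots, temperature = 300) {
  if (length(snapshots) < 2) stop("need at least 2 snapshots")
  grads <- lapply(snapshots, function(g) czar_gradient(g, temperature))
  out <- data.frame(snapshot = seq_along(snapshots), rms_change = NA_real_,
                    frac_full = NA_real_, min_count = NA_real_,
                    median_count = NA_real_)
  for (i in seq_along(snapshots)) {
    g <- snapshots[[i]]
    out$frac_full[i] <- mean(g$count_l >= g$full_samples)
    out$min_count[i] <- min(g$count_z)
    out$median_count[i] <- stats::median(g$count_z)
    if (i > 1) {
      dd <- grads[[i]] - grads[[i - 1]]
      out$rms_change[i] <- sqrt(mean(dd[is.finite(dd)]^2))
    }
  }
  out
}

#' Block (bootstrap-like) standard error of a mean
#'
#' Splits a correlated series into `n_blocks` contiguous blocks and reports
#' the standard error of the mean estimated from block means.
#'
#' @param x numeric series
#' @param n_blocks number of blocks
#' @return standard-error estimate
#' @export
block_error <- function(x, n_blocks = 10) {
  n <- length(x)
  stopifnot(n >= n_blocks, n_blocks >= 2)
  bs <- split(x, cut(seq_len(n), n_blocks, labels = FALSE))
  bm <- vapply(bs, mean, numeric(1))
  stats::sd(bm) / sqrt(n_blocks)
}
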