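#' Run umbrella sampling along a path
#'
#' Each image of the (refined) string becomes one window: Langevin sampling
#' under the sum of harmonic restraints 0.5*k_i*(z_i - c_i)^2 at the image's
#' raw-unit CV centre, with the first `burn_in` fraction of each window
#' discarded.
#'
#' @param potential a [model_potential()]
#' @param config a [langevin_config()]
#' @param cvs a `cv_map`
#' @param path a [path_string()] whose images define the window centres
#' @param restraint_k per-CV force constants in raw units (kcal/mol/U^2);
#'   CVs named in `exclude` get no restraint
#' @param n_steps steps per window
#' @param seed master seed
#' @param burn_in fraction of each window discarded before recording
#' @param exclude character vector of CV names excluded from restraint
#' @param x0_fn function(raw_center) giving the start configuration
#'   (defaults to the centre itself for coordinate CVs)
#' @param record_every thinning interval for the recorded CV series
#' @return object of class `window_ensemble`: `windows` (list of
#'   `center`, `k`, `samples`, `alpha`), `temperature`, `path`
#' @export
run_umbrella <- function(potential, config, cvs, path, restraint_k, n_steps,
                         seed, burn_in = 0.1, exclude = character(0),
                         x0_fn = NULL, record_every = 1) {
  M <- nrow(path$images)
  D <- ncol(path$images)
  kvec <- rep_len(restraint_k, D)
  nm <- colnames(path$images)
  if (length(exclude) && !is.null(nm)) kvec[nm %in% exclude] <- 0
  if (is.null(x0_fn)) {
    if (cvs$ncv != potential$dimension)
      stop("x0_fn is required when the CVs do not span configuration space")
    x0_fn <- function(center_raw) center_raw
  }
  alpha <- seq(0, 1, length.out = M)
  burn <- max(1, floor(burn_in * n_steps))
  windows <- vector("list", M)
  for (m in seq_len(M)) {
    center_raw <- norm_invert(path$map, path$images[m, ])
    ff <- restrained_force(potential, cvs, center_raw, kvec)
    tr <- simulate_langevin(potential, config, x0_fn(center_raw), n_steps,
                            seed = substream_seed(seed, paste0("window", m)),
                            force_fn = ff)
    rows <- seq(burn + 1, n_steps, by = record_every)
    zs <- t(apply(tr[rows, , drop = FALSE], 1, cvs$value))
    if (ncol(zs) != cvs$ncv) zs <- t(zs)
    colnames(zs) <- nm
    mu <- colMeans(zs); sdv <- apply(zs, 2, stats::sd)
    if (any(kvec > 0 & abs(mu - center_raw) > 5 * pmax(sdv, 1e-12)))
      warning(sprintf("window %d mean drifted > 5 sigma from its centre (poor restraint)", m))
    windows[[m]] <- list(center = center_raw, k = kvec, samples = zs,
                         alpha = alpha[m])
  }
  structure(list(windows = windows, temperature = config$temperature,
                 path = path),
            class = "window_ensemble")
}

#' @export
print.window_ensemble <- function(x, ...) {
  ns <- vapply(x$windows, function(w) nrow(w$samples), numeric(1))
  cat(sprintf("window_ensemble: %d windows x %d CVs, %g..%g samples/window, T = %g K\n",
              length(x$windows), ncol(x$windows[[1]]$samples),
              min(ns), max(ns), x$temperature))
  invisible(x)
}

#' Umbrella-Integration local mean-force estimate
#'
#' The per-window Gaussian estimate of the unbiased mean force at CV value z:
#' `(z - zbar)/(beta*sigma2) - k*(z - center)`, exact for Gaussian window
#' statistics on a quadratic PMF.
#'
#' @param z evaluation point(s)
#' @param zbar window sample mean
#' @param sigma2 window sample variance
#' @param k restraint force constant
#' @param center restraint centre
#' @param temperature temperature in K
#' @return local mean-force estimate (kcal/mol/U)
#' @export
ui_local_gradient <- function(z, zbar, sigma2, k, center, temperature = 300)
  (z - zbar) * kT(temperature) / sigma2 - k * (z - center)

#' PMF along the path by Umbrella Integration with the chain rule
#'
#' Per window and CV, the local mean-force estimate [ui_local_gradient()] is
#' evaluated at each window centre, combined across windows with weights
#' proportional to sample count times the window's normal density at the
#' evaluation point, projected onto the path tangent dz/dalpha (central
#' differences of the raw-unit window centres), and integrated over alpha by
#' cumulative trapezoid. Restraint-free CVs (k = 0) are skipped.
#'
#' @param ensemble a [window_ensemble()]
#' @param min_samples windows with fewer samples are excluded (warning)
#' @return a [fes()] over alpha
#' @export
pmf_umbrella_integration <- function(ensemble, min_samples = 50) {
  wins <- ensemble$windows
  keep <- vapply(wins, function(w) nrow(w$samples) >= min_samples, logical(1))
  if (!all(keep)) {
    warning(sprintf("%d window(s) excluded (< %d samples)", sum(!keep), min_samples))
    wins <- wins[keep]
  }
  if (length(wins) < 2) stop("fewer than 2 usable windows")
  kbt <- kT(ensemble$temperature)
  M <- length(wins)
  D <- length(wins[[1]]$center)
  alpha <- vapply(wins, `[[`, numeric(1), "alpha")
  centers <- do.call(rbind, lapply(wins, `[[`, "center"))
  zbar <- do.call(rbind, lapply(wins, function(w) colMeans(w$samples)))
  sig2 <- do.call(rbind, lapply(wins, function(w) apply(w$samples, 2, stats::var)))
  nsamp <- vapply(wins, function(w) nrow(w$samples), numeric(1))
  kmat <- do.call(rbind, lapply(wins, `[[`, "k"))
  active <- which(kmat[1, ] > 0)
  # adjacent-window overlap check (per active CV, product of coefficients)
  for (m in seq_len(M - 1)) {
    ov <- prod(vapply(active, function(i) {
      mu1 <- zbar[m, i]; mu2 <- zbar[m + 1, i]
      s <- sqrt((sig2[m, i] + sig2[m + 1, i]) / 2)
      2 * stats::pnorm(-abs(mu1 - mu2) / (2 * s))
    }, numeric(1)))
    if (ov < 0.01)
      warning(sprintf("windows %d and %d barely overlap (coefficient %.2g)", m, m + 1, ov))
  }
  # path tangent by central differences of raw centres over alpha
  tangent <- matrix(NA_real_, M, D)
  for (i in seq_len(D)) {
    tangent[2:(M - 1), i] <- (centers[3:M, i] - centers[1:(M - 2), i]) /
      (alpha[3:M] - alpha[1:(M - 2)])
    tangent[1, i] <- (centers[2, i] - centers[1, i]) / (alpha[2] - alpha[1])
    tangent[M, i] <- (centers[M, i] - centers[M - 1, i]) / (alpha[M] - alpha[M - 1])
  }
  dFda <- numeric(M)
  for (m in seq_len(M)) {
    z <- centers[m, ]
    for (i in active) {
      # normal-density window weights at z_i
      lw <- log(nsamp) + stats::dnorm(z[i], zbar[, i], sqrt(sig2[, i]), log = TRUE)
      lw <- lw - max(lw)
      wgt <- exp(lw); wgt <- wgt / sum(wgt)
      gi <- sum(wgt * ui_local_gradient(z[i], zbar[, i], sig2[, i],
                                        kmat[, i], centers[, i],
                                        ensemble$temperature))
      dFda[m] <- dFda[m] + gi * tangent[m, i]
    }
  }
  F <- c(0, cumsum(0.5 * (dFda[-1] + dFda[-M]) * diff(alpha)))
  fes(list(alpha), F, counts = nsamp, axis_names = "alpha")
}

# log-sum-exp over columns of a matrix
lse <- function(m) {
  mx <- apply(m, 2, max)
  mx + log(colSums(exp(sweep(m, 2, mx))))
}

#' Solve MBAR window free energies and unbiased sample weights
#'
#' Self-consistent iteration of the multistate Bennett acceptance ratio
#' equations, in log space, to tolerance `tol` on the free energies.
#'
#' @param u_kn K x N matrix of reduced bias energies (beta * U_bias) of every
#'   pooled sample under every window
#' @param n_k samples contributed per window
#' @param tol convergence tolerance on max |delta f|
#' @param max_iter iteration cap
#' @param f_init optional initial reduced free energies (a good guess, e.g.
#'   from Umbrella Integration, cuts the iteration count substantially)
#' @return list with `f` (window reduced free energies, f[1] = 0) and
#'   `weights` (unbiased per-sample weights summing to 1)
#' @export
mbar_solve <- function(u_kn, n_k, tol = 1e-8, max_iter = 5000, f_init = NULL) {
  K <- nrow(u_kn); N <- ncol(u_kn)
  stopifnot(length(n_k) == K, sum(n_k) == N)
  f <- if (is.null(f_init)) numeric(K) else f_init - f_init[1]
  logn <- log(n_k)
  for (it in seq_len(max_iter)) {
    logD <- lse(logn + f - u_kn)          # per-sample log denominator
    fnew <- -lse(t(sweep(-u_kn, 2, logD)))  # K-vector
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) { f <- fnew; break }
    f <- fnew
    if (it == max_iter) warning("MBAR did not converge to tolerance")
  }
  logD <- lse(logn + f - u_kn)
  lw <- -logD
  lw <- lw - max(lw)
  w <- exp(lw); w <- w / sum(w)
  list(f = f, weights = w)
}

#' PMF over arbitrary observables by MBAR with Gaussian KDE
#'
#' Pools all window samples, solves the MBAR equations for the window free
#' energies and per-sample unbiased weights, then estimates the density of
#' 1-2 target observables by weighted Gaussian kernel density estimation
#' (Scott's-rule bandwidth by default) and reports
#' `F = -kT ln(density)`, min-gauged to 0.
#'
#' @param ensemble a [window_ensemble()]
#' @param observables function mapping a CV sample row to 1 or 2 observable
#'   values (default: the first CV)
#' @param grid list with `min`, `max`, `nbins` per observable axis
#' @param bandwidth kernel bandwidth(s); `NULL` for Scott's rule
#' @param tol MBAR convergence tolerance
#' @param f_init optional initial window reduced free energies passed to
#'   [mbar_solve()] (e.g. beta times a UI profile at the window centres)
#' @return a [fes()] with per-bin effective sample counts
#' @export
pmf_mbar <- function(ensemble, observables = function(z) z[1], grid,
                     bandwidth = NULL, tol = 1e-8, f_init = NULL) {
  wins <- ensemble$windows
  K <- length(wins)
  n_k <- vapply(wins, function(w) nrow(w$samples), numeric(1))
  Z <- do.call(rbind, lapply(wins, `[[`, "samples"))
  N <- nrow(Z)
  beta <- 1 / kT(ensemble$temperature)
  u_kn <- matrix(NA_real_, K, N)
  for (k in seq_len(K)) {
    dz <- sweep(Z, 2, wins[[k]]$center)
    u_kn[k, ] <- beta * as.numeric(dz^2 %*% (wins[[k]]$k / 2))
  }
  solm <- mbar_solve(u_kn, n_k, tol = tol, f_init = f_init)
  w <- solm$weights
  ess <- 1 / sum(w^2)
  obs <- tryCatch({
    v <- observables(Z)
    if (is.matrix(v) && nrow(v) == N) v
    else if (length(v) == N) matrix(v, ncol = 1)
    else stop("not vectorised")
  }, error = function(e) {
    v <- t(apply(Z, 1, observables))
    if (nrow(v) == 1) t(v) else v
  })
  dobs <- ncol(obs)
  nb <- rep_len(grid$nbins, dobs)
  lo <- rep_len(grid$min, dobs); hi <- rep_len(grid$max, dobs)
  mids <- lapply(seq_len(dobs), function(j) {
    e <- seq(lo[j], hi[j], length.out = nb[j] + 1)
    (e[-1] + e[-length(e)]) / 2
  })
  if (is.null(bandwidth)) {
    wsd <- vapply(seq_len(dobs), function(j) {
      mu <- sum(w * obs[, j])
      sqrt(sum(w * (obs[, j] - mu)^2))
    }, numeric(1))
    bandwidth <- wsd * ess^(-1 / (dobs + 4))
  }
  bandwidth <- rep_len(bandwidth, dobs)
  if (dobs == 1) {
    dens <- vapply(mids[[1]], function(g)
      sum(w * stats::dnorm(g, obs[, 1], bandwidth[1])), numeric(1))
    effn <- vapply(mids[[1]], function(g) {
      kk <- stats::dnorm(g, obs[, 1], bandwidth[1])
      s1 <- sum(w * kk)
      if (s1 <= 0) 0 else s1^2 / sum((w * kk)^2)
    }, numeric(1))
    vals <- ifelse(dens > 0, -log(dens) / beta, NA_real_)
    fes(mids, vals, counts = effn, axis_names = "obs1")
  } else {
    dens <- matrix(0, nb[1], nb[2])
    effd <- matrix(0, nb[1], nb[2])
    for (i1 in seq_len(nb[1])) {
      k1 <- stats::dnorm(mids[[1]][i1], obs[, 1], bandwidth[1])
      for (i2 in seq_len(nb[2])) {
        kk <- k1 * stats::dnorm(mids[[2]][i2], obs[, 2], bandwidth[2])
        s1 <- sum(w * kk)
        dens[i1, i2] <- s1
        effd[i1, i2] <- if (s1 <= 0) 0 else s1^2 / sum((w * kk)^2)
      }
    }
    vals <- ifelse(dens > 0, -log(dens) / beta, NA_real_)
    fes(mids, vals, counts = effd, axis_names = c("obs1", "obs2"))
  }
}

#' Extrema and barriers of a 1D free-energy profile
#'
#' After optional moving-average smoothing, locates local minima and maxima
#' by sign changes of the discrete differences (ties broken toward lower
#' alpha; profile endpoints count as minima when the profile rises away from
#' them). The barrier between adjacent minima is the maximum value between
#' them minus the left minimum.
#'
#' @param profile a 1D [fes()] (or list with `midpoints`, `values`)
#' @param smoothing odd moving-average window length (1 = none)
#' @return list with data.frames `minima`, `maxima` (alpha, value,
#'   boundary flag) and `barriers` (from, to, barrier: left-minimum to
#'   intervening maximum)
#' @export
profile_extrema <- function(profile, smoothing = 1) {
  a <- profile$midpoints[[1]]
  y <- profile$values
  if (length(y) < 3) stop("need at least 3 profile points")
  if (smoothing > 1) {
    hw <- smoothing %/% 2
    ys <- y
    for (i in seq_along(y)) {
      j <- max(1, i - hw):min(length(y), i + hw)
      ys[i] <- mean(y[j])
    }
    y <- ys
  }
  n <- length(y)
  d <- diff(y)
  mins <- integer(0); maxs <- integer(0)
  if (d[1] > 0) mins <- c(mins, 1L)
  if (d[1] < 0) maxs <- c(maxs, 1L)
  for (i in 2:(n - 1)) {
    if (d[i - 1] < 0 && d[i] > 0) mins <- c(mins, i)
    if (d[i - 1] > 0 && d[i] < 0) maxs <- c(maxs, i)
  }
  if (d[n - 1] < 0) mins <- c(mins, n)
  if (d[n - 1] > 0) maxs <- c(maxs, n)
  barr <- NULL
  if (length(mins) >= 2) {
    barr <- data.frame(from = numeric(0), to = numeric(0), barrier = numeric(0))
    for (j in seq_len(length(mins) - 1)) {
      i1 <- mins[j]; i2 <- mins[j + 1]
      seg <- y[i1:i2]
      barr[j, ] <- c(a[i1], a[i2], max(seg) - y[i1])
    }
  }
  list(minima = data.frame(alpha = a[mins], value = y[mins],
                           boundary = mins %in% c(1L, n)),
       maxima = data.frame(alpha = a[maxs], value = y[maxs],
                           boundary = maxs %in% c(1L, n)),
       barriers = barr)
}

#' Arrhenius rate ratio of two activated processes
#'
#' Assuming equal pre-exponential factors, the rate ratio of a slow process
#' with barrier `barrier_slow` to a fast one with `barrier_fast` is
#' `exp((barrier_slow - barrier_fast)/kT)`.
#'
#' @param barrier_slow,barrier_fast barriers in kcal/mol
#' @param temperature temperature in K
#' @return the speed-up factor of the fast process over the slow one
#' @export
arrhenius_ratio <- function(barrier_slow, barrier_fast, temperature = 300) {
  stopifnot(temperature > 0)
  exp((barrier_slow - barrier_fast) / kT(temperature))
}

#' Simulation-campaign time bookkeeping
#'
#' Totals (in microseconds) for a stratified free-energy campaign — one
#' exploratory run plus per-window refinement runs — and for an
#' umbrella-sampling campaign of equally long windows.
#'
#' @param exploratory_ns exploratory run length, ns
#' @param n_windows number of stratification windows
#' @param window_ns per-window run length, ns
#' @return total sampling in microseconds
#' @export
stratified_campaign_us <- function(exploratory_ns, n_windows, window_ns)
  (exploratory_ns + n_windows * window_ns) / 1000

#' @rdname stratified_campaign_us
#' @param n_images number of umbrella windows (images)
#' @param ns_per_image sampling per image, ns
#' @export
umbrella_campaign_us <- function(n_images, ns_per_image)
  n_images * ns_per_image / 1000
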