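#' CV normalization map
#'
#' Normalizes each CV between 0 and 1 by its total variation between the two
#' path endpoints: `normalized = (raw - offset)/scale` with
#' `offset = min(a, b)` and `scale = |b - a|` per CV. Balanced scales keep
#' the equal-arc-length reparametrization from being dominated by CVs with
#' large raw ranges.
#'
#' @param endpoint_a,endpoint_b named numeric CV points (raw units)
#' @param fallback_scale scale used for CVs with zero endpoint variation
#'   (`NULL` makes that an error)
#' @return object of class `normalization_map` with `offset` and `scale`
#' @export
normalize_cvs <- function(endpoint_a, endpoint_b, fallback_scale = NULL) {
  stopifnot(length(endpoint_a) == length(endpoint_b))
  scale <- abs(endpoint_b - endpoint_a)
  offset <- pmin(endpoint_a, endpoint_b)
  zero <- scale == 0
  if (any(zero)) {
    if (is.null(fallback_scale))
      stop(sprintf("zero total variation for CV(s): %s",
                   paste(names(endpoint_a)[zero], collapse = ", ")))
    scale[zero] <- fallback_scale
  }
  structure(list(offset = offset, scale = scale,
                 names = names(endpoint_a)),
            class = "normalization_map")
}

#' Apply / invert a normalization map
#'
#' @param map a [normalization_map()]
#' @param x numeric vector or matrix (rows = points) of raw (resp.
#'   normalized) CV values
#' @return normalized (resp. raw) values, same shape
#' @export
norm_apply <- function(map, x) {
  if (is.matrix(x)) sweep(sweep(x, 2, map$offset), 2, map$scale, `/`)
  else (x - map$offset) / map$scale
}

#' @rdname norm_apply
#' @export
norm_invert <- function(map, x) {
  if (is.matrix(x)) sweep(sweep(x, 2, map$scale, `*`), 2, map$offset, `+`)
  else x * map$scale + map$offset
}

#' Initialize a path string
#'
#' Images linearly interpolate the two endpoints in normalized CV space
#' (the straight-path initial guess); endpoints are locked.
#'
#' @param endpoint_a,endpoint_b named raw-unit CV points
#' @param M number of images (>= 3)
#' @param map optional [normalize_cvs()] map (built from the endpoints by
#'   default)
#' @return object of class `path_string`: `images` (M x D normalized),
#'   `map`, `iteration`, `history`
#' @export
initialize_string <- function(endpoint_a, endpoint_b, M, map = NULL) {
  if (M < 3) stop("a string needs at least 3 images")
  if (is.null(map)) map <- normalize_cvs(endpoint_a, endpoint_b)
  na <- norm_apply(map, endpoint_a)
  nb <- norm_apply(map, endpoint_b)
  t <- seq(0, 1, length.out = M)
  images <- outer(1 - t, na) + outer(t, nb)
  colnames(images) <- map$names
  structure(list(images = images, map = map, iteration = 0L,
                 history = list(), initial = images),
            class = "path_string")
}

#' @export
print.path_string <- function(x, ...) {
  cat(sprintf("path_string: %d images x %d CVs, iteration %d, length %.4f (normalized)\n",
              nrow(x$images), ncol(x$images), x$iteration, path_length(x$images)))
  invisible(x)
}

path_length <- function(images)
  sum(sqrt(rowSums(diff(images)^2)))

# cumulative arc length, one entry per image
arc_lengths <- function(images)
  c(0, cumsum(sqrt(rowSums(diff(images)^2))))

#' Equal-arc-length reparametrization
#'
#' Approximates the string by its piecewise-linear interpolant and places the
#' images at equal spacing along it; endpoints are unchanged. Duplicate
#' adjacent images (zero-length segments) are merged before interpolation.
#' Because redistributed images sit on chords of the previous polyline, the
#' placement is iterated to a fixed point so that adjacent-image distances
#' are equal to within 1e-9 relative.
#'
#' @param path a [path_string()] or a plain image matrix
#' @return object of the same type with repositioned images
#' @export
reparametrize <- function(path) {
  images <- if (inherits(path, "path_string")) path$images else path
  M <- nrow(images)
  new_images <- images
  for (pass in 1:12) {
    keep <- c(TRUE, rowSums(diff(new_images)^2) > 1e-24)
    nodes <- new_images[keep, , drop = FALSE]
    s <- arc_lengths(nodes)
    L <- s[length(s)]
    target <- seq(0, L, length.out = M)
    upd <- matrix(NA_real_, M, ncol(images))
    for (j in seq_len(ncol(images)))
      upd[, j] <- stats::approx(s, nodes[, j], xout = target)$y
    upd[1, ] <- images[1, ]
    upd[M, ] <- images[M, ]
    new_images <- upd
    seg <- sqrt(rowSums(diff(new_images)^2))
    if (diff(range(seg)) <= 1e-9 * mean(seg)) break
  }
  colnames(new_images) <- colnames(images)
  if (inherits(path, "path_string")) {
    path$images <- new_images
    path
  } else new_images
}

#' Swarm-of-trajectories configuration
#'
#' @param restraint_k per-CV restraint force constants in raw units
#'   (kcal/mol/U^2), used for image equilibration
#' @param equil_steps restrained-equilibration steps per image
#' @param swarm_size number of unbiased trajectories per image
#' @param swarm_steps length of each unbiased trajectory in steps
#' @param snapshot_every restrained steps between successive swarm launch
#'   snapshots
#' @param damping drift multiplier (1 = undamped, the standard update)
#' @return object of class `swarm_config`
#' @export
swarm_config <- function(restraint_k, equil_steps = 200, swarm_size = 20,
                         swarm_steps = 20, snapshot_every = 10, damping = 1) {
  stopifnot(all(restraint_k > 0), swarm_size >= 1, swarm_steps >= 1)
  structure(list(restraint_k = restraint_k, equil_steps = equil_steps,
                 swarm_size = swarm_size, swarm_steps = swarm_steps,
                 snapshot_every = snapshot_every, damping = damping),
            class = "swarm_config")
}

# restrained force field: -grad U - sum_i k_i (z_i - c_i) grad z_i
restrained_force <- function(potential, cvs, center_raw, k_raw) {
  function(x) {
    z <- cvs$value(x)
    J <- cvs$jacobian(x)
    -potential$gradient(x) - as.numeric(t(J) %*% (k_raw * (z - center_raw)))
  }
}

#' One swarms-of-trajectories string iteration
#'
#' For each interior image: (1) restrained Langevin equilibration at the
#' image's raw-unit CV centre; (2) launch `swarm_size` short unbiased
#' trajectories from snapshots of the restrained run, velocities resampled
#' from Maxwell-Boltzmann; (3) estimate the drift as the swarm mean of the
#' final-minus-initial CV displacement in normalized space; (4) move the
#' image by the drift (times `damping`). Endpoints stay fixed. The updated
#' string is reparametrized and appended to the history.
#'
#' @param path a [path_string()]
#' @param potential a [model_potential()]
#' @param config a [langevin_config()]
#' @param cvs a `cv_map` from configuration space to the string's CVs
#' @param cfg a [swarm_config()]
#' @param seed master seed (deterministic sub-seeds per image/member)
#' @param x0_fn function(raw_center) giving a start configuration for the
#'   restrained equilibration; defaults to the raw centre itself when the CVs
#'   are coordinates (`cvs$ncv == potential$dimension`)
#' @return the updated [path_string()]; attribute `"drift_se"` holds the
#'   per-image standard error of the drift norm
#' @export
swarm_iteration <- function(path, potential, config, cvs, cfg, seed,
                            x0_fn = NULL) {
  M <- nrow(path$images)
  D <- ncol(path$images)
  if (is.null(x0_fn)) {
    if (cvs$ncv != potential$dimension)
      stop("x0_fn is required when the CVs do not span configuration space")
    x0_fn <- function(center_raw) center_raw
  }
  new_images <- path$images
  drift_se <- rep(NA_real_, M)
  for (m in 2:(M - 1)) {
    center_raw <- norm_invert(path$map, path$images[m, ])
    ff <- restrained_force(potential, cvs, center_raw, cfg$restraint_k)
    eq <- simulate_langevin(potential, config, x0_fn(center_raw),
                            cfg$equil_steps + cfg$swarm_size * cfg$snapshot_every,
                            seed = substream_seed(seed, sprintf("it%d-img%d-eq", path$iteration, m)),
                            force_fn = ff)
    snap_rows <- cfg$equil_steps + cfg$snapshot_every * seq_len(cfg$swarm_size)
    drifts <- matrix(NA_real_, cfg$swarm_size, D)
    for (s in seq_len(cfg$swarm_size)) {
      xs <- eq[snap_rows[s], ]
      tr <- simulate_langevin(potential, config, xs, cfg$swarm_steps,
                              seed = substream_seed(seed, sprintf("it%d-img%d-sw%d", path$iteration, m, s)))
      z0 <- norm_apply(path$map, cvs$value(xs))
      z1 <- norm_apply(path$map, cvs$value(tr[cfg$swarm_steps, ]))
      drifts[s, ] <- z1 - z0
    }
    mean_drift <- colMeans(drifts)
    drift_se[m] <- sqrt(sum(apply(drifts, 2, stats::var)) / cfg$swarm_size)
    new_images[m, ] <- path$images[m, ] + cfg$damping * mean_drift
  }
  path$images <- new_images
  path <- reparametrize(path)
  path$iteration <- path$iteration + 1L
  path$history[[length(path$history) + 1]] <- path$images
  attr(path, "drift_se") <- drift_se
  path
}

#' Run string iterations to convergence
#'
#' Repeats [swarm_iteration()] up to `max_iter` times; convergence is
#' declared when the RMSD-vs-initial-string series changes by less than
#' `rel_tol` relative over the trailing `window` iterations.
#'
#' @inheritParams swarm_iteration
#' @param max_iter maximum number of iterations
#' @param window trailing window for the plateau check
#' @param rel_tol relative change threshold
#' @return the final [path_string()] (history accumulated)
#' @export
optimize_string <- function(path, potential, config, cvs, cfg, seed,
                            max_iter = 60, window = 20, rel_tol = 0.01,
                            x0_fn = NULL) {
  for (it in seq_len(max_iter)) {
    path <- swarm_iteration(path, potential, config, cvs, cfg,
                            seed = substream_seed(seed, paste0("iter", it)),
                            x0_fn = x0_fn)
    if (it >= window + 5) {
      rmsd <- string_convergence(path)
      recent <- utils::tail(rmsd, window)
      if (diff(range(recent)) < rel_tol * max(mean(recent), 1e-12)) break
    }
  }
  path
}

#' RMSD of each iteration's string from the initial string
#'
#' RMSD is taken elementwise over all images and CVs in normalized space:
#' `sqrt(sum((P - P0)^2) / (M*D))`.
#'
#' @param path a [path_string()] with history
#' @return numeric vector, one value per iteration
#' @export
string_convergence <- function(path) {
  if (length(path$history) == 0) stop("empty history: no iterations recorded")
  init <- path$initial
  if (is.null(init)) {
    M <- nrow(path$images)
    t <- seq(0, 1, length.out = M)
    init <- outer(1 - t, path$images[1, ]) + outer(t, path$images[M, ])
  }
  vapply(path$history, function(P)
    sqrt(sum((P - init)^2) / length(P)), numeric(1))
}

#' Average string over the last iterations
#'
#' Image-wise mean over the last `last_n` recorded iterations, followed by
#' one reparametrization.
#'
#' @param path a [path_string()] with history
#' @param last_n number of trailing iterations to average (capped at the
#'   history length)
#' @return a [path_string()] holding the averaged images
#' @export
average_string <- function(path, last_n = 50) {
  H <- path$history
  if (length(H) == 0) stop("empty history: nothing to average")
  last_n <- min(last_n, length(H))
  sel <- H[(length(H) - last_n + 1):length(H)]
  avg <- Reduce(`+`, sel) / length(sel)
  out <- path
  out$images <- avg
  reparametrize(out)
}

#' Uplift a low-dimensional string into a larger CV space
#'
#' For each image of the low-dimensional string, runs sampling restrained
#' only on the low-dimensional CVs and sets the extra CV coordinates to
#' their sampled means; each extra-CV profile is then smoothed along the
#' path with a window-3 moving average, and the string is reparametrized in
#' the full normalized space.
#'
#' @param low_path a [path_string()] over the low-D CVs
#' @param potential a [model_potential()]
#' @param config a [langevin_config()]
#' @param cvs_full `cv_map` for the full CV set
#' @param low_idx indices of the low-D CVs within the full set
#' @param map_full [normalization_map()] for the full CV set
#' @param restraint_k raw-unit restraint constants for the low-D CVs
#' @param n_steps sampling steps per image
#' @param seed master seed
#' @param var_warn_factor warn if an extra CV's per-image variance exceeds
#'   this multiple of its squared normalization scale
#' @return a [path_string()] in the full CV space
#' @export
uplift_path <- function(low_path, potential, config, cvs_full, low_idx,
                        map_full, restraint_k, n_steps = 2000, seed = 1,
                        var_warn_factor = 1) {
  M <- nrow(low_path$images)
  Dfull <- cvs_full$ncv
  extra_idx <- setdiff(seq_len(Dfull), low_idx)
  cvs_low <- structure(list(ncv = length(low_idx),
                            value = function(x) cvs_full$value(x)[low_idx],
                            jacobian = function(x) cvs_full$jacobian(x)[low_idx, , drop = FALSE]),
                       class = "cv_map")
  raw_images <- matrix(NA_real_, M, Dfull)
  for (m in seq_len(M)) {
    center_low <- norm_invert(low_path$map, low_path$images[m, ])
    ff <- restrained_force(potential, cvs_low, center_low, restraint_k)
    x0 <- rep(0, potential$dimension)
    x0[seq_along(center_low)] <- center_low
    tr <- simulate_langevin(potential, config, x0, n_steps,
                            seed = substream_seed(seed, paste0("uplift", m)),
                            force_fn = ff)
    zfull <- t(apply(tr[(n_steps %/% 5):n_steps, , drop = FALSE], 1, cvs_full$value))
    raw_images[m, low_idx] <- center_low
    raw_images[m, extra_idx] <- colMeans(zfull)[extra_idx]
    vr <- apply(zfull, 2, stats::var)[extra_idx]
    if (any(vr > var_warn_factor * map_full$scale[extra_idx]^2))
      warning(sprintf("uplift: image %d extra-CV variance above threshold", m))
  }
  # window-3 moving-average smoothing of the extra-CV profiles (endpoints kept)
  for (j in extra_idx) {
    y <- raw_images[, j]
    sm <- y
    for (m in 2:(M - 1)) sm[m] <- mean(y[(m - 1):(m + 1)])
    raw_images[, j] <- sm
  }
  images <- norm_apply(map_full, raw_images)
  colnames(images) <- map_full$names
  out <- structure(list(images = images, map = map_full, iteration = 0L,
                        history = list()),
                   class = "path_string")
  out <- reparametrize(out)
  out$initial <- out$images
  out
}

#' Refine a path to more images by linear interpolation
#'
#' Piecewise-linear interpolation along the existing string followed by
#' equal spacing; endpoints preserved.
#'
#' @param path a [path_string()]
#' @param n_images new number of images (>= current, >= 3)
#' @return refined [path_string()]
#' @export
refine_path <- function(path, n_images) {
  if (n_images < 3) stop("need at least 3 images")
  images <- path$images
  keep <- c(TRUE, rowSums(diff(images)^2) > 1e-24)
  nodes <- images[keep, , drop = FALSE]
  s <- arc_lengths(nodes)
  target <- seq(0, s[length(s)], length.out = n_images)
  new_images <- matrix(NA_real_, n_images, ncol(images))
  for (j in seq_len(ncol(images)))
    new_images[, j] <- stats::approx(s, nodes[, j], xout = target)$y
  new_images[1, ] <- images[1, ]
  new_images[n_images, ] <- images[nrow(images), ]
  colnames(new_images) <- colnames(images)
  new_images <- reparametrize(new_images)
  path$images <- new_images
  path$history <- list()
  path$initial <- new_images
  path$iteration <- 0L
  path
}

#' Project CV points onto a path's progress coordinate
#'
#' For each raw-unit CV point, finds the closest point on the piecewise-
#' linear string (in normalized CV space) and returns its normalized arc
#' length alpha in `[0, 1]`. This turns an arbitrary CV sample into a
#' progress-along-the-transition observable, e.g. for reweighting umbrella
#' samples onto the path.
#'
#' @param path a [path_string()]
#' @param points_raw numeric matrix (n x D) or vector of raw CV values
#' @return numeric vector of alpha values
#' @export
path_alpha <- function(path, points_raw) {
  imgs <- path$images
  M <- nrow(imgs)
  s <- arc_lengths(imgs)
  stot <- s[M]
  P <- norm_apply(path$map, if (is.matrix(points_raw)) points_raw
                  else matrix(points_raw, nrow = 1))
  n <- nrow(P)
  best_d2 <- rep(Inf, n)
  best_alpha <- rep(NA_real_, n)
  for (m in seq_len(M - 1)) {
    A <- imgs[m, ]; B <- imgs[m + 1, ]
    AB <- B - A
    len2 <- sum(AB^2)
    if (len2 < 1e-24) next
    t <- pmin(pmax((sweep(P, 2, A) %*% AB) / len2, 0), 1)[, 1]
    proj <- outer(rep(1, n), A) + outer(t, AB)
    d2 <- rowSums((P - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_alpha[upd] <- (s[m] + t[upd] * sqrt(len2)) / stot
  }
  best_alpha
}

#' Export / import a string as tabular text
#'
#' One row per image: iteration, image index, then raw-unit CV values.
#'
#' @param path a [path_string()]
#' @param file output path
#' @return `file` invisibly
#' @export
write_string <- function(path, file) {
  raw <- norm_invert(path$map, path$images)
  df <- data.frame(iteration = path$iteration, image = seq_len(nrow(raw)), raw)
  names(df)[-(1:2)] <- path$map$names
  utils::write.table(df, file, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(file)
}

#' @rdname write_string
#' @param map the [normalization_map()] to re-normalize with
#' @export
read_string <- function(file, map) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  raw <- as.matrix(df[, -(1:2), drop = FALSE])
  images <- norm_apply(map, raw)
  colnames(images) <- map$names
  structure(list(images = images, map = map,
                 iteration = as.integer(df$iteration[1]), history = list()),
            class = "path_string")
}
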