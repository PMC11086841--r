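flat_pot_2 <- function()
  model_potential(1, function(x) 0, function(x) 0, domain = rbind(-6, 6))

test_that("flat landscape gives vanishing mean force and even occupancy", {
  pot <- flat_pot_2()
  g <- bias_grid(-1.5, 1.5, 12, k = 25, full_samples = 500)
  ext <- extended_state(k = 25, mass = 1, friction = 2)
  cfg <- ud_config(dt = 0.005)
  res <- run_eabf(pot, cfg, cv_identity(1), g, ext, n_steps = 3e5, seed = 2,
                  start = 0)
  mf <- res$grid$sum_force[, 1] / pmax(res$grid$count_l, 1)
  inner <- res$grid$count_l > 2000
  # per-bin noise of the instantaneous coupling force is sqrt(2 kT k)
  expect_lt(max(abs(mf[inner])), 0.8)
  occ <- res$grid$count_z / sum(res$grid$count_z)
  expect_lt(max(occ) / max(min(occ[occ > 0]), 1e-12), 4)
})

test_that("CZAR recovers a harmonic mean force within 5 percent", {
  pot <- harmonic_potential(2, 1)
  g <- bias_grid(-2, 2, 40, k = 100, full_samples = 500)
  ext <- extended_state(k = 100, mass = 1, friction = 2)
  cfg <- ud_config(dt = 0.005)
  res <- run_eabf(pot, cfg, cv_identity(1), g, ext, n_steps = 6e5, seed = 7,
                  start = 0)
  gr <- czar_gradient(res$grid, 300, min_count = 200)
  mids <- res$grid$mids[[1]]
  ok <- is.finite(gr[, 1]) & res$grid$count_z > 3000
  slope <- stats::coef(stats::lm(gr[ok, 1] ~ mids[ok]))[2]
  expect_equal(unname(slope), 2, tolerance = 0.05)
})

test_that("CZAR estimator is exact on closed-form coupled Gaussian samples", {
  # rho(z, lambda) ~ exp(-beta [kappa/2 z^2 + k/2 (z - lambda)^2])
  kappa <- 2; k <- 100; beta <- 1 / kT(300)
  P <- beta * matrix(c(kappa + k, -k, -k, k), 2, 2)
  S <- solve(P)
  set.seed(1)
  n <- 1e6
  xy <- matrix(stats::rnorm(2 * n), n, 2) %*% chol(S)
  g <- bias_grid(-2, 2, 40, k = k, full_samples = 500)
  idx <- pmin(pmax(floor((xy[, 1] - g$lower) / g$width) + 1, 1), 40)
  g$count_z <- as.numeric(tabulate(idx, 40))
  sl <- rowsum(xy[, 2], idx); sz <- rowsum(xy[, 1], idx)
  g$sum_lambda[as.integer(rownames(sl)), 1] <- sl
  g$sum_z[as.integer(rownames(sz)), 1] <- sz
  gr <- czar_gradient(g, 300, min_count = 2000)
  mids <- g$mids[[1]]
  ok <- is.finite(gr[, 1])
  fitc <- stats::coef(stats::lm(gr[ok, 1] ~ mids[ok]))
  expect_equal(unname(fitc[2]), kappa, tolerance = 0.02)
  expect_lt(abs(fitc[1]), 0.02)

  # stiff limit lambda == z: estimate is the Gaussian log-density derivative
  g2 <- bias_grid(-2, 2, 40, k = 50, full_samples = 500)
  sigma2 <- 0.25
  set.seed(2)
  zs <- stats::rnorm(5e5, 0, sqrt(sigma2))
  idx2 <- pmin(pmax(floor((zs - g2$lower) / g2$width) + 1, 1), 40)
  g2$count_z <- as.numeric(tabulate(idx2, 40))
  szs <- rowsum(zs, idx2)
  g2$sum_z[as.integer(rownames(szs)), 1] <- szs
  g2$sum_lambda <- g2$sum_z   # lambda identical to z
  gr2 <- czar_gradient(g2, 300, min_count = 2000)
  ok2 <- is.finite(gr2[, 1])
  slope2 <- stats::coef(stats::lm(gr2[ok2, 1] ~ g2$mids[[1]][ok2]))[2]
  expect_equal(unname(slope2), kT(300) / sigma2, tolerance = 0.03)

  # shifting all lambda by c shifts the estimate by k*c
  g3 <- g
  g3$sum_lambda <- g$sum_lambda + 0.2 * g$count_z
  gr3 <- czar_gradient(g3, 300, min_count = 2000)
  expect_equal(gr3[ok, 1] - gr[ok, 1], rep(100 * 0.2, sum(ok)), tolerance = 1e-9)
})

test_that("gradient integration is exact for consistent fields", {
  g <- bias_grid(c(-1, -1), c(1, 1), c(15, 15), k = c(10, 10))
  m1 <- g$mids[[1]]; m2 <- g$mids[[2]]
  gx <- outer(m1, rep(1, 15))            # F = x^2/2 + 3 y^2 / 2
  gy <- outer(rep(1, 15), 3 * m2)
  grad <- cbind(as.vector(gx), as.vector(gy))
  attr(grad, "mids") <- g$mids
  f <- integrate_gradient(grad, g)
  analytic <- outer(m1^2 / 2, rep(1, 15)) + outer(rep(1, 15), 1.5 * m2^2)
  analytic <- analytic - min(analytic)
  expect_equal(f$values, analytic, tolerance = 1e-8)

  # rotational (curl) contamination of amplitude eps perturbs F only by O(eps)
  eps <- 0.05
  gradc <- grad + eps * cbind(as.vector(outer(rep(1, 15), -m2)),
                              as.vector(outer(m1, rep(1, 15))))
  fc <- integrate_gradient(gradc, g)
  expect_lt(max(abs(fc$values - analytic)), 5 * eps)

  # 1D linear gradient integrates to a tilted line
  g1 <- bias_grid(0, 1, 11, k = 10)
  grad1 <- matrix(2, 11, 1)
  f1 <- integrate_gradient(grad1, g1)
  expect_equal(f1$values, 2 * (g1$mids[[1]] - g1$mids[[1]][1]), tolerance = 1e-10)
})

test_that("missing-bin handling splits integration into components", {
  g <- bias_grid(0, 1, 9, k = 10)
  grad <- matrix(1, 9, 1)
  grad[5, 1] <- NA
  f <- integrate_gradient(grad, g)
  expect_true(is.na(f$values[5]))
  expect_equal(sum(is.na(f$values)), 1)
  # each component separately gauged to start at 0
  expect_equal(f$values[1], 0)
  expect_equal(f$values[6], 0)
})

test_that("stratified windows merge without leakage and match a single run", {
  pot <- make_two_basin_potential(2, 2, 0)
  cvs <- cv_components(1, 2)
  cfg <- ud_config(dt = 0.005)
  ext <- extended_state(k = 25, mass = 1, friction = 2)
  g <- bias_grid(-1.5, 1.5, 15, k = 25, full_samples = 500)
  single <- run_eabf(pot, cfg, cvs, g, ext, n_steps = 8e5, seed = 5,
                     start = c(-1, 0))
  plan <- stratification_plan(0, g, list(c(-1, 0), c(1, 0)), n_steps = 4e5)
  merged <- stratified_eabf(pot, cfg, cvs, plan, g, ext, seed = 6)
  f1 <- integrate_gradient(czar_gradient(single$grid, 300, min_count = 200),
                           single$grid)
  f2 <- integrate_gradient(czar_gradient(merged, 300, min_count = 200), merged)
  ok <- is.finite(f1$values) & is.finite(f2$values) &
    single$grid$count_z > 2000 & merged$count_z > 2000
  d1 <- f1$values[ok] - mean(f1$values[ok])
  d2 <- f2$values[ok] - mean(f2$values[ok])
  # barrier height agreement between stratified and unstratified runs
  expect_lt(abs(max(d1) - max(d2)), 0.2)
  expect_error(stratification_plan(c(0, 0), g, list(1, 2, 3), 10), "duplicate")
})

test_that("warm-started windows sample more evenly than cold starts", {
  pot <- make_two_basin_potential(2, 2, 0)
  cvs <- cv_components(1, 2)
  cfg <- ud_config(dt = 0.005)
  ext <- extended_state(k = 25, mass = 1, friction = 2)
  g <- bias_grid(-1.5, 1.5, 15, k = 25, full_samples = 500)
  warm <- run_eabf(pot, cfg, cvs, g, ext, n_steps = 6e5, seed = 21,
                   start = c(-1, 0))$grid
  entropy <- function(grid, sel) {
    p <- grid$count_z[sel] / sum(grid$count_z[sel])
    -sum(ifelse(p > 0, p * log(p), 0))
  }
  win <- list(lo = -1.5, hi = 0)
  sel_bins <- which(g$mids[[1]] < 0)
  steps <- 4e4
  cold_run <- run_eabf(pot, cfg, cvs, g, ext, n_steps = steps, seed = 22,
                       start = c(-1, 0), window = win)
  warm0 <- warm
  warm0$count_z[] <- 0; warm0$sum_lambda[] <- 0; warm0$sum_z[] <- 0
  warm_run <- run_eabf(pot, cfg, cvs, warm0, ext, n_steps = steps, seed = 22,
                       start = c(-1, 0), window = win)
  expect_gt(entropy(warm_run$grid, sel_bins), entropy(cold_run$grid, sel_bins))
})

test_that("grid merging is associative and order-independent", {
  g <- bias_grid(-1, 1, 8, k = 10)
  fill <- function(seed) {
    set.seed(seed)
    h <- g
    h$count_z <- stats::rpois(8, 40)
    h$sum_lambda <- matrix(stats::rnorm(8), 8, 1)
    h$sum_z <- matrix(stats::rnorm(8), 8, 1)
    h$count_l <- stats::rpois(8, 40)
    h$sum_force <- matrix(stats::rnorm(8), 8, 1)
    h
  }
  add <- function(a, b) {
    a$count_z <- a$count_z + b$count_z
    a$sum_lambda <- a$sum_lambda + b$sum_lambda
    a$sum_z <- a$sum_z + b$sum_z
    a$count_l <- a$count_l + b$count_l
    a$sum_force <- a$sum_force + b$sum_force
    a
  }
  a <- fill(1); b <- fill(2); c3 <- fill(3)
  m1 <- add(add(a, b), c3)
  m2 <- add(a, add(c3, b))
  expect_equal(m1$count_z, m2$count_z)
  expect_equal(m1$sum_force, m2$sum_force)
})

test_that("convergence report tracks gradient stabilisation", {
  pot <- harmonic_potential(2, 1)
  cfg <- ud_config(dt = 0.005)
  ext <- extended_state(k = 50, mass = 1, friction = 2)
  g <- bias_grid(-1.5, 1.5, 20, k = 50, full_samples = 500)
  snaps <- list()
  cur <- g
  for (i in 1:4) {
    res <- run_eabf(pot, cfg, cv_identity(1), cur, ext,
                    n_steps = c(2e4, 6e4, 2e5, 4e5)[i], seed = 10 + i, start = 0)
    cur <- res$grid
    snaps[[i]] <- cur
  }
  rep_ <- convergence_report(snaps, 300)
  expect_true(all(is.na(rep_$rms_change[1])))
  expect_true(all(rep_$rms_change[-1] > 0))
  expect_lt(rep_$rms_change[4], rep_$rms_change[2])
  expect_true(all(diff(rep_$frac_full) >= 0))
  expect_error(convergence_report(snaps[1]), "2 snapshots")

  # identical snapshots have zero gradient change
  rep0 <- convergence_report(list(cur, cur), 300)
  expect_equal(rep0$rms_change[2], 0)
})

test_that("block error of an uncorrelated series scales as the standard error", {
  set.seed(4)
  x <- stats::rnorm(4000, 0, 2)
  expect_equal(block_error(x, 20), 2 / sqrt(4000), tolerance = 0.4)
  expect_error(block_error(1:5, 10), "n_blocks")
})

test_that("bias grid state round-trips through its text serialization", {
  pot <- harmonic_potential(2, 1)
  cfg <- ud_config(dt = 0.005)
  ext <- extended_state(k = 50, mass = 1, friction = 2)
  g <- bias_grid(-1.5, 1.5, 10, k = 50, full_samples = 123, clamp = TRUE)
  res <- run_eabf(pot, cfg, cv_identity(1), g, ext, n_steps = 2e4, seed = 3,
                  start = 0)
  tf <- tempfile(fileext = ".txt")
  write_bias_grid(res$grid, tf)
  back <- read_bias_grid(tf)
  expect_equal(back$count_z, res$grid$count_z)
  expect_equal(back$sum_force, res$grid$sum_force, tolerance = 1e-12)
  expect_equal(back$full_samples, 123)
  expect_equal(back$k, 50)
})
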