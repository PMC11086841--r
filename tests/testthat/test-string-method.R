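test_that("endpoint normalization maps total variation to the unit box", {
  a <- c(Xc = 5, dRMSD = 1.4)
  b <- c(Xc = -10, dRMSD = -1.4)
  map <- normalize_cvs(a, b)
  expect_equal(unname(map$scale), c(15, 2.8))
  expect_equal(unname(norm_apply(map, a)), c(1, 1))
  expect_equal(unname(norm_apply(map, b)), c(0, 0))
  # round trip
  x <- c(Xc = -2.3, dRMSD = 0.7)
  expect_equal(norm_invert(map, norm_apply(map, x)), x, tolerance = 1e-12)

  expect_error(normalize_cvs(c(u = 1, v = 2), c(u = 1, v = 5)), "u")
  map2 <- normalize_cvs(c(u = 1, v = 2), c(u = 1, v = 5), fallback_scale = 1)
  expect_equal(unname(map2$scale), c(1, 3))
})

test_that("straight initialization gives equally spaced images", {
  a <- c(x = 0, y = 0); b <- c(x = 2, y = 1)
  p3 <- initialize_string(a, b, 3)
  expect_equal(p3$images[2, ], c(x = 0.5, y = 0.5))   # normalized midpoint
  p32 <- initialize_string(a, b, 32)
  seg <- sqrt(rowSums(diff(p32$images)^2))
  expect_equal(max(abs(seg - seg[1])) / seg[1], 0, tolerance = 1e-9)
  expect_equal(nrow(p32$images), 32)
  expect_error(initialize_string(a, b, 2), "at least 3")
})

test_that("reparametrization enforces equal arc length on the interpolant", {
  # collinear images at parameters 0, 0.2, 1 move to 0, 0.5, 1
  img <- rbind(c(0, 0), c(0.2, 0.2), c(1, 1))
  out <- reparametrize(img)
  expect_equal(out[2, ], c(0.5, 0.5), tolerance = 1e-12)

  # idempotence on an already equal path
  eq <- cbind(seq(0, 1, length.out = 7), seq(0, 2, length.out = 7))
  expect_equal(reparametrize(eq), eq, tolerance = 1e-12)

  # right-angle polyline with 5 images: hand-computed arc positions
  ra <- rbind(c(0, 0), c(1, 0), c(1, 1))
  colnames(ra) <- c("x", "y")
  p <- structure(list(images = ra, map = normalize_cvs(c(x = 0, y = 0), c(x = 1, y = 1)),
                      iteration = 0L, history = list(), initial = ra),
                 class = "path_string")
  p5 <- refine_path(p, 5)
  expect_equal(unname(p5$images),
               rbind(c(0, 0), c(0.5, 0), c(1, 0), c(1, 0.5), c(1, 1)),
               tolerance = 1e-12)

  # duplicate adjacent images are merged, not fatal
  dup <- rbind(c(0, 0), c(0, 0), c(1, 1))
  out2 <- reparametrize(dup)
  expect_equal(out2[2, ], c(0.5, 0.5), tolerance = 1e-12)

  # purely tangential displacement is projected out
  base <- cbind(seq(0, 1, length.out = 9), 0.5 * seq(0, 1, length.out = 9))
  shifted <- base
  shifted[2:8, ] <- base[2:8, ] + 0.03 * (base[3:9, ] - base[1:7, ])
  expect_equal(reparametrize(shifted), base, tolerance = 1e-6)
})

test_that("path refinement interpolates linearly and is reversible", {
  a <- c(x = 0, y = 0); b <- c(x = 1, y = 1)
  p3 <- initialize_string(a, b, 3)
  p5 <- refine_path(p3, 5)
  expect_equal(p5$images[, 1], seq(0, 1, length.out = 5), tolerance = 1e-12)
  back <- refine_path(p5, 3)
  expect_equal(back$images, p3$images, tolerance = 1e-9)

  # 32 -> 128 refinement of a curved path keeps equal spacing
  t <- seq(0, 1, length.out = 32)
  curved <- cbind(t, sin(pi * t) / pi)
  colnames(curved) <- c("x", "y")
  pc <- structure(list(images = reparametrize(curved),
                       map = normalize_cvs(a, b), iteration = 0L,
                       history = list(), initial = curved),
                  class = "path_string")
  pr <- refine_path(pc, 128)
  expect_equal(nrow(pr$images), 128)
  seg <- sqrt(rowSums(diff(pr$images)^2))
  expect_lt(diff(range(seg)) / mean(seg), 1e-6)
})

test_that("swarm drift is stationary at a free-energy minimum", {
  pot <- harmonic_potential(c(2, 2))
  cfg <- langevin_config(300, friction = 2, timestep = 0.01, mass = 1,
                         scheme = "overdamped")
  a <- c(x = -1, y = 0); b <- c(x = 1, y = 0)
  path <- initialize_string(a, b, 3,
                            map = normalize_cvs(a, b, fallback_scale = 1))
  # put the middle image exactly at the minimum (0,0) -> normalized (0.5, 0.5)
  cvs <- cv_identity(2)
  cfgs <- swarm_config(restraint_k = c(50, 50), equil_steps = 300,
                       swarm_size = 60, swarm_steps = 10)
  upd <- swarm_iteration(path, pot, cfg, cvs, cfgs, seed = 5)
  drift_se <- attr(upd, "drift_se")[2]
  moved <- sqrt(sum((upd$images[2, ] - path$images[2, ])^2))
  expect_lt(moved, 3 * drift_se + 1e-9)
  # determinism
  upd2 <- swarm_iteration(path, pot, cfg, cvs, cfgs, seed = 5)
  expect_identical(upd$images, upd2$images)
})

test_that("swarm drift follows the Ornstein-Uhlenbeck relaxation law", {
  kappa <- 2; gam <- 2; dt <- 0.01
  pot <- harmonic_potential(kappa, 1)
  cfg <- langevin_config(300, friction = gam, timestep = dt, mass = 1,
                         scheme = "overdamped")
  z0 <- 0.8; tlen <- 40
  S <- 200
  set.seed(31)
  finals <- numeric(S)
  for (s in seq_len(S)) {
    tr <- simulate_langevin(pot, cfg, z0, tlen, seed = 1000 + s)
    finals[s] <- tr[tlen, 1]
  }
  drift <- mean(finals) - z0
  expected <- (0 - z0) * (1 - exp(-kappa * tlen * dt / gam))
  se <- stats::sd(finals) / sqrt(S)
  expect_lt(abs(drift - expected), 3 * se)
})

test_that("convergence series and averaging behave as defined", {
  a <- c(x = 0, y = 0); b <- c(x = 1, y = 1)
  p <- initialize_string(a, b, 5)
  # fabricate history: identical paths -> zero RMSD, average equals the path
  p$history <- list(p$images, p$images, p$images)
  expect_equal(string_convergence(p), c(0, 0, 0))
  avg <- average_string(p, last_n = 3)
  expect_equal(avg$images, p$images, tolerance = 1e-12)

  # known offset on one image: RMSD = delta/sqrt(M*D)
  delta <- 0.12
  shifted <- p$images
  shifted[3, 1] <- shifted[3, 1] + delta
  p$history <- list(shifted)
  expect_equal(string_convergence(p), delta / sqrt(5 * 2), tolerance = 1e-12)

  # average of two paths symmetric about the straight line is the line
  up <- p$images; dn <- p$images
  up[2:4, 2] <- up[2:4, 2] + 0.1
  dn[2:4, 2] <- dn[2:4, 2] - 0.1
  p$history <- list(up, dn)
  avg2 <- average_string(p, last_n = 2)
  expect_equal(avg2$images, initialize_string(a, b, 5)$images, tolerance = 1e-9)

  p$history <- list()
  expect_error(string_convergence(p), "history")
})

test_that("uplifting sets extra CVs to restrained conditional means", {
  # coupled harmonic: U = 1/2*2*x^2 + 1/2*8*(y - 0.6 x)^2, so E[y|x] = 0.6 x
  pot <- model_potential(2,
    function(p) 0.5 * 2 * p[1]^2 + 0.5 * 8 * (p[2] - 0.6 * p[1])^2,
    function(p) c(2 * p[1] - 0.6 * 8 * (p[2] - 0.6 * p[1]),
                  8 * (p[2] - 0.6 * p[1])),
    domain = rbind(c(-4, -4), c(4, 4)))
  cfg <- langevin_config(300, friction = 2, timestep = 0.01, mass = 1,
                         scheme = "overdamped")
  a_low <- c(x = -1); b_low <- c(x = 1)
  low <- initialize_string(a_low, b_low, 7)
  map_full <- normalize_cvs(c(x = -1, y = -0.6), c(x = 1, y = 0.6))
  up <- uplift_path(low, pot, cfg, cv_identity(2), low_idx = 1,
                    map_full = map_full, restraint_k = 100, n_steps = 4000,
                    seed = 2)
  raw <- norm_invert(map_full, up$images)
  # uplifted y profile tracks 0.6 * x within sampling error
  expect_lt(max(abs(raw[, 2] - 0.6 * raw[, 1])), 0.15)

  # an extra CV uncorrelated with the low-D CV stays near its global mean
  pot2 <- harmonic_potential(c(2, 5))
  up2 <- uplift_path(low, pot2, cfg, cv_identity(2), low_idx = 1,
                     map_full = normalize_cvs(c(x = -1, y = -1), c(x = 1, y = 1)),
                     restraint_k = 100, n_steps = 4000, seed = 3)
  raw2 <- norm_invert(normalize_cvs(c(x = -1, y = -1), c(x = 1, y = 1)), up2$images)
  expect_lt(max(abs(raw2[, 2])), 0.2)
})

test_that("string state round-trips through tabular text", {
  a <- c(x = 0, y = 0); b <- c(x = 2, y = 3)
  p <- initialize_string(a, b, 6)
  tf <- tempfile(fileext = ".tsv")
  write_string(p, tf)
  q <- read_string(tf, p$map)
  expect_equal(q$images, p$images, tolerance = 1e-9)
})
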