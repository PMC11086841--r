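test_that("Kabsch superposition is exact on rigid motions", {
  cf <- toy_conf4()
  self <- superpose_kabsch(cf, cf)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-10)

  R <- rotation_about_axis(c(1, 2, -0.5), 37)
  moved <- transform_conformation(cf, R, c(3, -2, 8))
  fit <- superpose_kabsch(moved, cf)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # mismatched selections and degenerate geometry are rejected
  cf3 <- conformation(c("A", "B", "C"), 1:3, rep("C", 3),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(superpose_kabsch(cf3, cf3), "collinear")
  expect_error(superpose_kabsch(cf, cf, sel(resid = 1:2)), "at least 3")
})

test_that("Kabsch minimum matches brute-force rotation search and bio3d", {
  a <- toy_conf4()
  b <- random_conformation(4, seed = 8, spread = 2)
  fit <- superpose_kabsch(a, b)

  # oracle 1: numerical minimisation over Euler angles from many starts
  P0 <- sweep(a$xyz, 2, colMeans(a$xyz))
  Q0 <- sweep(b$xyz, 2, colMeans(b$xyz))
  obj <- function(ang) {
    R <- rotation_about_axis(c(0, 0, 1), ang[3] * 180 / pi) %*%
      rotation_about_axis(c(0, 1, 0), ang[2] * 180 / pi) %*%
      rotation_about_axis(c(1, 0, 0), ang[1] * 180 / pi)
    sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
  }
  best <- Inf
  set.seed(1)
  for (i in 1:40) {
    r <- stats::optim(stats::runif(3, -pi, pi), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, r$value)
  }
  expect_equal(fit$rmsd, best, tolerance = 1e-3)

  # oracle 2: bio3d least-squares fit
  rb <- bio3d::rmsd(as.vector(t(b$xyz)), as.vector(t(a$xyz)), fit = TRUE)
  expect_equal(fit$rmsd, rb, tolerance = 1e-3)
})

test_that("delta-RMSD endpoints, antisymmetry and bound", {
  a <- make_bead_helix(9, 0)
  b <- make_bead_helix(9, 40)
  d_ab <- rmsd_fit(a, b)
  expect_equal(delta_rmsd(a, b, a), d_ab, tolerance = 1e-12)
  expect_equal(delta_rmsd(b, b, a), -d_ab, tolerance = 1e-12)
  for (s in 1:5) {
    x <- random_conformation(9, seed = 100 + s, spread = 4)
    x$resid <- a$resid
    expect_equal(delta_rmsd(x, a, b), -delta_rmsd(x, b, a), tolerance = 1e-12)
    expect_lte(abs(delta_rmsd(x, a, b)), d_ab + 1e-9)
    # rigid-motion invariance
    xr <- transform_conformation(x, random_rotation(s), c(5, -1, 2))
    expect_equal(delta_rmsd(xr, a, b), delta_rmsd(x, a, b), tolerance = 1e-9)
  }
})

test_that("principal-axes projection fixes the frame against a reference", {
  # asymmetric 10-bead body with analytically known axes: spread along z > y > x
  set.seed(2)
  body_xyz <- cbind(stats::rnorm(10, 0, 0.3), stats::rnorm(10, 0, 1.0),
                    stats::rnorm(10, 0, 3.0))
  body_xyz <- sweep(body_xyz, 2, colMeans(body_xyz))
  # probe placed 3 A from the body centre along the long (z) axis
  probe <- matrix(colMeans(body_xyz) + c(0, 0, 3), 1, 3)
  cf <- conformation(c(paste0("B", 1:10), "P"), c(1:10, 11), rep("C", 11),
                     rbind(body_xyz, probe))
  p <- principal_axes_projection(cf, sel(resid = 1:10), sel(resid = 11), cf)
  expect_equal(unname(p["Z"]), 3, tolerance = 0.2)
  expect_lt(abs(p["X"]), 0.35)
  expect_lt(abs(p["Y"]), 0.35)

  # probe at the body centre of geometry projects to the origin
  cf0 <- cf
  cf0$xyz[11, ] <- colMeans(body_xyz)
  p0 <- principal_axes_projection(cf0, sel(resid = 1:10), sel(resid = 11), cf0)
  expect_equal(unname(p0), c(0, 0, 0), tolerance = 1e-10)

  # invariance under global rigid motion (reference fixes signs)
  moved <- transform_conformation(cf, random_rotation(5), c(4, 4, -7))
  pm <- principal_axes_projection(moved, sel(resid = 1:10), sel(resid = 11), cf)
  expect_equal(pm, p, tolerance = 1e-8)
})

test_that("orientation angle recovers constructed tilts", {
  ref <- make_bead_helix(9, 0)
  expect_lt(orientation_angle(ref, sel(resid = 485:493), ref), 1e-5)
  # rotate the whole helix by a constructed angle about an axis orthogonal
  # to its principal direction, leaving the anchor out of the fit
  for (ang in c(25, 90)) {
    R <- rotation_about_axis(c(1, 0, 0), ang)
    tilted <- transform_conformation(ref, R, c(0, 0, 0))
    # anchored two-part object: helix plus 4 fixed anchor beads, so the
    # anchoring superposition cannot absorb the fragment rotation
    anchor <- conformation(paste0("X", 1:4), 601:604, rep("C", 4),
                           rbind(c(8, 0, 0), c(8, 2, 1), c(10, -1, 0), c(9, 1, 4)))
    both_ref <- conformation(c(ref$atom, anchor$atom), c(ref$resid, anchor$resid),
                             c(ref$element, anchor$element),
                             rbind(ref$xyz, anchor$xyz))
    both_tilt <- conformation(both_ref$atom, both_ref$resid, both_ref$element,
                              rbind(tilted$xyz, anchor$xyz))
    got2 <- orientation_angle(both_tilt, sel(resid = 485:493), both_ref,
                              anchor_selection = sel(resid = 601:604))
    expect_equal(got2, ang, tolerance = 0.1)
  }
})

test_that("distances, centre-of-geometry distances and dihedrals", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0),
               c(1, 0, 0), c(0, 0, 0.5), c(2, 0, 1),    # group A (cog 1,0,0.5)
               c(8.25, 0, 0), c(7.25, 0, 0.5), c(9.25, 0, 1))  # group B (cog +7.25 in x)
  cf <- conformation(paste0("A", 1:8), 1:8, rep("C", 8), xyz)
  d <- cv_definition("d", "distance", selections = list(sel(resid = 1), sel(resid = 2)))
  expect_equal(evaluate_cv(cf, d), 5, tolerance = 1e-12)
  cog <- cv_definition("cog", "cog_distance",
                       selections = list(sel(resid = 3:5), sel(resid = 6:8)))
  expect_equal(evaluate_cv(cf, cog), 7.25, tolerance = 1e-12)

  cis <- conformation(paste0("T", 1:4), 1:4, rep("C", 4),
                      rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  trans <- conformation(paste0("T", 1:4), 1:4, rep("C", 4),
                        rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)))
  dih <- cv_definition("chi", "dihedral",
                       selections = list(sel(resid = 1), sel(resid = 2),
                                         sel(resid = 3), sel(resid = 4)))
  expect_equal(evaluate_cv(cis, dih), 0, tolerance = 1e-10)
  expect_equal(abs(evaluate_cv(trans, dih)), 180, tolerance = 1e-10)

  pt <- distances_and_dihedrals(cf, list(d, cog))
  expect_named(pt, c("d", "cog"))

  bad <- cv_definition("x", "distance",
                       selections = list(sel(atoms = "ZZ"), sel(resid = 2)))
  expect_error(evaluate_cv(cf, bad), "zero atoms")
})

test_that("contact counting uses a strict heavy-atom cutoff", {
  far <- conformation(c("A", "B"), 1:2, c("C", "C"), rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_equal(count_contacts(far, sel(resid = 1), sel(resid = 2)), 0)

  exact <- conformation(c("A", "B"), 1:2, c("C", "C"), rbind(c(0, 0, 0), c(4.5, 0, 0)))
  expect_equal(count_contacts(exact, sel(resid = 1), sel(resid = 2)), 0)
  near <- conformation(c("A", "B"), 1:2, c("C", "C"), rbind(c(0, 0, 0), c(4.499, 0, 0)))
  expect_equal(count_contacts(near, sel(resid = 1), sel(resid = 2)), 1)

  # brute-force O(n^2) oracle on random clouds, plus hydrogens excluded
  set.seed(6)
  A <- matrix(stats::runif(30, 0, 8), ncol = 3)
  B <- matrix(stats::runif(30, 0, 8), ncol = 3)
  elemA <- sample(c("C", "N", "O", "H"), 10, replace = TRUE)
  elemB <- sample(c("C", "O", "H"), 10, replace = TRUE)
  cf <- conformation(paste0("X", 1:20), 1:20, c(elemA, elemB), rbind(A, B))
  brute <- 0
  for (i in 1:10) for (j in 1:10)
    if (elemA[i] != "H" && elemB[j] != "H" &&
        sqrt(sum((A[i, ] - B[j, ])^2)) < 4.5) brute <- brute + 1
  expect_equal(count_contacts(cf, sel(resid = 1:10), sel(resid = 11:20)), brute)

  # monotone in the cutoff
  cuts <- c(2, 3.5, 4.5, 6, 9)
  counts <- vapply(cuts, function(cc)
    count_contacts(cf, sel(resid = 1:10), sel(resid = 11:20), cutoff = cc),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(count_contacts(cf, sel(resid = 1:10), sel(resid = 10:20)),
               "overlap")
})
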