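#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between the
#' selected atoms of `mobile` and `reference`, via SVD of the covariance
#' matrix with the usual determinant correction guaranteeing det(R) = +1.
#'
#' @param mobile a [conformation()]
#' @param reference a [conformation()]
#' @param selection selection applied to both structures (see [sel()]);
#'   must resolve to equal counts of >= 3 non-collinear atoms
#' @return list with `rmsd` (Angstrom), `rotation` (3 x 3), `translation`
#'   (length 3: transform is `x %*% t(R) + t`), applied to mobile coordinates
#' @export
superpose_kabsch <- function(mobile, reference, selection = NULL) {
  im <- resolve_selection(mobile, selection)
  ir <- resolve_selection(reference, selection)
  if (length(im) != length(ir))
    stop(sprintf("selection sizes differ (%d vs %d atoms)", length(im), length(ir)))
  if (length(im) < 3)
    stop("superposition needs at least 3 atoms (degenerate geometry)")
  P <- mobile$xyz[im, , drop = FALSE]
  Q <- reference$xyz[ir, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  if (svd(P0)$d[2] < 1e-10 * max(svd(P0)$d[1], 1))
    stop("selected atoms are collinear (degenerate geometry)")
  H <- t(P0) %*% Q0
  s <- svd(H)
  dsign <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, dsign))
  R <- s$v %*% D %*% t(s$u)
  Pfit <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pfit - Q0)^2)))
  translation <- as.numeric(cq - R %*% cp)
  list(rmsd = rmsd, rotation = R, translation = translation)
}

#' RMSD after optimal superposition
#'
#' @inheritParams superpose_kabsch
#' @return RMSD in Angstrom
#' @export
rmsd_fit <- function(mobile, reference, selection = NULL)
  superpose_kabsch(mobile, reference, selection)$rmsd

#' Delta-RMSD collective variable
#'
#' `delta_rmsd(x) = RMSD(x, ref_b) - RMSD(x, ref_a)`, each RMSD computed after
#' independent optimal superposition on `selection`. With ref_b the
#' kinked-helix (post-transition) reference and ref_a the straight-helix
#' (pre-transition) reference, the CV is positive near ref_a and negative near
#' ref_b, providing a signed progress coordinate for the local backbone
#' rearrangement.
#'
#' @param x conformation to evaluate
#' @param ref_b first reference (subtracted-from term)
#' @param ref_a second reference (subtracted term)
#' @param selection atom selection (e.g. backbone heavy atoms N, CA, C, O of a
#'   residue range)
#' @return signed value in Angstrom
#' @export
delta_rmsd <- function(x, ref_b, ref_a, selection = NULL)
  rmsd_fit(x, ref_b, selection) - rmsd_fit(x, ref_a, selection)

# Principal axes of the gyration tensor of a point cloud, ordered by
# descending eigenvalue; columns are unit axis vectors.
gyration_axes <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  S <- t(c0) %*% c0 / nrow(c0)
  e <- eigen(S, symmetric = TRUE)
  if ((e$values[1] - e$values[2]) < 1e-8 * max(e$values[1], 1e-12) ||
      (e$values[2] - e$values[3]) < 1e-8 * max(e$values[1], 1e-12))
    stop("degenerate gyration tensor: principal axes ambiguous")
  e$vectors   # ordered by decreasing eigenvalue
}

#' Principal-axes projection of a probe group
#'
#' Expresses the centre of geometry of `probe_selection` in the frame formed
#' by the principal axes of the body defined by `body_selection` (gyration
#' tensor, axes ordered by descending eigenvalue). Axis signs are fixed by
#' alignment with the axes of the same body in `reference`, making the map
#' continuous under small perturbations. The longitudinal (largest-spread)
#' axis is reported as Z, then Y, then X, matching the convention of tracking
#' a domain's position relative to a molecular body.
#'
#' @param conf conformation to evaluate
#' @param body_selection selection defining the body frame
#' @param probe_selection selection whose centre of geometry is projected
#' @param reference reference conformation fixing axis signs (and supplying
#'   the reference axes); defaults to `conf` itself
#' @return named numeric `c(X=, Y=, Z=)` in Angstrom, Z along the major axis
#' @export
principal_axes_projection <- function(conf, body_selection, probe_selection,
                                      reference = conf) {
  ib <- resolve_selection(conf, body_selection)
  ip <- resolve_selection(conf, probe_selection)
  ax <- gyration_axes(conf$xyz[ib, , drop = FALSE])
  rb <- resolve_selection(reference, body_selection)
  ax_ref <- gyration_axes(reference$xyz[rb, , drop = FALSE])
  # sign disambiguation: carry the reference axes into the conformation's
  # frame by the body superposition, then align each axis with them (a raw
  # axis comparison would break under global rigid motion)
  fit <- superpose_kabsch(reference, conf, body_selection)
  ax_ref_here <- fit$rotation %*% ax_ref
  for (j in 1:3) if (sum(ax[, j] * ax_ref_here[, j]) < 0) ax[, j] <- -ax[, j]
  body_cog <- colMeans(conf$xyz[ib, , drop = FALSE])
  probe_cog <- colMeans(conf$xyz[ip, , drop = FALSE])
  rel <- probe_cog - body_cog
  proj <- as.numeric(t(ax) %*% rel)
  c(X = proj[3], Y = proj[2], Z = proj[1])
}

# Principal direction (major gyration axis) of a fragment, sign-fixed to
# point from the first to the last selected atom.
fragment_direction <- function(conf, selection) {
  i <- resolve_selection(conf, selection)
  if (length(i) < 3) stop("fragment needs >= 3 atoms to define a direction")
  xyz <- conf$xyz[i, , drop = FALSE]
  c0 <- sweep(xyz, 2, colMeans(xyz))
  S <- t(c0) %*% c0
  e <- eigen(S, symmetric = TRUE)
  if (e$values[1] < 1e-10) stop("degenerate fragment direction")
  u <- e$vectors[, 1]
  ends <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(u * ends) < 0) u <- -u
  u
}

#' Orientation angle of a fragment relative to a reference
#'
#' Angle in degrees between the principal direction of `fragment_selection`
#' in `conf` and in `reference`, measured after superposing `conf` onto
#' `reference` over `anchor_selection` (so that global rigid motion does not
#' register as fragment re-orientation).
#'
#' @param conf conformation to evaluate
#' @param fragment_selection selection of the fragment (>= 3 atoms)
#' @param reference reference conformation
#' @param anchor_selection selection used for the anchoring superposition;
#'   `NULL` uses all atoms
#' @return angle in degrees, in `[0, 180]`
#' @export
orientation_angle <- function(conf, fragment_selection, reference,
                              anchor_selection = NULL) {
  fit <- superpose_kabsch(conf, reference, anchor_selection)
  conf_fit <- transform_conformation(conf, fit$rotation, fit$translation)
  u <- fragment_direction(conf_fit, fragment_selection)
  v <- fragment_direction(reference, fragment_selection)
  cth <- max(-1, min(1, sum(u * v)))
  acos(cth) * 180 / pi
}

#' Collective-variable definition
#'
#' One entry of a CV catalogue. Kinds:
#' * `"distance"`: Euclidean distance between two single atoms (`sel_a`,
#'   `sel_b` each resolving to one atom).
#' * `"cog_distance"`: distance between centres of geometry of two groups.
#' * `"dihedral"`: four-point torsion, `selections` a list of four one-atom
#'   selections, value in (-180, 180].
#' * `"delta_rmsd"`: signed two-reference RMSD difference (see
#'   [delta_rmsd()]); needs `references = list(ref_b, ref_a)`.
#' * `"principal_axes_projection"`: one component (`axis` = "X","Y","Z") of
#'   [principal_axes_projection()].
#' * `"orientation_angle"`: see [orientation_angle()].
#'
#' @param name CV name (e.g. "Xc", "dRMSD", "k1")
#' @param kind one of the kinds above
#' @param selections list of [sel()] objects (meaning depends on kind)
#' @param references list of reference [conformation()]s where needed
#' @param axis for projections: which component to report
#' @param force_constant harmonic force constant for biased use,
#'   kcal/mol/U^2 (U = Angstrom or degree)
#' @return object of class `cv_definition`
#' @export
cv_definition <- function(name, kind, selections = list(), references = list(),
                          axis = "X", force_constant = NA_real_) {
  kind <- match.arg(kind, c("distance", "cog_distance", "dihedral", "delta_rmsd",
                            "principal_axes_projection", "orientation_angle"))
  if (kind == "delta_rmsd" && length(references) != 2)
    stop("delta_rmsd requires exactly two references")
  structure(list(name = name, kind = kind, selections = selections,
                 references = references, axis = axis,
                 force_constant = force_constant),
            class = "cv_definition")
}

single_atom_xyz <- function(conf, selection) {
  i <- resolve_selection(conf, selection)
  if (length(i) != 1)
    stop(sprintf("selection must resolve to one atom, got %d", length(i)))
  conf$xyz[i, ]
}

#' Dihedral angle of four points
#'
#' Standard four-point convention; returns degrees in (-180, 180], 0 for cis,
#' 180 for trans.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors
#' @return dihedral in degrees
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Evaluate one collective variable on a conformation
#'
#' @param conf a [conformation()]
#' @param cv a [cv_definition()]
#' @return numeric value (Angstrom or degrees)
#' @export
evaluate_cv <- function(conf, cv) {
  switch(cv$kind,
    distance = {
      a <- single_atom_xyz(conf, cv$selections[[1]])
      b <- single_atom_xyz(conf, cv$selections[[2]])
      sqrt(sum((a - b)^2))
    },
    cog_distance = {
      a <- colMeans(conf$xyz[resolve_selection(conf, cv$selections[[1]]), , drop = FALSE])
      b <- colMeans(conf$xyz[resolve_selection(conf, cv$selections[[2]]), , drop = FALSE])
      sqrt(sum((a - b)^2))
    },
    dihedral = {
      ps <- lapply(cv$selections[1:4], function(s) single_atom_xyz(conf, s))
      dihedral_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
    },
    delta_rmsd = delta_rmsd(conf, cv$references[[1]], cv$references[[2]],
                            cv$selections[[1]]),
    principal_axes_projection = {
      p <- principal_axes_projection(conf, cv$selections[[1]], cv$selections[[2]],
                                     if (length(cv$references)) cv$references[[1]] else conf)
      unname(p[cv$axis])
    },
    orientation_angle = orientation_angle(conf, cv$selections[[1]],
                                          cv$references[[1]],
                                          if (length(cv$selections) > 1) cv$selections[[2]] else NULL)
  )
}

#' Evaluate a catalogue of distance/dihedral-type CVs
#'
#' @param conf a [conformation()]
#' @param cv_set list of [cv_definition()]s
#' @return named numeric vector (a CV point)
#' @export
distances_and_dihedrals <- function(conf, cv_set) {
  vals <- vapply(cv_set, function(cv) evaluate_cv(conf, cv), numeric(1))
  names(vals) <- vapply(cv_set, `[[`, character(1), "name")
  vals
}

#' Count heavy-atom contacts between two groups
#'
#' A contact is a pair of heavy atoms (one per group) strictly closer than
#' `cutoff`. Hydrogens are excluded by element.
#'
#' @param conf a [conformation()]
#' @param group_a,group_b disjoint selections
#' @param cutoff contact cutoff in Angstrom (default 4.5)
#' @return integer number of contacts
#' @export
count_contacts <- function(conf, group_a, group_b, cutoff = 4.5) {
  ia <- resolve_selection(conf, group_a)
  ib <- resolve_selection(conf, group_b)
  ia <- ia[conf$element[ia] != "H"]
  ib <- ib[conf$element[ib] != "H"]
  if (length(intersect(ia, ib)) > 0) stop("contact groups overlap (selection error)")
  if (length(ia) == 0 || length(ib) == 0) return(0L)
  A <- conf$xyz[ia, , drop = FALSE]
  B <- conf$xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  sum(d2 < cutoff^2 - 1e-12)
}
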