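#' Construct a conformation
#'
#' An ordered set of atom records (name, residue index, element, Cartesian
#' coordinates in Angstrom) — the unit of structural analysis. Atom order is
#' fixed and meaningful: selections index into it and frames of an ensemble
#' must share it.
#'
#' @param atom character vector of atom names (e.g. "CA", "O")
#' @param resid integer residue indices (1-based, PDB-style)
#' @param element character element symbols ("C", "N", "O", ...)
#' @param xyz numeric n x 3 matrix of coordinates in Angstrom
#' @param chain optional chain identifiers
#' @return object of class `conformation`
#' @export
conformation <- function(atom, resid, element, xyz, chain = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  stopifnot(length(atom) == n, length(resid) == n, length(element) == n,
            all(is.finite(xyz)))
  structure(list(atom = as.character(atom), resid = as.integer(resid),
                 element = as.character(element), xyz = xyz,
                 chain = if (is.null(chain)) rep(NA_character_, n) else as.character(chain)),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("conformation: %d atoms, residues %d..%d\n",
              nrow(x$xyz), min(x$resid), max(x$resid)))
  invisible(x)
}

n_atoms <- function(conf) nrow(conf$xyz)

#' Atom selection
#'
#' A minimal selection grammar: residue ranges plus atom-name and element
#' filters, combined conjunctively. `NULL` fields match everything.
#'
#' @param resid integer vector of residue indices to keep (e.g. `485:493`)
#' @param atoms character vector of atom names to keep (e.g. `c("N","CA","C","O")`)
#' @param elements character vector of element symbols to keep
#' @param exclude_elements elements to drop (e.g. `"H"` for heavy atoms)
#' @return object of class `atom_selection`
#' @export
sel <- function(resid = NULL, atoms = NULL, elements = NULL, exclude_elements = NULL) {
  structure(list(resid = resid, atoms = atoms, elements = elements,
                 exclude_elements = exclude_elements),
            class = "atom_selection")
}

#' Resolve a selection to atom indices
#'
#' @param conf a [conformation()]
#' @param selection an [sel()] object, an integer index vector, or `NULL`
#'   (all atoms)
#' @return integer vector of atom indices in conformation order
#' @export
resolve_selection <- function(conf, selection) {
  if (is.null(selection)) return(seq_len(n_atoms(conf)))
  if (is.numeric(selection)) return(as.integer(selection))
  stopifnot(inherits(selection, "atom_selection"))
  keep <- rep(TRUE, n_atoms(conf))
  if (!is.null(selection$resid)) keep <- keep & conf$resid %in% selection$resid
  if (!is.null(selection$atoms)) keep <- keep & conf$atom %in% selection$atoms
  if (!is.null(selection$elements)) keep <- keep & conf$element %in% selection$elements
  if (!is.null(selection$exclude_elements))
    keep <- keep & !(conf$element %in% selection$exclude_elements)
  idx <- which(keep)
  if (length(idx) == 0) stop("selection resolves to zero atoms (selection error)")
  idx
}

#' Apply a rigid-body transform to a conformation
#'
#' @param conf a [conformation()]
#' @param rotation 3 x 3 proper rotation matrix
#' @param translation length-3 translation vector (applied after rotation)
#' @return transformed [conformation()]
#' @export
transform_conformation <- function(conf, rotation = diag(3), translation = c(0, 0, 0)) {
  conf$xyz <- conf$xyz %*% t(rotation) + matrix(translation, n_atoms(conf), 3, byrow = TRUE)
  conf
}

#' Rotation matrix about an axis
#'
#' @param axis length-3 axis vector (normalised internally)
#' @param angle_deg rotation angle in degrees
#' @return 3 x 3 rotation matrix
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Read a conformation (or multi-model ensemble) from a PDB file
#'
#' Parses ATOM/HETATM records via bio3d; for alternate locations only the
#' highest-occupancy altloc of each atom is kept. Hydrogens are retained
#' (filter with [sel()] if needed).
#'
#' @param path PDB file path
#' @param multi if TRUE return a list of conformations (one per MODEL)
#' @return a [conformation()] or list thereof
#' @export
read_pdb_conformation <- function(path, multi = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  a <- pdb$atom
  # keep highest-occupancy altloc per (resid, atom name)
  if (any(nzchar(a$alt) & !is.na(a$alt))) {
    key <- paste(a$chain, a$resno, a$elety)
    occ <- ifelse(is.na(a$o), 1, a$o)
    keep <- logical(nrow(a))
    for (k in unique(key)) {
      i <- which(key == k)
      keep[i[which.max(occ[i])]] <- TRUE
    }
    a <- a[keep, , drop = FALSE]
    xyz_all <- pdb$xyz[, as.vector(rbind(keep, keep, keep)), drop = FALSE]
  } else {
    xyz_all <- pdb$xyz
  }
  elem <- a$elesy
  if (is.null(elem) || all(!nzchar(elem))) elem <- substr(gsub("[0-9]", "", a$elety), 1, 1)
  build <- function(xyzrow)
    conformation(a$elety, a$resno, elem, matrix(xyzrow, ncol = 3, byrow = TRUE),
                 chain = a$chain)
  if (multi && nrow(xyz_all) > 1) {
    lapply(seq_len(nrow(xyz_all)), function(i) build(xyz_all[i, ]))
  } else {
    build(xyz_all[1, ])
  }
}

#' Write conformations to a (multi-model) PDB file
#'
#' @param confs a [conformation()] or list of them (written as MODELs)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pdb_conformation <- function(confs, path) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(confs) > 1
  for (m in seq_along(confs)) {
    cf <- confs[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(n_atoms(cf))) {
      writeLines(sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                         i, substr(cf$atom[i], 1, 4), "GLY",
                         ifelse(is.na(cf$chain[i]), "A", cf$chain[i]),
                         cf$resid[i], cf$xyz[i, 1], cf$xyz[i, 2], cf$xyz[i, 3],
                         1.0, 0.0, cf$element[i]), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
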