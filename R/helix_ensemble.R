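#' Ideal bead-helix reference conformations
#'
#' Builds an N-bead poly-CA chain on an ideal alpha-helical spiral
#' (radius 2.3 A, rise 1.5 A per residue, 100 degrees per turn step), either
#' straight or with a kink: beyond the midpoint the helical axis is bent by
#' `kink_angle` degrees. The pair emulates the straight vs locally-kinked
#' backbone states of a helix undergoing a conformational transition.
#'
#' @param n_beads number of beads (residues)
#' @param kink_angle bend angle in degrees (0 = straight)
#' @param start_resid residue index of the first bead
#' @return a [conformation()] of CA beads
#' @export
make_bead_helix <- function(n_beads = 9, kink_angle = 0, start_resid = 485) {
  r <- 2.3; rise <- 1.5; step <- 100 * pi / 180
  t <- seq_len(n_beads) - 1
  xyz <- cbind(r * cos(t * step), r * sin(t * step), rise * t)
  if (kink_angle != 0) {
    mid <- ceiling(n_beads / 2)
    pivot <- xyz[mid, ]
    R <- rotation_about_axis(c(1, 0, 0), kink_angle)
    tail_idx <- (mid + 1):n_beads
    xyz[tail_idx, ] <- sweep(sweep(xyz[tail_idx, , drop = FALSE], 2, pivot) %*% t(R),
                             2, pivot, `+`)
  }
  conformation(rep("CA", n_beads), start_resid + t, rep("C", n_beads), xyz)
}

#' Generate a toy helix conformer ensemble
#'
#' Frames are copies of the straight or kinked reference bead helix, plus
#' isotropic Gaussian coordinate noise, each subjected to a random rigid-body
#' rotation and translation. Ground-truth state labels are recorded. The
#' ensemble emulates trajectory frames of a helix sampled on either side of a
#' kinking transition, for exercising RMSD-based clustering and
#' representative-structure extraction.
#'
#' @param n_frames number of frames
#' @param mixture named fractions per state, e.g. `c(straight = 0.7, kinked
#'   = 0.3)`; must sum to 1
#' @param noise_amplitude per-coordinate Gaussian noise s.d. in Angstrom
#' @param seed master seed (fans out to noise and rigid-motion streams)
#' @param n_beads beads per frame
#' @param kink_angle kink angle of the kinked reference, degrees
#' @return object of class `toy_helix_ensemble`: list with `frames`,
#'   `state_labels`, `reference_straight`, `reference_kinked`
#' @export
generate_toy_helix_ensemble <- function(n_frames, mixture = c(straight = 0.7, kinked = 0.3),
                                        noise_amplitude = 0.1, seed = 1,
                                        n_beads = 9, kink_angle = 40) {
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture fractions must sum to 1")
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0")
  refs <- list(straight = make_bead_helix(n_beads, 0),
               kinked = make_bead_helix(n_beads, kink_angle))
  states <- names(mixture)
  if (!all(states %in% names(refs)))
    stop("mixture names must be 'straight' and/or 'kinked'")
  # deterministic counts per state (rounded, remainder to the first state)
  counts <- floor(mixture * n_frames)
  counts[1] <- counts[1] + (n_frames - sum(counts))
  labels <- rep(states, counts)
  frames <- vector("list", n_frames)
  set.seed(substream_seed(seed, "ensemble"))
  for (i in seq_len(n_frames)) {
    cf <- refs[[labels[i]]]
    if (noise_amplitude > 0)
      cf$xyz <- cf$xyz + matrix(stats::rnorm(3 * n_atoms(cf), 0, noise_amplitude),
                                ncol = 3)
    axis <- stats::rnorm(3); ang <- stats::runif(1, 0, 360)
    R <- rotation_about_axis(axis, ang)
    tr <- stats::runif(3, -20, 20)
    frames[[i]] <- transform_conformation(cf, R, tr)
  }
  structure(list(frames = frames, state_labels = labels,
                 reference_straight = refs$straight,
                 reference_kinked = refs$kinked),
            class = "toy_helix_ensemble")
}

#' @export
print.toy_helix_ensemble <- function(x, ...) {
  cat(sprintf("toy_helix_ensemble: %d frames (%s), %d beads\n",
              length(x$frames),
              paste(sprintf("%s %.0f%%", names(table(x$state_labels)),
                            100 * table(x$state_labels) / length(x$frames)),
                    collapse = ", "),
              n_atoms(x$frames[[1]])))
  invisible(x)
}
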