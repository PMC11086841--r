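#' Pairwise RMSD matrix of an ensemble of frames
#'
#' Symmetric matrix of Kabsch-minimal RMSDs between all frame pairs over the
#' given selection (e.g. the CA atoms of the two helices flanking a
#' conformational switch).
#'
#' @param frames list of [conformation()]s with identical atom ordering
#' @param selection atom selection for the fit and the RMSD
#' @return n x n symmetric matrix in Angstrom (zero diagonal)
#' @export
pairwise_rmsd_matrix <- function(frames, selection = NULL) {
  n <- length(frames)
  if (n < 2) stop("need at least 2 frames")
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- rmsd_fit(frames[[i]], frames[[j]], selection)
    m[i, j] <- r; m[j, i] <- r
  }
  m
}

#' Agglomerative clustering of frames from a distance matrix
#'
#' Deterministic average-linkage hierarchical clustering (base `hclust`) cut
#' at `n_clusters`, with occupancy fractions and the most populated cluster
#' (ties broken toward the lowest label). Labels are contiguous from 1 in
#' order of first appearance.
#'
#' @param matrix symmetric distance matrix (e.g. [pairwise_rmsd_matrix()])
#' @param n_clusters number of clusters, 1..n_frames
#' @return object of class `cluster_model`: `labels`, `occupancy`,
#'   `top_cluster`, `linkage`
#' @export
cluster_frames <- function(matrix, n_clusters) {
  n <- nrow(matrix)
  if (n_clusters < 1 || n_clusters > n) stop("invalid n_clusters")
  if (n_clusters == n) {
    labels <- seq_len(n)
  } else if (n_clusters == 1) {
    labels <- rep(1L, n)
  } else {
    hc <- stats::hclust(stats::as.dist(matrix), method = "average")
    raw <- stats::cutree(hc, k = n_clusters)
    labels <- match(raw, unique(raw))   # contiguous, order of first appearance
  }
  occ <- as.numeric(table(factor(labels, levels = seq_len(n_clusters)))) / n
  structure(list(labels = labels, occupancy = occ,
                 top_cluster = which.max(occ),   # ties -> lowest label
                 linkage = "average"),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: %d clusters (%s), top cluster %d\n",
              length(x$occupancy),
              paste(sprintf("%.1f%%", 100 * x$occupancy), collapse = ", "),
              x$top_cluster))
  invisible(x)
}

#' Smallest cluster count meeting an occupancy rule
#'
#' Advisory routine: increases the number of clusters until at least
#' `n_required` clusters exceed `min_occupancy`, or the frame count is
#' reached.
#'
#' @param matrix distance matrix
#' @param min_occupancy occupancy threshold (default 10%)
#' @param n_required required number of well-populated clusters
#' @return chosen number of clusters
#' @export
advise_n_clusters <- function(matrix, min_occupancy = 0.1, n_required = 2) {
  for (k in seq(n_required, nrow(matrix))) {
    cm <- cluster_frames(matrix, k)
    if (sum(cm$occupancy > min_occupancy) >= n_required) return(k)
  }
  nrow(matrix)
}

#' Representative (average) structure of the most populated cluster
#'
#' Aligns every frame of the most populated cluster onto its first member
#' over `align_selection`, then takes the coordinate-wise mean over all
#' atoms.
#'
#' @param frames list of [conformation()]s
#' @param model a [cluster_model()]
#' @param align_selection selection used for the alignment fit
#' @return a [conformation()] (the average structure)
#' @export
representative_structure <- function(frames, model, align_selection = NULL) {
  idx <- which(model$labels == model$top_cluster)
  if (length(idx) == 0) stop("most populated cluster is empty")
  ref <- frames[[idx[1]]]
  acc <- matrix(0, n_atoms(ref), 3)
  for (i in idx) {
    fit <- superpose_kabsch(frames[[i]], ref, align_selection)
    acc <- acc + (frames[[i]]$xyz %*% t(fit$rotation) +
                    matrix(fit$translation, n_atoms(ref), 3, byrow = TRUE))
  }
  out <- ref
  out$xyz <- acc / length(idx)
  out
}

#' Typical frame: closest to the ensemble average
#'
#' Frames are aligned to the first frame over `align_selection`, the
#' all-atom average structure is computed, and the index of the frame
#' minimising the RMSD to the average over `rmsd_selection` is returned
#' (ties toward the lowest index).
#'
#' @param frames list of [conformation()]s
#' @param align_selection selection for the common alignment
#' @param rmsd_selection selection for the RMSD to the average
#' @return frame index (1-based)
#' @export
typical_frame <- function(frames, align_selection = NULL, rmsd_selection = NULL) {
  n <- length(frames)
  if (n == 1) return(1L)
  ref <- frames[[1]]
  aligned <- vector("list", n)
  acc <- matrix(0, n_atoms(ref), 3)
  for (i in seq_len(n)) {
    fit <- superpose_kabsch(frames[[i]], ref, align_selection)
    al <- transform_conformation(frames[[i]], fit$rotation, fit$translation)
    aligned[[i]] <- al
    acc <- acc + al$xyz
  }
  avg <- ref
  avg$xyz <- acc / n
  isel <- resolve_selection(ref, rmsd_selection)
  d <- vapply(aligned, function(f)
    sqrt(mean(rowSums((f$xyz[isel, , drop = FALSE] - avg$xyz[isel, , drop = FALSE])^2))),
    numeric(1))
  which.min(d)   # ties -> lowest index
}

#' Elliptical metastable-state region
#'
#' @param name state name
#' @param center named CV-space centre
#' @param semi_axes named per-axis semi-axes (> 0), same names as `center`
#' @return object of class `state_region`
#' @export
state_region <- function(name, center, semi_axes) {
  stopifnot(all(semi_axes > 0), length(center) == length(semi_axes))
  if (!identical(sort(names(center)), sort(names(semi_axes))))
    stop("center and semi_axes must share axis names")
  structure(list(name = name, center = center,
                 semi_axes = semi_axes[names(center)]),
            class = "state_region")
}

#' Assign CV frames to elliptical state regions
#'
#' A frame belongs to a region iff
#' `sum_i ((z_i - center_i)/semi_axis_i)^2 <= 1`; when regions overlap the
#' first-listed wins; otherwise the frame is `"unassigned"`.
#'
#' @param cv_series matrix (frames x CVs) with column names matching region
#'   axis names
#' @param regions list of [state_region()]s
#' @return character vector of state names / "unassigned"
#' @export
assign_states <- function(cv_series, regions) {
  cv_series <- as.matrix(cv_series)
  out <- rep("unassigned", nrow(cv_series))
  for (reg in regions) {
    ax <- names(reg$center)
    if (!all(ax %in% colnames(cv_series)))
      stop(sprintf("region '%s': CV axes %s missing from series", reg$name,
                   paste(setdiff(ax, colnames(cv_series)), collapse = ", ")))
    z <- cv_series[, ax, drop = FALSE]
    q <- rowSums(sweep(sweep(z, 2, reg$center), 2, reg$semi_axes, `/`)^2)
    hit <- q <= 1 & out == "unassigned"
    out[hit] <- reg$name
  }
  out
}

#' Swing fraction from a calibrated total displacement
#'
#' Expresses a displacement as a percentage of a total conformational swing,
#' calibrated by a reference displacement with a known fraction:
#' `total = reference_displacement * 100 / reference_fraction`, returned
#' value `100 * displacement / total`.
#'
#' @param displacement displacement magnitude (Angstrom), or a vector whose
#'   Euclidean norm is used
#' @param total_calibration numeric `c(reference displacement, reference
#'   fraction in percent)`
#' @return percentage of the total swing
#' @export
swing_fraction <- function(displacement, total_calibration) {
  ref_d <- total_calibration[1]; ref_f <- total_calibration[2]
  if (!(ref_f > 0 && ref_f <= 100) || !(ref_d > 0))
    stop("calibration must have displacement > 0 and fraction in (0, 100]")
  dnorm_ <- sqrt(sum(displacement^2))
  total <- ref_d * 100 / ref_f
  100 * dnorm_ / total
}
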