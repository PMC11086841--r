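#' Serialize a bias grid to structured text (restartable)
#'
#' Header lines carry the grid geometry and coupling constants; the body is
#' one row per bin with counts and running sums.
#'
#' @param grid a [bias_grid()]
#' @param file output path
#' @return `file` invisibly
#' @export
write_bias_grid <- function(grid, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# bias_grid ncv=%d", grid$ncv),
    sprintf("# nbins=%s", paste(grid$nbins, collapse = ",")),
    sprintf("# lower=%s", paste(format(grid$lower, digits = 17), collapse = ",")),
    sprintf("# upper=%s", paste(format(grid$upper, digits = 17), collapse = ",")),
    sprintf("# k=%s", paste(format(grid$k, digits = 17), collapse = ",")),
    sprintf("# full_samples=%g clamp=%d", grid$full_samples, as.integer(grid$clamp))), con)
  df <- data.frame(bin = seq_along(grid$count_z), count_z = grid$count_z,
                   grid$sum_lambda, grid$sum_z, count_l = grid$count_l,
                   grid$sum_force)
  names(df) <- c("bin", "count_z", paste0("sum_lambda", seq_len(grid$ncv)),
                 paste0("sum_z", seq_len(grid$ncv)),
                 "count_l", paste0("sum_force", seq_len(grid$ncv)))
  utils::write.table(format(df, digits = 17), con, row.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(file)
}

#' @rdname write_bias_grid
#' @export
read_bias_grid <- function(file) {
  lines <- readLines(file, n = 6)
  gv <- function(i, key) {
    m <- regmatches(lines[i], regexec(paste0(key, "=([^ ]+)"), lines[i]))[[1]][2]
    as.numeric(strsplit(m, ",")[[1]])
  }
  ncv <- gv(1, "ncv")
  nbins <- gv(2, "nbins"); lower <- gv(3, "lower"); upper <- gv(4, "upper")
  k <- gv(5, "k")
  fs <- gv(6, "full_samples"); clamp <- gv(6, "clamp") == 1
  g <- bias_grid(lower, upper, nbins, k, full_samples = fs, clamp = clamp)
  df <- utils::read.table(file, header = TRUE, skip = 6, sep = "\t")
  g$count_z <- df$count_z
  g$sum_lambda <- as.matrix(df[, paste0("sum_lambda", seq_len(ncv)), drop = FALSE])
  g$sum_z <- as.matrix(df[, paste0("sum_z", seq_len(ncv)), drop = FALSE])
  g$count_l <- df$count_l
  g$sum_force <- as.matrix(df[, paste0("sum_force", seq_len(ncv)), drop = FALSE])
  dimnames(g$sum_lambda) <- NULL; dimnames(g$sum_force) <- NULL
  dimnames(g$sum_z) <- NULL
  g
}

#' Export a free-energy surface as tabular text
#'
#' Columns: bin midpoints (1 or 2), free energy, count, error (if present).
#'
#' @param surface a [fes()]
#' @param file output path
#' @return `file` invisibly
#' @export
write_fes <- function(surface, file) {
  if (surface$ndim == 1) {
    df <- data.frame(z1 = surface$midpoints[[1]], F = as.numeric(surface$values))
  } else {
    g <- expand.grid(z1 = surface$midpoints[[1]], z2 = surface$midpoints[[2]])
    df <- data.frame(g, F = as.numeric(surface$values))
  }
  if (!is.null(surface$counts)) df$count <- as.numeric(surface$counts)
  if (!is.null(surface$errors)) df$error <- as.numeric(surface$errors)
  utils::write.table(df, file, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(file)
}

#' Serialize a model potential's samples or a conformer ensemble to text
#'
#' Writes conformations as a whitespace-separated fixture: one header line
#' per frame (`frame <i> <n_atoms> <label>`) then atom rows
#' (name resid element x y z).
#'
#' @param frames list of [conformation()]s
#' @param file output path
#' @param labels optional per-frame labels
#' @return `file` invisibly
#' @export
write_conformer_fixture <- function(frames, file, labels = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    cf <- frames[[i]]
    lab <- if (is.null(labels)) "." else labels[i]
    writeLines(sprintf("frame %d %d %s", i, n_atoms(cf), lab), con)
    writeLines(sprintf("%s %d %s %.10g %.10g %.10g", cf$atom, cf$resid,
                       cf$element, cf$xyz[, 1], cf$xyz[, 2], cf$xyz[, 3]), con)
  }
  invisible(file)
}

#' @rdname write_conformer_fixture
#' @export
read_conformer_fixture <- function(file) {
  lines <- readLines(file)
  frames <- list(); labels <- character(0)
  i <- 1
  while (i <= length(lines)) {
    hd <- strsplit(lines[i], " +")[[1]]
    stopifnot(hd[1] == "frame")
    na <- as.integer(hd[3])
    rows <- lines[(i + 1):(i + na)]
    parts <- do.call(rbind, strsplit(rows, " +"))
    frames[[length(frames) + 1]] <- conformation(
      parts[, 1], as.integer(parts[, 2]), parts[, 3],
      matrix(as.numeric(parts[, 4:6]), ncol = 3))
    labels <- c(labels, hd[4])
    i <- i + na + 1
  }
  list(frames = frames, labels = labels)
}
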