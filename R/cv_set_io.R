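#' Write / read a CV-set definition file
#'
#' Serializes a catalogue of [cv_definition()]s to a YAML document: kind,
#' selections (residue ranges, atom-name and element filters), projection
#' axis and biased-use force constant. Reference conformations are not
#' embedded; they are re-attached at read time (structures travel as PDB or
#' fixture files).
#'
#' @param cv_set list of [cv_definition()]s
#' @param file output path
#' @return `file` invisibly
#' @export
write_cv_set <- function(cv_set, file) {
  enc_sel <- function(s) {
    if (is.null(s)) return(NULL)
    if (is.numeric(s)) return(list(index = as.integer(s)))
    Filter(Negate(is.null),
           list(resid = s$resid, atoms = s$atoms, elements = s$elements,
                exclude_elements = s$exclude_elements))
  }
  doc <- lapply(cv_set, function(cv) {
    Filter(Negate(is.null), list(
      name = cv$name, kind = cv$kind,
      selections = lapply(cv$selections, enc_sel),
      axis = if (cv$kind == "principal_axes_projection") cv$axis else NULL,
      n_references = length(cv$references),
      force_constant = if (is.finite(cv$force_constant)) cv$force_constant else NULL))
  })
  yaml::write_yaml(doc, file)
  invisible(file)
}

#' @rdname write_cv_set
#' @param references list of reference [conformation()]s to re-attach, in
#'   the order the definitions consume them
#' @export
read_cv_set <- function(file, references = list()) {
  doc <- yaml::read_yaml(file)
  ref_i <- 0
  dec_sel <- function(s) {
    if (!is.null(s$index)) return(as.integer(s$index))
    sel(resid = s$resid, atoms = s$atoms, elements = s$elements,
        exclude_elements = s$exclude_elements)
  }
  lapply(doc, function(d) {
    nref <- if (is.null(d$n_references)) 0 else d$n_references
    refs <- if (nref > 0) references[ref_i + seq_len(nref)] else list()
    ref_i <<- ref_i + nref
    cv_definition(d$name, d$kind,
                  selections = lapply(d$selections, dec_sel),
                  references = refs,
                  axis = if (is.null(d$axis)) "X" else d$axis,
                  force_constant = if (is.null(d$force_constant)) NA_real_
                                   else d$force_constant)
  })
}

#' Export umbrella-window samples as tabular text
#'
#' One row per recorded frame: window id, alpha, then the CV values; a
#' header block carries the per-window centres and force constants.
#'
#' @param ensemble a [window_ensemble()]
#' @param file output path
#' @return `file` invisibly
#' @export
write_window_ensemble <- function(ensemble, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature %.10g", ensemble$temperature), con)
  for (i in seq_along(ensemble$windows)) {
    w <- ensemble$windows[[i]]
    writeLines(sprintf("# window %d alpha %.10g center %s k %s", i, w$alpha,
                       paste(format(w$center, digits = 12), collapse = ","),
                       paste(format(w$k, digits = 12), collapse = ",")), con)
  }
  all <- do.call(rbind, lapply(seq_along(ensemble$windows), function(i) {
    w <- ensemble$windows[[i]]
    data.frame(window = i, alpha = w$alpha, w$samples, check.names = FALSE)
  }))
  utils::write.table(all, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(file)
}

#' @rdname write_window_ensemble
#' @export
read_window_ensemble <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  temperature <- as.numeric(sub("# temperature ", "", hdr[1]))
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", check.names = FALSE)
  cvcols <- setdiff(names(df), c("window", "alpha"))
  windows <- lapply(sort(unique(df$window)), function(i) {
    h <- hdr[i + 1]
    m <- regmatches(h, regexec("alpha ([^ ]+) center ([^ ]+) k ([^ ]+)", h))[[1]]
    rows <- df$window == i
    samples <- as.matrix(df[rows, cvcols, drop = FALSE])
    list(center = as.numeric(strsplit(m[3], ",")[[1]]),
         k = as.numeric(strsplit(m[4], ",")[[1]]),
         samples = samples, alpha = as.numeric(m[2]))
  })
  structure(list(windows = windows, temperature = temperature, path = NULL),
            class = "window_ensemble")
}

#' Export cluster assignments and occupancies as tabular text
#'
#' @param model a [cluster_model()]
#' @param file output path
#' @return `file` invisibly
#' @export
write_cluster_assignments <- function(model, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# occupancy %s", paste(format(model$occupancy, digits = 6),
                                             collapse = ",")), con)
  writeLines(sprintf("# top_cluster %d  linkage %s", model$top_cluster,
                     model$linkage), con)
  utils::write.table(data.frame(frame = seq_along(model$labels),
                                cluster = model$labels),
                     con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(file)
}
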