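#' Read node labels from a text file
#'
#' One region identifier per line; order is significant and defines the shared
#' node ordering of a study.
#'
#' @param path Text file path.
#' @return Character vector of labels.
#' @export
read_node_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("node labels file not found: '%s'.", path))
  labs <- trimws(readLines(path, warn = FALSE))
  labs <- labs[nzchar(labs)]
  if (length(labs) == 0) abort(sprintf("no labels in '%s'.", path))
  if (anyDuplicated(labs)) abort(sprintf("duplicate labels in '%s'.", path))
  labs
}

parse_numeric_row <- function(fields, path, row) {
  vals <- suppressWarnings(as.numeric(fields))
  bad <- which(is.na(vals) & !(fields %in% c("NA", "NaN")))
  if (length(bad) > 0) {
    abort(sprintf("'%s': non-numeric cell at row %d, column %d ('%s').",
                  path, row, bad[1], fields[bad[1]]))
  }
  vals
}

#' Read an adjacency matrix from delimited text
#'
#' The file must hold a square numeric matrix, optionally preceded by a single
#' header row of node labels. If a header is present it must match
#' `node_labels`. Parsed values go through the [brain_graph()] invariants:
#' symmetrization within tolerance, zero diagonal, modality-specific range
#' checks.
#'
#' @param path Delimited text file.
#' @param node_labels Expected node ordering; `NULL` accepts the header labels
#'   (or positional labels when no header).
#' @param modality `"structural"` or `"functional"`.
#' @param delimiter Field separator (`","` or `"\t"`).
#' @param subject_id Subject identifier; defaults to the file name.
#' @param symmetry_tol Passed to [brain_graph()].
#' @return A [brain_graph()].
#' @export
read_adjacency <- function(path, node_labels = NULL,
                           modality = c("structural", "functional"),
                           delimiter = ",",
                           subject_id = sub("\\.[^.]*$", "", basename(path)),
                           symmetry_tol = 1e-9) {
  modality <- match.arg(modality)
  if (!file.exists(path)) abort(sprintf("adjacency file not found: '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("'%s' is empty.", path))
  rows <- strsplit(lines, delimiter, fixed = TRUE)
  first <- trimws(rows[[1]])
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  header <- NULL
  if (has_header) {
    header <- first
    rows <- rows[-1]
  }
  ncols <- length(rows[[1]])
  mat <- matrix(NA_real_, length(rows), ncols)
  for (i in seq_along(rows)) {
    fields <- trimws(rows[[i]])
    if (length(fields) != ncols) {
      abort(sprintf("'%s': row %d has %d fields, expected %d.",
                    path, i + has_header, length(fields), ncols))
    }
    mat[i, ] <- parse_numeric_row(fields, path, i + has_header)
  }
  if (nrow(mat) != ncol(mat)) {
    abort(sprintf("'%s': matrix is %d x %d, not square.",
                  path, nrow(mat), ncol(mat)))
  }
  if (!is.null(header)) {
    if (length(header) != ncol(mat)) {
      abort(sprintf("'%s': header has %d labels for %d columns.",
                    path, length(header), ncol(mat)))
    }
    if (!is.null(node_labels) && !identical(header, as.character(node_labels))) {
      abort(sprintf("'%s': header labels do not match the expected node ordering.",
                    path))
    }
    node_labels <- header
  }
  if (!is.null(node_labels) && length(node_labels) != nrow(mat)) {
    abort(sprintf("'%s': %d node labels for a %d x %d matrix.",
                  path, length(node_labels), nrow(mat), ncol(mat)))
  }
  if (any(diag(mat) != 0)) {
    inform(sprintf("'%s': nonzero diagonal entries set to 0.", path))
  }
  tryCatch(
    brain_graph(mat, node_labels, modality, subject_id, symmetry_tol),
    error = function(e) {
      abort(sprintf("'%s': %s", path, conditionMessage(e)))
    })
}

#' Write an adjacency matrix as delimited text
#'
#' Writes the full square matrix (not just a triangle, for human
#' inspectability) with a header row of node labels, using 17 significant
#' digits so doubles round-trip bit-faithfully through [read_adjacency()].
#'
#' @param graph A [brain_graph()].
#' @param path Output file.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(graph, path, delimiter = ",") {
  stopifnot(is_brain_graph(graph))
  lines <- c(paste(graph$node_labels, collapse = delimiter),
             apply(graph$weights, 1, function(r)
               paste(sprintf("%.17g", r), collapse = delimiter)))
  tryCatch(writeLines(lines, path),
           error = function(e) abort(sprintf("cannot write '%s': %s",
                                             path, conditionMessage(e))))
  invisible(path)
}

#' Read a dataset manifest
#'
#' The manifest is a YAML file assigning each adjacency file its subject id,
#' class label and modality, plus study-wide options:
#'
#' ```yaml
#' node_labels: labels.txt
#' delimiter: ","
#' functional_threshold: 0
#' graphs:
#'   - {path: sA01.csv, subject: sA01, class: A, modality: structural}
#'   - {path: fB03.csv, subject: fB03, class: B, modality: functional}
#' ```
#'
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest file.
#' @return A `dataset_manifest`: list with `entries` (tibble: `path`,
#'   `subject`, `class`, `modality`), `node_labels_path`, `delimiter`,
#'   `functional_threshold`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: '%s'.", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$graphs) || length(raw$graphs) == 0) {
    abort(sprintf("manifest '%s' lists no graphs.", path))
  }
  root <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  }
  entries <- dplyr::bind_rows(lapply(raw$graphs, function(g) {
    for (f in c("path", "subject", "class", "modality")) {
      if (is.null(g[[f]])) {
        abort(sprintf("manifest '%s': a graph entry is missing field '%s'.",
                      path, f))
      }
    }
    tibble::tibble(path = resolve(as.character(g$path)),
                   subject = as.character(g$subject),
                   class = as.character(g$class),
                   modality = as.character(g$modality))
  }))
  bad_mod <- setdiff(unique(entries$modality), c("structural", "functional"))
  if (length(bad_mod) > 0) {
    abort(sprintf("manifest '%s': unknown modality '%s'.", path, bad_mod[1]))
  }
  missing <- entries$path[!file.exists(entries$path)]
  if (length(missing) > 0) {
    abort(sprintf("manifest '%s': file not found: '%s'.", path, missing[1]))
  }
  if (is.null(raw$node_labels)) {
    abort(sprintf("manifest '%s' must name a node_labels file.", path))
  }
  structure(
    list(entries = entries,
         node_labels_path = resolve(as.character(raw$node_labels)),
         delimiter = raw$delimiter %||% ",",
         functional_threshold = raw$functional_threshold %||% 0),
    class = "dataset_manifest")
}

#' Load the datasets described by a manifest
#'
#' Reads every adjacency file, thresholds functional graphs at the manifest's
#' `functional_threshold`, groups graphs by modality, checks the fixed node
#' correspondence, and reports per-class counts.
#'
#' @param manifest A `dataset_manifest` or a path to one.
#' @param quiet Suppress the load log.
#' @return Named list with the present modalities, each a [graph_dataset()]
#'   (`structural` and/or `functional`).
#' @export
read_dataset <- function(manifest, quiet = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "dataset_manifest"))
  labs <- read_node_labels(manifest$node_labels_path)
  out <- list()
  for (mod in intersect(c("structural", "functional"),
                        unique(manifest$entries$modality))) {
    sel <- manifest$entries[manifest$entries$modality == mod, ]
    classes <- unique(sel$class)
    if (length(classes) != 2) {
      abort(sprintf("%s graphs: two classes required, found %d (%s).",
                    mod, length(classes), paste(classes, collapse = ", ")))
    }
    if (min(table(sel$class)) < 2) {
      abort(sprintf("%s graphs: need at least two graphs per class.", mod))
    }
    graphs <- purrr::map2(sel$path, sel$subject, function(p, s) {
      g <- read_adjacency(p, labs, mod, manifest$delimiter, subject_id = s)
      if (mod == "functional") {
        g <- threshold_positive(g, manifest$functional_threshold)
      }
      g
    })
    ds <- graph_dataset(graphs, sel$class, labs)
    report <- validate_fcvs(ds)
    if (nrow(report) > 0) {
      abort(sprintf("%s dataset fails validation (%d violations).",
                    mod, nrow(report)))
    }
    if (!quiet) {
      tab <- table(sel$class)
      inform(sprintf("loaded %d %s graphs (%s), %d nodes.",
                     nrow(sel), mod,
                     paste(sprintf("%d x %s", tab, names(tab)),
                           collapse = " + "),
                     length(labs)))
    }
    out[[mod]] <- ds
  }
  out
}

#' Write a simulated study as adjacency files plus a manifest
#'
#' Materializes the output of [simulate_dataset()] on disk in the exact layout
#' [read_dataset()] consumes, so the whole command-line pipeline can be
#' exercised end-to-end from nothing.
#'
#' @param sim List with `structural` and `functional` [graph_dataset()]s.
#' @param dir Output directory (created if needed).
#' @param delimiter Field separator for the adjacency files.
#' @return Path of the written manifest, invisibly.
#' @export
write_simulation <- function(sim, dir, delimiter = ",") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labs <- sim$structural$shared_node_labels
  writeLines(labs, file.path(dir, "node_labels.txt"))
  entries <- list()
  for (mod in c("structural", "functional")) {
    ds <- sim[[mod]]
    for (i in seq_along(ds$graphs)) {
      g <- ds$graphs[[i]]
      fname <- paste0(g$subject_id, ".csv")
      write_adjacency(g, file.path(dir, fname), delimiter)
      entries <- c(entries, list(list(path = fname, subject = g$subject_id,
                                      class = ds$class_labels[[i]],
                                      modality = mod)))
    }
  }
  manifest <- list(node_labels = "node_labels.txt", delimiter = delimiter,
                   functional_threshold = 0, graphs = entries)
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}
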