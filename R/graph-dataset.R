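#' Construct a labeled graph dataset
#'
#' A `graph_dataset` bundles the connectivity graphs of one modality for a
#' two-class study: every graph must share the same ordered node-label
#' sequence (the fixed-cardinality vertex sequence, FCVS, property that gives
#' a one-to-one node correspondence across subjects), carry the same modality
#' tag, and have a class label.
#'
#' @param graphs List of [brain_graph()]s.
#' @param class_labels Vector of class labels, one per graph; exactly two
#'   distinct values must occur.
#' @param shared_node_labels The node ordering all graphs must match; defaults
#'   to the first graph's labels.
#' @return An object of class `graph_dataset` with fields `graphs`,
#'   `class_labels` (character), `shared_node_labels`, `modality`.
#' @seealso [validate_fcvs()] for a non-throwing validation report.
#' @export
graph_dataset <- function(graphs, class_labels,
                          shared_node_labels = graphs[[1]]$node_labels) {
  if (length(graphs) == 0) abort("`graphs` must contain at least one graph.")
  stopifnot(all(vapply(graphs, is_brain_graph, logical(1))))
  class_labels <- as.character(class_labels)
  if (length(class_labels) != length(graphs)) {
    abort(sprintf("%d class labels for %d graphs.",
                  length(class_labels), length(graphs)))
  }
  if (length(unique(class_labels)) != 2) {
    abort(sprintf("exactly two classes required; got: %s.",
                  paste(unique(class_labels), collapse = ", ")))
  }
  mods <- unique(vapply(graphs, function(g) g$modality, character(1)))
  if (length(mods) != 1) {
    abort("all graphs in a dataset must share one modality.")
  }
  ds <- structure(
    list(graphs = graphs, class_labels = class_labels,
         shared_node_labels = as.character(shared_node_labels),
         modality = mods),
    class = "graph_dataset")
  report <- validate_fcvs(ds)
  if (nrow(report) > 0) {
    abort(paste0(
      "dataset violates graph invariants:\n",
      paste(sprintf("  - %s: %s", report$subject_id, report$detail),
            collapse = "\n")))
  }
  ds
}

#' @export
print.graph_dataset <- function(x, ...) {
  tab <- table(x$class_labels)
  cat(sprintf("<graph_dataset> %s, %d nodes, %s\n", x$modality,
              length(x$shared_node_labels),
              paste(sprintf("%d x '%s'", tab, names(tab)), collapse = " + ")))
  invisible(x)
}

#' @export
length.graph_dataset <- function(x) length(x$graphs)

is_graph_dataset <- function(x) inherits(x, "graph_dataset")

#' Validate the fixed node correspondence of a dataset
#'
#' Checks every graph of a dataset against the invariants required for the
#' direct connection embedding to be meaningful: node labels identical (and
#' identically ordered) across graphs, square symmetric weight matrices of the
#' right size, and a zero diagonal. Validation never throws; it reports.
#'
#' @param dataset A [graph_dataset()], or a bare list of [brain_graph()]s plus
#'   `shared_node_labels`.
#' @param shared_node_labels Node ordering to check against when `dataset` is
#'   a bare list; ignored otherwise.
#' @param tol Symmetry tolerance.
#' @return A tibble with columns `subject_id`, `violation`
#'   (`"size"`, `"node_labels"`, `"asymmetry"`, `"diagonal"`), `detail`.
#'   Zero rows if and only if all invariants hold.
#' @export
validate_fcvs <- function(dataset, shared_node_labels = NULL, tol = 1e-9) {
  if (is_graph_dataset(dataset)) {
    graphs <- dataset$graphs
    labs <- dataset$shared_node_labels
  } else {
    graphs <- dataset
    labs <- shared_node_labels %||% graphs[[1]]$node_labels
  }
  if (length(graphs) == 0) abort("validate_fcvs() needs at least one graph.")
  l <- length(labs)
  rows <- purrr::map(graphs, function(g) {
    out <- list()
    w <- g$weights
    if (nrow(w) != ncol(w) || nrow(w) != l) {
      out <- c(out, list(tibble::tibble(
        subject_id = g$subject_id, violation = "size",
        detail = sprintf("matrix is %d x %d, expected %d x %d",
                         nrow(w), ncol(w), l, l))))
    }
    if (!identical(g$node_labels, labs)) {
      out <- c(out, list(tibble::tibble(
        subject_id = g$subject_id, violation = "node_labels",
        detail = "node labels differ from the shared ordering")))
    }
    if (nrow(w) == ncol(w)) {
      asym <- max(abs(w - t(w)))
      if (asym > tol) {
        out <- c(out, list(tibble::tibble(
          subject_id = g$subject_id, violation = "asymmetry",
          detail = sprintf("max |A - t(A)| = %.3g exceeds %.3g", asym, tol))))
      }
      if (any(diag(w) != 0)) {
        out <- c(out, list(tibble::tibble(
          subject_id = g$subject_id, violation = "diagonal",
          detail = "diagonal has nonzero entries")))
      }
    }
    out
  })
  rows <- purrr::list_flatten(rows)
  if (length(rows) == 0) {
    tibble::tibble(subject_id = character(), violation = character(),
                   detail = character())
  } else {
    dplyr::bind_rows(rows)
  }
}
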