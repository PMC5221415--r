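#' Construct a brain connectivity graph
#'
#' A `brain_graph` is a simple, undirected, node-labeled, edge-weighted graph
#' stored as a square symmetric adjacency matrix. Absent edges are encoded as
#' exact zeros, so the edge set is implicitly the set of node pairs with
#' nonzero weight. Structural graphs carry nonnegative streamline-count-like
#' weights; functional graphs carry correlation weights in \[-1, 1\]
#' (nonnegative after positive thresholding).
#'
#' On construction the matrix is symmetrized as `(A + t(A)) / 2` when the
#' maximum asymmetry is below `symmetry_tol` (larger asymmetries are an error,
#' usually indicating a corrupt file), and the diagonal is forced to zero
#' (self-loops carry no between-region information; correlation matrices
#' arrive with ones on the diagonal).
#'
#' @param weights Square numeric matrix of edge weights.
#' @param node_labels Character vector of unique region identifiers, one per
#'   node, in a fixed order shared across a study. Defaults to the matrix
#'   rownames.
#' @param modality `"structural"` or `"functional"`.
#' @param subject_id Identifier for the subject the graph belongs to.
#' @param symmetry_tol Maximum tolerated `max(abs(A - t(A)))` before the
#'   matrix is rejected as asymmetric.
#' @return An object of class `brain_graph`: a list with fields
#'   `node_labels`, `weights`, `modality`, `subject_id`.
#' @examples
#' g <- brain_graph(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3),
#'                  node_labels = c("a", "b", "c"), modality = "structural")
#' g$weights["a", "c"]
#' @export
brain_graph <- function(weights,
                        node_labels = rownames(weights),
                        modality = c("structural", "functional"),
                        subject_id = "subject",
                        symmetry_tol = 1e-9) {
  modality <- match.arg(modality)
  if (!is.matrix(weights) || !is.numeric(weights)) {
    abort("`weights` must be a numeric matrix.")
  }
  if (nrow(weights) != ncol(weights)) {
    abort(sprintf("`weights` must be square; got %d x %d.",
                  nrow(weights), ncol(weights)))
  }
  if (is.null(node_labels)) {
    node_labels <- sprintf("n%02d", seq_len(nrow(weights)))
  }
  node_labels <- as.character(node_labels)
  if (length(node_labels) != nrow(weights)) {
    abort(sprintf(
      "subject '%s': %d node labels for a %d x %d matrix.",
      subject_id, length(node_labels), nrow(weights), ncol(weights)))
  }
  if (anyDuplicated(node_labels)) {
    abort(sprintf("subject '%s': node labels must be unique.", subject_id))
  }
  if (anyNA(weights)) {
    abort(sprintf("subject '%s': weights contain missing values.", subject_id))
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > symmetry_tol) {
    abort(sprintf(
      "subject '%s': adjacency matrix is asymmetric (max |A - t(A)| = %.3g > %.3g).",
      subject_id, asym, symmetry_tol))
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (modality == "structural" && any(weights < 0)) {
    abort(sprintf("subject '%s': structural weights must be nonnegative.",
                  subject_id))
  }
  if (modality == "functional" && any(abs(weights) > 1 + 1e-12)) {
    abort(sprintf(
      "subject '%s': functional weights must be correlations in [-1, 1].",
      subject_id))
  }
  dimnames(weights) <- list(node_labels, node_labels)
  structure(
    list(node_labels = node_labels, weights = weights,
         modality = modality, subject_id = as.character(subject_id)),
    class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("<brain_graph> subject '%s', %s, %d nodes, %d nonzero edges\n",
              x$subject_id, x$modality, length(x$node_labels), nz))
  invisible(x)
}

is_brain_graph <- function(x) inherits(x, "brain_graph")

#' Number of nodes of a brain graph
#' @param graph A [brain_graph()].
#' @return Integer node count.
#' @export
n_nodes <- function(graph) length(graph$node_labels)

#' Keep only edge weights at or above a threshold
#'
#' Functional connectivity weights are Pearson correlations, which are not a
#' similarity measure when negative. Before kernel-based testing, negative
#' (more generally, sub-threshold) correlations are zeroed out. The default
#' threshold 0 keeps only positive correlations; thresholds up to 0.5 are
#' supported for sensitivity analyses.
#'
#' Applying the same threshold twice is a no-op.
#'
#' @param graph A functional [brain_graph()].
#' @param threshold Weights strictly below this value are set to 0. Must lie
#'   in \[0, 0.5\].
#' @return A new functional `brain_graph` with sub-threshold weights zeroed.
#' @export
threshold_positive <- function(graph, threshold = 0) {
  stopifnot(is_brain_graph(graph))
  if (graph$modality != "functional") {
    abort(sprintf(
      "threshold_positive() applies to functional graphs; subject '%s' is %s. %s",
      graph$subject_id, graph$modality,
      "This usually indicates a mis-wired pipeline."))
  }
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 0.5) {
    abort("`threshold` must be a single value in [0, 0.5].")
  }
  w <- graph$weights
  w[w < threshold] <- 0
  brain_graph(w, graph$node_labels, graph$modality, graph$subject_id)
}

#' Group-average connectivity graph
#'
#' Structural graphs are averaged element-wise on the raw (streamline count)
#' scale. Functional graphs are Fisher z-transformed (`atanh`), averaged, and
#' back-transformed (`tanh`), the standard way to average correlation
#' matrices. Correlations are clipped to `1 - 1e-7` in absolute value before
#' `atanh`, which diverges at +/-1.
#'
#' @param graphs List of [brain_graph()]s sharing one modality and node order.
#' @param modality Modality of the inputs; defaults to the common modality of
#'   `graphs`.
#' @return A `brain_graph` tagged `subject_id = "group_average"`.
#' @export
group_average <- function(graphs, modality = NULL) {
  if (length(graphs) == 0) abort("`graphs` must contain at least one graph.")
  stopifnot(all(vapply(graphs, is_brain_graph, logical(1))))
  mods <- unique(vapply(graphs, function(g) g$modality, character(1)))
  if (length(mods) > 1) {
    abort(sprintf("mixed modalities in group_average(): %s.",
                  paste(mods, collapse = ", ")))
  }
  if (is.null(modality)) modality <- mods
  if (modality != mods) {
    abort(sprintf("graphs are %s but modality = '%s' was requested.",
                  mods, modality))
  }
  labs <- graphs[[1]]$node_labels
  for (g in graphs) {
    if (!identical(g$node_labels, labs)) {
      abort(sprintf("subject '%s': node ordering differs within group_average().",
                    g$subject_id))
    }
  }
  mats <- lapply(graphs, function(g) g$weights)
  if (modality == "structural") {
    avg <- Reduce(`+`, mats) / length(mats)
  } else {
    clip <- 1 - 1e-7
    zs <- lapply(mats, function(m) atanh(pmin(pmax(m, -clip), clip)))
    avg <- tanh(Reduce(`+`, zs) / length(zs))
  }
  brain_graph(avg, labs, modality, subject_id = "group_average")
}
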