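#' Pooled empirical CDF of a modality's edge weights
#'
#' Collects every nonzero upper-triangle edge weight across all graphs of a
#' dataset (both classes; class labels play no role) into one pooled sample
#' and represents its empirical cumulative distribution function. Evaluating
#' a modality's own weights through this ECDF maps them to (0, 1] with an
#' approximately uniform distribution, which is what makes structural
#' (streamline-count) and functional (correlation) weights comparable on a
#' common scale. Zero entries encode absent edges and are excluded, so edge
#' density differences do not distort the weight distribution.
#'
#' @param dataset A [graph_dataset()].
#' @return An object of class `edge_ecdf`: list with `sorted_weights`
#'   (ascending, with multiplicity) and `modality`.
#' @export
pooled_ecdf <- function(dataset) {
  stopifnot(is_graph_dataset(dataset))
  w <- unlist(lapply(dataset$graphs, function(g) {
    v <- dce_embed(g)
    v[v != 0]
  }), use.names = FALSE)
  if (length(w) == 0) {
    abort("no nonzero edge weights in the dataset; cannot build an ECDF.")
  }
  structure(list(sorted_weights = sort(w), modality = dataset$modality),
            class = "edge_ecdf")
}

#' @export
print.edge_ecdf <- function(x, ...) {
  cat(sprintf("<edge_ecdf> %s, |Omega| = %d, range [%.4g, %.4g]\n",
              x$modality, length(x$sorted_weights),
              x$sorted_weights[1],
              x$sorted_weights[length(x$sorted_weights)]))
  invisible(x)
}

#' Evaluate a pooled edge-weight ECDF
#'
#' `F(x) = #\{w in Omega : w <= x\} / |Omega|`, computed by binary search.
#' Ties count fully (the `<=` convention, no midranks).
#'
#' @param ecdf An [pooled_ecdf()] object.
#' @param x Numeric vector of evaluation points.
#' @return Values in \[0, 1\], nondecreasing in `x`.
#' @export
ecdf_evaluate <- function(ecdf, x) {
  stopifnot(inherits(ecdf, "edge_ecdf"))
  findInterval(x, ecdf$sorted_weights) / length(ecdf$sorted_weights)
}

#' Map a dataset into the common representation space
#'
#' Replaces every nonzero edge weight by its pooled-ECDF value; zero (absent)
#' edges stay exactly zero, so graph sparsity is preserved. Because the ECDF
#' depends only on the ranks of the weights, the transformed dataset is
#' invariant under any strictly increasing rescaling of the raw weights.
#'
#' @param dataset A [graph_dataset()].
#' @param ecdf An `edge_ecdf` built from a dataset of the same modality;
#'   defaults to the pooled ECDF of `dataset` itself.
#' @return A [graph_dataset()] with transformed weights in (0, 1\], tagged
#'   with the original modality.
#' @export
transform_graphs <- function(dataset, ecdf = pooled_ecdf(dataset)) {
  stopifnot(is_graph_dataset(dataset), inherits(ecdf, "edge_ecdf"))
  if (!identical(ecdf$modality, dataset$modality)) {
    abort(sprintf("ECDF was built from %s graphs but the dataset is %s.",
                  ecdf$modality, dataset$modality))
  }
  graphs <- lapply(dataset$graphs, function(g) {
    w <- g$weights
    nz <- w != 0
    w[nz] <- ecdf_evaluate(ecdf, w[nz])
    # common-space weights live in (0, 1]; keep the modality tag but bypass
    # the structural/functional range checks via the functional branch
    out <- g
    out$weights <- w
    out
  })
  out <- dataset
  out$graphs <- graphs
  out
}

#' Common-space MMD statistics for two modalities
#'
#' Builds each modality's pooled ECDF, maps both datasets into the common
#' representation space, and computes the unbiased squared MMD between classes
#' within each transformed dataset. One shared kernel bandwidth — the median
#' pairwise distance over the pooled embedded transformed graphs of both
#' modalities — is used for both statistics so that they live on one scale and
#' can share a null distribution (`per_modality_sigma = TRUE` reverts to
#' separate bandwidths for sensitivity analysis).
#'
#' @param ds Structural [graph_dataset()].
#' @param df Functional [graph_dataset()] (positive-thresholded).
#' @param sigma_method Passed to [median_sigma()].
#' @param per_modality_sigma Use a separate bandwidth per modality.
#' @return List with `mmd2_s`, `mmd2_f`, `sigma` (length 2 when
#'   `per_modality_sigma`), plus the transformed datasets and kernel matrices
#'   (`transformed_s`, `transformed_f`, `kernel_s`, `kernel_f`) for reuse.
#' @export
common_space_mmds <- function(ds, df, sigma_method = c("median", "mean"),
                              per_modality_sigma = FALSE) {
  stopifnot(is_graph_dataset(ds), is_graph_dataset(df))
  if (ds$modality != "structural" || df$modality != "functional") {
    abort("`ds` must be structural and `df` functional.")
  }
  sigma_method <- match.arg(sigma_method)
  ts <- transform_graphs(ds)
  tf <- transform_graphs(df)
  es <- embedding_matrix(ts)
  ef <- embedding_matrix(tf)
  if (per_modality_sigma) {
    sig_s <- median_sigma(es, sigma_method)
    sig_f <- median_sigma(ef, sigma_method)
  } else {
    sig_s <- sig_f <- median_sigma(rbind(es, ef), sigma_method)
  }
  ids <- function(d) vapply(d$graphs, function(g) g$subject_id, character(1))
  ks <- kernel_matrix_from_embeddings(es, sig_s, ids(ts))
  kf <- kernel_matrix_from_embeddings(ef, sig_f, ids(tf))
  list(mmd2_s = mmd2u(ks, ds$class_labels),
       mmd2_f = mmd2u(kf, df$class_labels),
       sigma = if (per_modality_sigma) c(structural = sig_s, functional = sig_f)
               else sig_s,
       transformed_s = ts, transformed_f = tf,
       kernel_s = ks, kernel_f = kf)
}

#' Differential test of modality involvement
#'
#' Tests whether the condition separates the two classes more in structural
#' than in functional connectivity. The statistic is
#' `MMD^2_SF = MMD^2_S - MMD^2_F`, the difference of the two common-space
#' squared MMDs; positive values mean the structural modality is more
#' affected. Its null distribution is approximated by jointly permuting class
#' labels within the structural dataset and, independently, within the
#' functional dataset (the four group sizes are preserved; structural and
#' functional graphs may come from different subjects, so no pairing is
#' assumed), recomputing both statistics on the fixed transformed kernel
#' matrices each time. ECDFs and the shared bandwidth are computed once from
#' the unpermuted data — their construction never looks at class labels, so
#' they are permutation-invariant.
#'
#' The default test is one-sided (structural more affected); `two_sided`
#' doubles the smaller tail.
#'
#' @inheritParams common_space_mmds
#' @param iterations Number of permutations (default 100000).
#' @param seed Optional integer seed.
#' @param two_sided Report a two-sided p-value.
#' @return An object of class `mmd_sf_result`: fields `mmd2_s`, `mmd2_f`,
#'   `mmd2_sf`, `null_sample` (differences), `p_value`, `p_s`, `p_f`
#'   (per-modality p-values against the within-modality permutation nulls of
#'   the shared construction), `iterations`, `seed`, `sigma`, `group_sizes`.
#'   Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
mmd_sf_test <- function(ds, df, iterations = 100000L, seed = NULL,
                        sigma_method = c("median", "mean"),
                        per_modality_sigma = FALSE, two_sided = FALSE) {
  if (!is.numeric(iterations) || length(iterations) != 1 || iterations < 1) {
    abort("`iterations` must be a positive integer.")
  }
  iterations <- as.integer(iterations)
  cs <- common_space_mmds(ds, df, sigma_method, per_modality_sigma)
  ks <- cs$kernel_s$values
  kf <- cs$kernel_f$values
  mask_s <- ds$class_labels == unique(ds$class_labels)[[1]]
  mask_f <- df$class_labels == unique(df$class_labels)[[1]]
  nulls <- with_seed(seed, function() {
    null_s <- numeric(iterations)
    null_f <- numeric(iterations)
    for (i in seq_len(iterations)) {
      null_s[i] <- mmd2u_mask(ks, sample(mask_s))
      null_f[i] <- mmd2u_mask(kf, sample(mask_f))
    }
    list(s = null_s, f = null_f)
  })
  observed <- cs$mmd2_s - cs$mmd2_f
  null_sf <- nulls$s - nulls$f
  p_one <- permutation_pvalue(observed, null_sf)
  p_value <- if (two_sided) {
    p_lo <- permutation_pvalue(-observed, -null_sf)
    min(1, 2 * min(p_one, p_lo))
  } else {
    p_one
  }
  structure(
    list(mmd2_s = cs$mmd2_s, mmd2_f = cs$mmd2_f, mmd2_sf = observed,
         null_sample = null_sf, null_s = nulls$s, null_f = nulls$f,
         p_value = p_value,
         p_s = permutation_pvalue(cs$mmd2_s, nulls$s),
         p_f = permutation_pvalue(cs$mmd2_f, nulls$f),
         iterations = iterations, seed = seed, sigma = cs$sigma,
         two_sided = two_sided,
         group_sizes = c(structural = as.integer(table(ds$class_labels)),
                         functional = as.integer(table(df$class_labels)))),
    class = "mmd_sf_result")
}

#' @export
print.mmd_sf_result <- function(x, ...) {
  cat(sprintf(
    paste0("Common-space differential modality test\n",
           "  MMD^2_S = %.6g (p = %.3g)   MMD^2_F = %.6g (p = %.3g)\n",
           "  MMD^2_SF = %.6g   p = %.3g (%s)   T = %d   sigma = %s\n"),
    x$mmd2_s, x$p_s, x$mmd2_f, x$p_f, x$mmd2_sf, x$p_value,
    if (x$two_sided) "two-sided" else "one-sided", x$iterations,
    paste(sprintf("%.6g", x$sigma), collapse = "/")))
  invisible(x)
}

#' @rdname mmd_sf_test
#' @param x A `mmd_sf_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mmd_sf_result <- function(x, ...) {
  tibble::tibble(
    statistic = c("mmd2_s", "mmd2_f", "mmd2_sf"),
    estimate = c(x$mmd2_s, x$mmd2_f, x$mmd2_sf),
    p_value = c(x$p_s, x$p_f, x$p_value))
}

#' @rdname mmd_sf_test
#' @exportS3Method generics::glance
glance.mmd_sf_result <- function(x, ...) {
  tibble::tibble(mmd2_s = x$mmd2_s, mmd2_f = x$mmd2_f, mmd2_sf = x$mmd2_sf,
                 p_s = x$p_s, p_f = x$p_f, p_value = x$p_value,
                 sigma = x$sigma[[1]], iterations = x$iterations)
}

#' @rdname mmd_sf_test
#' @param object A `mmd_sf_result`.
#' @param bins Histogram bin count.
#' @exportS3Method ggplot2::autoplot
autoplot.mmd_sf_result <- function(object, bins = 60, ...) {
  df <- tibble::tibble(null = object$null_sample)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$mmd2_sf,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = expression(MMD[SF]^2), y = "permutations",
      title = sprintf("MMD^2_SF = %.3g, p = %.3g",
                      object$mmd2_sf, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Shared reference null over the pooled common-space graphs
#'
#' For visual comparison of `MMD^2_S` and `MMD^2_F` against one scale, draws a
#' null distribution of squared-MMD values from the pooled transformed graphs
#' of both modalities: at each iteration a random two-group split of the
#' pooled graphs is drawn, with group sizes alternating between the structural
#' design and the functional design. This reference distribution is for
#' plotting only; the differential test's p-value comes from [mmd_sf_test()].
#'
#' @inheritParams mmd_sf_test
#' @param sigma Shared bandwidth; `NULL` applies the pooled median heuristic
#'   (an explicit value is needed when all transformed graphs coincide).
#' @return Numeric vector of `iterations` null statistics, with attribute
#'   `sigma`.
#' @export
shared_null_reference <- function(ds, df, iterations = 100000L, seed = NULL,
                                  sigma_method = c("median", "mean"),
                                  sigma = NULL) {
  if (!is.numeric(iterations) || length(iterations) != 1 || iterations < 1) {
    abort("`iterations` must be a positive integer.")
  }
  iterations <- as.integer(iterations)
  ts <- transform_graphs(ds)
  tf <- transform_graphs(df)
  e <- rbind(embedding_matrix(ts), embedding_matrix(tf))
  if (is.null(sigma)) sigma <- median_sigma(e, match.arg(sigma_method))
  ids <- unlist(lapply(c(ts$graphs, tf$graphs),
                       function(g) g$subject_id), use.names = FALSE)
  k <- kernel_matrix_from_embeddings(e, sigma, make.unique(ids))$values
  n_total <- nrow(e)
  sizes_s <- as.integer(table(ds$class_labels))
  sizes_f <- as.integer(table(df$class_labels))
  out <- with_seed(seed, function() {
    vapply(seq_len(iterations), function(i) {
      sizes <- if (i %% 2 == 1) sizes_s else sizes_f
      idx <- sample.int(n_total, sum(sizes))
      m <- logical(length(idx))
      m[seq_len(sizes[1])] <- TRUE
      mmd2u_mask(k[idx, idx, drop = FALSE], m)
    }, numeric(1))
  })
  attr(out, "sigma") <- sigma
  out
}

#' Compare the two common-space statistics against the shared reference null
#'
#' @param shared_null Output of [shared_null_reference()].
#' @param mmd2_s,mmd2_f Common-space statistics from [common_space_mmds()] or
#'   [mmd_sf_test()].
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_shared_null <- function(shared_null, mmd2_s, mmd2_f, bins = 60) {
  df <- tibble::tibble(null = as.numeric(shared_null))
  marks <- tibble::tibble(
    statistic = factor(c("MMD^2_S", "MMD^2_F"), c("MMD^2_S", "MMD^2_F")),
    value = c(mmd2_s, mmd2_f))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$value, colour = .data$statistic),
      linewidth = 1) +
    ggplot2::labs(x = expression(MMD[u]^2), y = "draws", colour = NULL) +
    ggplot2::theme_minimal()
}
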