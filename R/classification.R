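#' Exact binomial test for above-chance classification
#'
#' For a binary classifier evaluated on `n` held-out samples, the chance-level
#' null says each prediction is correct with probability 1/2. Given `r`
#' misclassified samples, the p-value is the exact cumulative binomial sum
#' \deqn{\Pr(i \le r \mid H_0) = \sum_{i=0}^{r} \binom{n}{i} 2^{-n}.}
#' Binomial coefficients are exact in double precision for the sample sizes of
#' interest (`n <= 50`), so the sum is computed directly.
#'
#' @param r Number of misclassified samples, `0 <= r <= n`.
#' @param n Number of predictions, `n >= 1`.
#' @return p-value in (0, 1\].
#' @examples
#' binomial_pvalue(0, 16)   # 2^-16
#' binomial_pvalue(1, 20)   # 21 / 2^20
#' @export
binomial_pvalue <- function(r, n) {
  if (!is.numeric(r) || !is.numeric(n) || length(r) != 1 || length(n) != 1 ||
      r != round(r) || n != round(n) || n < 1 || r < 0 || r > n) {
    abort("need integers 0 <= r <= n with n >= 1.")
  }
  sum(choose(n, 0:r)) / 2^n
}

#' Leave-one-subject-out cross-validated kernel classification
#'
#' The comparator pipeline for the kernel two-sample test: a maximum-margin
#' classifier (SVM with the precomputed direct embedding kernel) is trained on
#' all subjects but one and predicts the held-out subject, for every subject
#' in turn. The kernel bandwidth is recomputed in each fold from the training
#' embeddings only, so no information from the held-out subject leaks into the
#' model. Accuracy is tested against chance with [binomial_pvalue()].
#'
#' @param dataset A two-class [graph_dataset()] with at least two graphs per
#'   class.
#' @param sigma Fixed bandwidth, or `"auto"` for the per-fold median
#'   heuristic.
#' @param regularization SVM cost parameter `C`.
#' @param sigma_method Passed to [median_sigma()].
#' @return An object of class `cv_result`: fields `predictions` (tibble with
#'   `subject_id`, `truth`, `prediction`, `correct`), `accuracy`,
#'   `misclassified`, `p_value`, `folds`. Has [tidy()] and [glance()] methods.
#' @export
loso_cv <- function(dataset, sigma = "auto", regularization = 1,
                    sigma_method = c("median", "mean")) {
  stopifnot(is_graph_dataset(dataset))
  sigma_method <- match.arg(sigma_method)
  e <- embedding_matrix(dataset)
  y <- factor(dataset$class_labels)
  n <- nrow(e)
  if (min(table(y)) < 2) abort("need at least two graphs per class.")
  d2 <- as.matrix(dist(e))^2
  preds <- character(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    if (length(unique(y[train])) < 2) {
      abort("a training fold contains a single class.")
    }
    sig <- if (identical(sigma, "auto")) {
      median_sigma(e[train, , drop = FALSE], method = sigma_method)
    } else {
      sigma
    }
    k <- exp(-d2 / (2 * sig^2))
    fit <- kernlab::ksvm(kernlab::as.kernelMatrix(k[train, train]),
                         y[train], kernel = "matrix", C = regularization)
    sv <- kernlab::SVindex(fit)
    ktest <- kernlab::as.kernelMatrix(
      k[i, train, drop = FALSE][, sv, drop = FALSE])
    preds[i] <- as.character(kernlab::predict(fit, ktest))
  }
  correct <- preds == as.character(y)
  r <- sum(!correct)
  structure(
    list(predictions = tibble::tibble(
           subject_id = vapply(dataset$graphs, function(g) g$subject_id,
                               character(1)),
           truth = as.character(y), prediction = preds, correct = correct),
         accuracy = 1 - r / n,
         misclassified = r,
         p_value = binomial_pvalue(r, n),
         folds = n,
         modality = dataset$modality),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    paste0("Leave-one-subject-out kernel SVM (%s connectivity)\n",
           "  folds = %d   accuracy = %.3f   misclassified = %d   ",
           "binomial p = %.3g\n"),
    x$modality, x$folds, x$accuracy, x$misclassified, x$p_value))
  invisible(x)
}

#' @rdname loso_cv
#' @param x A `cv_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) x$predictions

#' @rdname loso_cv
#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) {
  tibble::tibble(modality = x$modality, accuracy = x$accuracy,
                 misclassified = x$misclassified, p_value = x$p_value,
                 folds = x$folds)
}
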