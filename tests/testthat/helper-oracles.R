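# Independent brute-force oracles and small fixture builders.

# Literal four-nested-loop evaluation of the unbiased squared-MMD estimator.
mmd2u_bruteforce <- function(K, labels) {
  if (inherits(K, "kernel_matrix")) K <- K$values
  lev <- unique(labels)
  a <- which(labels == lev[1])
  b <- which(labels == lev[2])
  m <- length(a); n <- length(b)
  s_aa <- 0
  for (i in a) for (j in a) if (i != j) s_aa <- s_aa + K[i, j]
  s_bb <- 0
  for (i in b) for (j in b) if (i != j) s_bb <- s_bb + K[i, j]
  s_ab <- 0
  for (i in a) for (j in b) s_ab <- s_ab + K[i, j]
  s_aa / (m * (m - 1)) + s_bb / (n * (n - 1)) - 2 * s_ab / (m * n)
}

# Median pairwise Euclidean distance by explicit enumeration.
median_sigma_bruteforce <- function(vectors) {
  n <- nrow(vectors)
  d <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- c(d, sqrt(sum((vectors[i, ] - vectors[j, ])^2)))
  }
  median(d)
}

# Random symmetric zero-diagonal nonnegative matrix.
random_adjacency <- function(l, density = 1, max_w = 10) {
  a <- matrix(0, l, l)
  ut <- upper.tri(a)
  w <- round(runif(sum(ut), 0, max_w), 6)
  w[runif(sum(ut)) > density] <- 0
  a[ut] <- w
  a + t(a)
}

random_graph <- function(l, modality = "structural", id = "g",
                         labels = sprintf("n%02d", seq_len(l))) {
  brain_graph(random_adjacency(l), labels, modality, id)
}

random_dataset <- function(n_per_class = 3, l = 6, modality = "structural") {
  graphs <- lapply(seq_len(2 * n_per_class), function(i)
    random_graph(l, modality, sprintf("s%02d", i)))
  graph_dataset(graphs, rep(c("A", "B"), each = n_per_class))
}

# Random positive semidefinite kernel-like matrix with unit diagonal.
random_kernel <- function(n, d = 3) {
  x <- matrix(rnorm(n * d), n)
  k <- exp(-as.matrix(dist(x))^2 / 2)
  diag(k) <- 1
  k
}

# Small fully specified deterministic graph.
tiny_graph <- function(modality = "structural") {
  brain_graph(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3),
              c("a", "b", "c"), modality, "tiny")
}
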