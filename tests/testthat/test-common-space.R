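make_dataset_from_mats <- function(mats, modality, classes = NULL) {
  l <- nrow(mats[[1]])
  labs <- sprintf("n%02d", seq_len(l))
  graphs <- purrr::imap(mats, function(m, i)
    brain_graph(m, labs, modality, sprintf("s%02d", i)))
  graph_dataset(graphs, classes %||% rep(c("A", "B"),
                                         length.out = length(mats)))
}

test_that("pooled_ecdf counts with the <= convention including ties", {
  # Omega = {10, 20, 30, 40} spread over two graphs
  m1 <- matrix(0, 3, 3); m1[1, 2] <- m1[2, 1] <- 10; m1[1, 3] <- m1[3, 1] <- 20
  m2 <- matrix(0, 3, 3); m2[1, 2] <- m2[2, 1] <- 30; m2[1, 3] <- m2[3, 1] <- 40
  ds <- make_dataset_from_mats(list(m1, m2), "structural")
  e <- pooled_ecdf(ds)
  expect_equal(ecdf_evaluate(e, c(5, 10, 25, 40)), c(0, 0.25, 0.5, 1))

  # ties: {1, 2, 2, 3} -> F(2) = 0.75
  t1 <- matrix(0, 3, 3); t1[1, 2] <- t1[2, 1] <- 1; t1[1, 3] <- t1[3, 1] <- 2
  t2 <- matrix(0, 3, 3); t2[1, 2] <- t2[2, 1] <- 2; t2[1, 3] <- t2[3, 1] <- 3
  e2 <- pooled_ecdf(make_dataset_from_mats(list(t1, t2), "structural"))
  expect_equal(ecdf_evaluate(e2, 2), 0.75)

  # fully dense paper-sized pool: |Omega| = 16 * 1225
  set.seed(51)
  dense <- lapply(1:16, function(i) random_adjacency(50, density = 1) + 1e-3)
  dense <- lapply(dense, function(m) { diag(m) <- 0; m })
  e3 <- pooled_ecdf(make_dataset_from_mats(dense, "structural"))
  expect_length(e3$sorted_weights, 16 * 1225)

  empty <- matrix(0, 3, 3)
  expect_error(pooled_ecdf(make_dataset_from_mats(list(empty, empty),
                                                  "structural")),
               "nonzero")
})

test_that("transform_graphs is the rank map: zeros fixed, ranks to (0, 1]", {
  set.seed(52)
  mats <- lapply(1:4, function(i) random_adjacency(8, density = 0.7))
  ds <- make_dataset_from_mats(mats, "structural")
  tr <- transform_graphs(ds)

  pooled_raw <- unlist(lapply(ds$graphs, function(g) {
    v <- dce_embed(g); v[v != 0] }))
  pooled_tr <- unlist(lapply(tr$graphs, function(g) {
    v <- dce_embed(g); v[v != 0] }))
  n <- length(pooled_raw)
  # all-distinct weights: transformed pool is exactly {1/N, ..., N/N}
  stopifnot(!anyDuplicated(pooled_raw))
  expect_identical(sort(pooled_tr), (1:n) / n)

  # zeros preserved exactly, monotone on nonzeros
  for (i in seq_along(mats)) {
    expect_identical(tr$graphs[[i]]$weights == 0, ds$graphs[[i]]$weights == 0)
  }
  o <- order(pooled_raw)
  expect_true(all(diff(pooled_tr[o]) >= 0))

  # graph holding the pooled maximum maps it to exactly 1
  expect_equal(max(pooled_tr), 1)

  expect_error(
    transform_graphs(ds, pooled_ecdf(make_dataset_from_mats(
      lapply(mats, function(m) pmin(m / max(m), 1)), "functional"))),
    "built from functional")
})

test_that("the common-space map is invariant under monotone rescaling", {
  set.seed(53)
  mats <- lapply(1:6, function(i) random_adjacency(10, density = 0.8))
  ds <- make_dataset_from_mats(mats, "structural")
  cubed <- make_dataset_from_mats(lapply(mats, function(m) m^3), "structural")
  tr1 <- transform_graphs(ds)
  tr2 <- transform_graphs(cubed)
  for (i in 1:6) {
    expect_identical(tr1$graphs[[i]]$weights, tr2$graphs[[i]]$weights)
  }
})

test_that("common_space_mmds shares one bandwidth and detects one-sided effects", {
  sim <- simulate_dataset(simulation_params(
    l = 20, n_per_class_structural = 6, n_per_class_functional = 6,
    delta_s = 0.9, delta_f = 0, seed = 54))
  cs <- common_space_mmds(sim$structural, sim$functional)
  expect_length(cs$sigma, 1)
  expect_equal(cs$kernel_s$sigma, cs$kernel_f$sigma)
  expect_gt(cs$mmd2_s, cs$mmd2_f)

  csp <- common_space_mmds(sim$structural, sim$functional,
                           per_modality_sigma = TRUE)
  expect_length(csp$sigma, 2)

  # statistics invariant to a strictly monotone rescaling of raw weights
  cubed_graphs <- lapply(sim$structural$graphs, function(g) {
    g$weights <- g$weights^3
    g
  })
  ds3 <- graph_dataset(cubed_graphs, sim$structural$class_labels)
  cs3 <- common_space_mmds(ds3, sim$functional)
  expect_identical(cs3$mmd2_s, cs$mmd2_s)
  expect_identical(cs3$mmd2_f, cs$mmd2_f)
})

test_that("mmd_sf_test permutes within modalities and honours its conventions", {
  sim <- simulate_dataset(simulation_params(
    l = 14, n_per_class_structural = 4, n_per_class_functional = 5,
    delta_s = 0.7, delta_f = 0.1, seed = 55))
  res <- mmd_sf_test(sim$structural, sim$functional, iterations = 400,
                     seed = 9)
  expect_s3_class(res, "mmd_sf_result")
  expect_identical(res$mmd2_sf, res$mmd2_s - res$mmd2_f)
  expect_length(res$null_sample, 400)
  expect_equal(res$p_value,
               max(sum(res$null_sample >= res$mmd2_sf), 1) / 400)
  expect_gt(res$p_s, 0); expect_lte(res$p_s, 1)

  # reproducible under seed
  res2 <- mmd_sf_test(sim$structural, sim$functional, iterations = 400,
                      seed = 9)
  expect_identical(res2$null_sample, res$null_sample)
  expect_identical(res2$p_value, res$p_value)

  # two-sided doubles the smaller tail (capped at 1)
  res_t <- mmd_sf_test(sim$structural, sim$functional, iterations = 400,
                       seed = 9, two_sided = TRUE)
  expect_identical(res_t$mmd2_sf, res$mmd2_sf)
  expect_lte(res_t$p_value, 1)

  td <- tidy(res)
  expect_identical(td$estimate[td$statistic == "mmd2_sf"], res$mmd2_sf)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("swapping the modality roles negates the observed difference", {
  sim <- simulate_dataset(simulation_params(
    l = 14, n_per_class_structural = 4, n_per_class_functional = 5,
    delta_s = 0.7, delta_f = 0.1, seed = 56))
  cs <- common_space_mmds(sim$structural, sim$functional)
  expect_identical(-(cs$mmd2_f - cs$mmd2_s), cs$mmd2_s - cs$mmd2_f)
  # the same invariance through the test object
  res <- mmd_sf_test(sim$structural, sim$functional, 100, seed = 2)
  expect_identical(res$mmd2_sf, -(res$mmd2_f - res$mmd2_s))
})

test_that("shared_null_reference is deterministic and degenerate on identical graphs", {
  sim <- simulate_dataset(simulation_params(
    l = 12, n_per_class_structural = 3, n_per_class_functional = 4,
    seed = 57))
  n1 <- shared_null_reference(sim$structural, sim$functional, 200, seed = 8)
  n2 <- shared_null_reference(sim$structural, sim$functional, 200, seed = 8)
  expect_identical(n1, n2)
  expect_length(n1, 200)
  expect_s3_class(plot_shared_null(n1, 0.1, 0.05), "ggplot")

  set.seed(58)
  labs <- sprintf("n%02d", 1:4)
  m <- random_adjacency(4) + 0.1; diag(m) <- 0
  gs <- graph_dataset(lapply(1:6, function(i)
    brain_graph(m, labs, "structural", paste0("s", i))),
    rep(c("A", "B"), 3))
  mf <- pmin(m / max(m), 0.9); diag(mf) <- 0
  gf <- graph_dataset(lapply(1:6, function(i)
    brain_graph(mf, labs, "functional", paste0("f", i))),
    rep(c("A", "B"), 3))
  # all graphs identical within each modality and, after the rank transform,
  # identical across modalities: every null value is exactly zero
  nz <- shared_null_reference(gs, gf, 50, seed = 3, sigma = 1)
  expect_true(all(nz == 0))
})
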