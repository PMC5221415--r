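test_that("simulation parameters are validated", {
  expect_error(simulation_params(l = 7), "even")
  expect_error(simulation_params(l = 2), "even")
  expect_error(simulation_params(delta_s = 1.2), "0, 1")
  expect_error(simulation_params(n_per_class_structural = 1), "two subjects")
  expect_error(simulation_params(l = 50, functional_timepoints = 40),
               "exceed")
})

test_that("base connectomes have the advertised structure and are reproducible", {
  p <- simulation_params(l = 20, seed = 71)
  b1 <- make_base_connectomes(p)
  b2 <- make_base_connectomes(p)
  expect_identical(b1, b2)

  s <- b1$structural_base
  expect_identical(s, t(s))
  expect_equal(unname(diag(s)), rep(0, 20))
  expect_true(all(s >= 0))
  # homotopic callosal edges always present
  expect_true(all(s[cbind(1:10, 11:20)] > 0))

  cv <- b1$functional_cov
  expect_identical(cv, t(cv))
  expect_equal(unname(diag(cv)), rep(1, 20))
  expect_gt(min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("simulate_dataset produces valid paper-shaped datasets", {
  p <- simulation_params(l = 50, seed = 72)
  sim <- simulate_dataset(p)
  expect_length(sim$structural, 16)
  expect_length(sim$functional, 20)
  expect_identical(length(sim$structural$shared_node_labels), 50L)
  expect_identical(nrow(validate_fcvs(sim$structural)), 0L)
  expect_identical(nrow(validate_fcvs(sim$functional)), 0L)
  # structural counts are integers; thresholded correlations live in [0, 1]
  ws <- sim$structural$graphs[[1]]$weights
  expect_true(all(ws == round(ws)))
  wf <- sim$functional$graphs[[1]]$weights
  expect_true(all(wf >= 0 & wf <= 1))

  # raw (unthresholded) functional graphs are correlations in [-1, 1]
  raw <- simulate_dataset(p, functional_threshold = NULL)
  wr <- do.call(rbind, lapply(raw$functional$graphs, function(g) g$weights))
  expect_true(all(wr >= -1 & wr <= 1))
  expect_true(any(wr < 0))

  # same seed, same study; different seed, different study
  sim2 <- simulate_dataset(p)
  expect_identical(sim2$structural$graphs[[3]]$weights,
                   sim$structural$graphs[[3]]$weights)
  sim3 <- simulate_dataset(simulation_params(l = 50, seed = 73))
  expect_false(identical(sim3$structural$graphs[[3]]$weights,
                         sim$structural$graphs[[3]]$weights))
})

test_that("delta_s = 1 severs class-B inter-hemispheric structural edges", {
  p <- simulation_params(l = 12, n_per_class_structural = 3,
                         n_per_class_functional = 2, delta_s = 1, seed = 74)
  sim <- simulate_dataset(p)
  inter <- outer(1:12 <= 6, 1:12 <= 6, xor)
  for (i in which(sim$structural$class_labels == "B")) {
    expect_true(all(sim$structural$graphs[[i]]$weights[inter] == 0))
  }
  # class A keeps its callosal edges
  a1 <- sim$structural$graphs[[1]]$weights
  expect_gt(sum(a1[inter]), 0)
})

test_that("downstream p-values are fully reproducible from one seed", {
  p <- simulation_params(l = 12, n_per_class_structural = 3,
                         n_per_class_functional = 3, delta_s = 0.5, seed = 75)
  run <- function() {
    sim <- simulate_dataset(p)
    ktst_test(sim$structural, 200, seed = 11)$p_value
  }
  expect_identical(run(), run())
})

test_that("structural test power is monotone in the effect size", {
  rates <- vapply(c(0, 0.45, 0.9), function(d) {
    p <- simulation_params(l = 16, n_per_class_structural = 5,
                           n_per_class_functional = 2, delta_s = d,
                           seed = 760 + round(100 * d))
    seeds <- 1000 + seq_len(40)
    rej <- vapply(seeds, function(s) {
      p$seed <- s
      sim <- simulate_dataset(p)
      ktst_test(sim$structural, 200, seed = s)$p_value <= 0.05
    }, logical(1))
    mean(rej)
  }, numeric(1))
  # nondecreasing up to Monte-Carlo slack
  expect_true(all(diff(rates) >= -0.05))
  expect_gt(rates[3], rates[1])
})

test_that("replicate_study reports one row per replicate plus a summary", {
  p <- simulation_params(l = 10, n_per_class_structural = 3,
                         n_per_class_functional = 3, delta_s = 0.8,
                         delta_f = 0.1, seed = 77)
  rep1 <- replicate_study(p, replicates = 1, iterations = 100)
  expect_identical(nrow(tidy(rep1)), 1L)
  expect_identical(nrow(glance(rep1)), 1L)

  rep3 <- replicate_study(p, replicates = 3, iterations = 100)
  expect_identical(nrow(tidy(rep3)), 3L)
  expect_true(all(c("reject_sf", "sign_recovery") %in% names(glance(rep3))))
  # deterministic under the params seed
  rep3b <- replicate_study(p, replicates = 3, iterations = 100)
  expect_identical(tidy(rep3b), tidy(rep3))
})
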