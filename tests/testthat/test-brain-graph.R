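test_that("brain_graph enforces the adjacency invariants", {
  g <- tiny_graph()
  expect_identical(g$node_labels, c("a", "b", "c"))
  expect_equal(g$weights["a", "b"], 1)
  expect_equal(unname(diag(g$weights)), rep(0, 3))

  # diagonal forced to zero (correlation matrices arrive with ones)
  m <- diag(3) * 1.0
  m[1, 2] <- m[2, 1] <- 0.5
  g2 <- brain_graph(m, c("a", "b", "c"), "functional")
  expect_equal(unname(diag(g2$weights)), rep(0, 3))

  # asymmetry beyond tolerance is rejected, sub-tolerance symmetrized
  bad <- matrix(c(0, 3, 4, 0), 2)
  expect_error(brain_graph(bad, c("a", "b"), "structural"), "asymmetric")
  near <- matrix(c(0, 1, 1 + 1e-12, 0), 2)
  g3 <- brain_graph(near, c("a", "b"), "structural")
  expect_identical(g3$weights, t(g3$weights))

  expect_error(brain_graph(matrix(0, 2, 3), c("a", "b"), "structural"),
               "square")
  expect_error(brain_graph(matrix(c(0, -1, -1, 0), 2), c("a", "b"),
                           "structural"), "nonnegative")
  expect_error(brain_graph(matrix(c(0, 2, 2, 0), 2), c("a", "b"),
                           "functional"), "\\[-1, 1\\]")
  expect_error(brain_graph(matrix(0, 2, 2), c("a", "a"), "structural"),
               "unique")
})

test_that("threshold_positive zeroes sub-threshold correlations and is idempotent", {
  m <- matrix(c(0, -0.3, 0.7, -0.3, 0, -1, 0.7, -1, 0), 3)
  g <- brain_graph(m, c("a", "b", "c"), "functional")
  thr <- threshold_positive(g)
  expect_equal(thr$weights["a", "b"], 0)
  expect_equal(thr$weights["a", "c"], 0.7)
  expect_identical(thr$subject_id, g$subject_id)
  expect_identical(threshold_positive(thr)$weights, thr$weights)

  # all-nonnegative input unchanged; all-negative input zeroed
  pos <- brain_graph(matrix(c(0, .2, .2, 0), 2), c("a", "b"), "functional")
  expect_identical(threshold_positive(pos)$weights, pos$weights)
  neg <- brain_graph(matrix(c(0, -.2, -.2, 0), 2), c("a", "b"), "functional")
  expect_true(all(threshold_positive(neg)$weights == 0))

  expect_error(threshold_positive(tiny_graph("structural")), "functional")
  expect_error(threshold_positive(pos, 0.7), "0, 0.5")
})

test_that("group_average means structural counts and Fisher-averages correlations", {
  s1 <- brain_graph(matrix(c(0, 2, 2, 0), 2), c("a", "b"), "structural", "s1")
  s2 <- brain_graph(matrix(c(0, 4, 4, 0), 2), c("a", "b"), "structural", "s2")
  avg <- group_average(list(s1, s2))
  expect_equal(avg$weights["a", "b"], 3)
  expect_identical(avg$subject_id, "group_average")

  f1 <- brain_graph(matrix(c(0, 0.2, 0.2, 0), 2), c("a", "b"), "functional")
  f2 <- brain_graph(matrix(c(0, 0.6, 0.6, 0), 2), c("a", "b"), "functional")
  favg <- group_average(list(f1, f2))
  expect_equal(favg$weights["a", "b"], tanh((atanh(0.2) + atanh(0.6)) / 2),
               tolerance = 1e-12)
  # closed-form value of the transform chain
  expect_equal(favg$weights["a", "b"], 0.4202041029, tolerance = 1e-8)

  # averaging identical correlation matrices is the identity
  fsame <- group_average(list(f1, f1, f1))
  expect_equal(fsame$weights, f1$weights, tolerance = 1e-10)

  # single graph returns that graph, both modalities
  expect_equal(group_average(list(s1))$weights, s1$weights)
  expect_equal(group_average(list(f2))$weights, f2$weights, tolerance = 1e-10)

  # perfect correlations survive via clipping rather than diverging
  fperf <- brain_graph(matrix(c(0, 1, 1, 0), 2), c("a", "b"), "functional")
  expect_true(is.finite(group_average(list(fperf, f1))$weights["a", "b"]))

  expect_error(group_average(list()), "at least one")
  expect_error(group_average(list(s1, f1)), "mixed")
})

test_that("group_average preserves symmetry and the zero diagonal", {
  set.seed(41)
  graphs <- lapply(1:4, function(i) {
    m <- random_adjacency(6, max_w = 0.9)
    brain_graph(m, sprintf("n%02d", 1:6), "functional", paste0("f", i))
  })
  avg <- group_average(graphs)
  expect_identical(avg$weights, t(avg$weights))
  expect_equal(unname(diag(avg$weights)), rep(0, 6))
})

test_that("validate_fcvs reports each violated invariant without raising", {
  g1 <- random_graph(5, id = "ok1")
  g2 <- random_graph(5, id = "ok2")
  expect_identical(nrow(validate_fcvs(list(g1, g2))), 0L)

  # permuted node ordering is a violation naming the subject
  perm <- g1
  perm$node_labels <- rev(perm$node_labels)
  perm$subject_id <- "permuted"
  rep1 <- validate_fcvs(list(g1, perm), shared_node_labels = g1$node_labels)
  expect_identical(rep1$subject_id, "permuted")
  expect_identical(rep1$violation, "node_labels")

  # asymmetry injected after construction is caught
  asym <- g1
  asym$weights[1, 2] <- 3; asym$weights[2, 1] <- 4
  asym$subject_id <- "asym"
  rep2 <- validate_fcvs(list(asym), shared_node_labels = g1$node_labels)
  expect_true("asymmetry" %in% rep2$violation)

  # wrong size reported with dimensions
  small <- random_graph(4, id = "small")
  rep3 <- validate_fcvs(list(g1, small),
                        shared_node_labels = g1$node_labels)
  expect_true(all(c("size", "node_labels") %in% rep3$violation))
  expect_true(all(rep3$subject_id == "small"))
})
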