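#' Parameters for the synthetic connectome study
#'
#' Describes a two-class, two-modality connectome simulation patterned on a
#' mouse study of callosal agenesis: 50 bilateral brain regions, structural
#' connectivity as streamline-count graphs (8 subjects per class) and
#' functional connectivity as resting-state correlation graphs (10 subjects
#' per class, 360 timepoints). The class effect removes a fraction `delta_s`
#' of inter-hemispheric structural weight and a fraction `delta_f` of
#' inter-hemispheric latent functional covariance, emulating a condition that
#' disrupts the white-matter bridge between the hemispheres while functional
#' coupling may be partly preserved. `delta_s = delta_f = 0` puts both
#' modalities under the null (both classes drawn from one distribution).
#'
#' @param l Even node count >= 4; the first half forms the left hemisphere.
#' @param n_per_class_structural Structural subjects per class (>= 2).
#' @param n_per_class_functional Functional subjects per class (>= 2).
#' @param delta_s,delta_f Class effect sizes in \[0, 1\]: the fraction of
#'   inter-hemispheric structural weight / functional covariance removed in
#'   class B. `delta = 1` severs the hemispheres completely.
#' @param structural_noise Log-scale standard deviation of the multiplicative
#'   log-normal noise applied per edge per subject (0.25 ~ 25% count
#'   variability between subjects).
#' @param functional_timepoints Length of the simulated fMRI time series from
#'   which each subject's sample correlation matrix is computed.
#' @param hemisphere_block Fraction of nodes in the first hemisphere.
#' @param within_density Probability that a within-hemisphere structural edge
#'   exists in the base connectome.
#' @param callosal_density Probability that a non-homotopic inter-hemispheric
#'   structural edge exists (homotopic pairs are always connected).
#' @param isotropic_effect If `TRUE`, the class effect scales *all* edges
#'   instead of inter-hemispheric ones only.
#' @param seed Integer seed; every simulation function derives its randomness
#'   from it.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(l = 50,
                              n_per_class_structural = 8,
                              n_per_class_functional = 10,
                              delta_s = 0,
                              delta_f = 0,
                              structural_noise = 0.25,
                              functional_timepoints = 360,
                              hemisphere_block = 0.5,
                              within_density = 0.7,
                              callosal_density = 0.1,
                              isotropic_effect = FALSE,
                              seed = NULL) {
  p <- list(l = as.integer(l),
            n_per_class_structural = as.integer(n_per_class_structural),
            n_per_class_functional = as.integer(n_per_class_functional),
            delta_s = delta_s, delta_f = delta_f,
            structural_noise = structural_noise,
            functional_timepoints = as.integer(functional_timepoints),
            hemisphere_block = hemisphere_block,
            within_density = within_density,
            callosal_density = callosal_density,
            isotropic_effect = isotropic_effect,
            seed = seed)
  if (p$l < 4 || p$l %% 2 != 0) abort("`l` must be an even integer >= 4.")
  if (p$n_per_class_structural < 2 || p$n_per_class_functional < 2) {
    abort("need at least two subjects per class and modality.")
  }
  if (delta_s < 0 || delta_s > 1 || delta_f < 0 || delta_f > 1) {
    abort("`delta_s` and `delta_f` must lie in [0, 1].")
  }
  if (structural_noise < 0) abort("`structural_noise` must be nonnegative.")
  if (p$functional_timepoints < p$l + 2) {
    abort("`functional_timepoints` must exceed the node count.")
  }
  structure(p, class = "simulation_params")
}

sim_node_labels <- function(l) {
  h <- l %/% 2
  c(sprintf("L%02d", seq_len(h)), sprintf("R%02d", seq_len(l - h)))
}

# Inter-hemispheric indicator matrix and homotopic pair index.
hemisphere_structure <- function(l, hemisphere_block) {
  h <- max(2L, min(l - 2L, as.integer(round(l * hemisphere_block))))
  left <- seq_len(l) <= h
  inter <- outer(left, left, xor)
  homotopic <- cbind(seq_len(min(h, l - h)), h + seq_len(min(h, l - h)))
  list(h = h, inter = inter, homotopic = homotopic)
}

# Base matrices without seeding; callers own the RNG state.
make_base_connectomes_impl <- function(params) {
  l <- params$l
  hs <- hemisphere_structure(l, params$hemisphere_block)
  ut <- upper.tri(matrix(0, l, l))

  # structural base: log-normal streamline-count scales
  base <- matrix(0, l, l)
  within_mask <- ut & !hs$inter & runif(l * l) < params$within_density
  base[within_mask] <- exp(rnorm(sum(within_mask), meanlog_within, 1))
  cal_mask <- ut & hs$inter & runif(l * l) < params$callosal_density
  base[cal_mask] <- exp(rnorm(sum(cal_mask), meanlog_crossing, 1))
  for (r in seq_len(nrow(hs$homotopic))) {
    i <- hs$homotopic[r, 1]; j <- hs$homotopic[r, 2]
    base[i, j] <- exp(rnorm(1, meanlog_homotopic, 0.8))
  }
  base[lower.tri(base)] <- 0
  base <- base + t(base)

  # functional latent covariance: block correlation structure + jitter
  cov <- matrix(0.3, l, l)
  cov[hs$inter] <- 0.15
  for (r in seq_len(nrow(hs$homotopic))) {
    i <- hs$homotopic[r, 1]; j <- hs$homotopic[r, 2]
    cov[i, j] <- cov[j, i] <- 0.5
  }
  jit <- matrix(0, l, l)
  jit[ut] <- runif(sum(ut), -0.05, 0.05)
  cov <- cov + jit + t(jit)
  diag(cov) <- 1
  cov <- ensure_pd(cov)

  list(structural_base = base, functional_cov = cov,
       interhemispheric = hs$inter, node_labels = sim_node_labels(l))
}

# count scales chosen for streamline-like magnitudes (~80k streamlines over
# 50 regions): within-hemisphere median ~e^4=55, homotopic callosal ~e^4.5,
# other crossing ~e^3
meanlog_within <- 4
meanlog_homotopic <- 4.5
meanlog_crossing <- 3

# Diagonal-load to positive definiteness, then rescale to a correlation matrix.
ensure_pd <- function(m, floor_eig = 0.05) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  lo <- min(ev)
  if (lo < floor_eig) {
    m <- m + diag(floor_eig - lo, nrow(m))
    m <- stats::cov2cor(m)
  }
  m
}

#' Base connectomes underlying the simulation
#'
#' @param params A [simulation_params()].
#' @return List with `structural_base` (symmetric nonnegative count-scale
#'   matrix, zero diagonal), `functional_cov` (positive-definite correlation
#'   matrix, unit diagonal), `interhemispheric` (logical indicator matrix),
#'   `node_labels`.
#' @export
make_base_connectomes <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, function() make_base_connectomes_impl(params))
}

# Scale inter-hemispheric covariance by (1 - delta): a convex combination of
# the full covariance and its block-diagonal part, hence still PD.
scale_interhemispheric_cov <- function(cov, inter, delta) {
  out <- cov
  out[inter] <- (1 - delta) * cov[inter]
  ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    warn("scaled covariance lost positive definiteness; re-loading diagonal.")
    out <- ensure_pd(out)
  }
  out
}

structural_subject <- function(base, noise_sd, labels, id) {
  l <- nrow(base)
  noise <- matrix(0, l, l)
  ut <- upper.tri(noise)
  noise[ut] <- exp(rnorm(sum(ut), 0, noise_sd))
  noise <- noise + t(noise)
  w <- round(base * noise)
  brain_graph(w, labels, "structural", id)
}

functional_subject <- function(cov_chol, timepoints, labels, id,
                               threshold = 0) {
  l <- ncol(cov_chol)
  x <- matrix(rnorm(timepoints * l), timepoints, l) %*% cov_chol
  r <- cor(x)
  diag(r) <- 0
  g <- brain_graph(r, labels, "functional", id)
  if (is.null(threshold)) g else threshold_positive(g, threshold)
}

#' Simulate a paired two-class, two-modality connectome dataset
#'
#' Class A subjects are noisy realizations of the base connectomes; class B
#' subjects are realizations of the bases with inter-hemispheric structural
#' weights scaled by `1 - delta_s` and inter-hemispheric functional covariance
#' scaled by `1 - delta_f`. Structural subjects apply independent
#' multiplicative log-normal noise per edge and round to integer counts;
#' functional subjects are the sample Pearson correlation matrices of
#' `functional_timepoints` multivariate normal draws from the (scaled) latent
#' covariance, so sampling noise has genuine correlation-matrix geometry.
#'
#' @param params A [simulation_params()].
#' @param functional_threshold Threshold passed to [threshold_positive()] on
#'   each functional graph (default 0: keep positive correlations); `NULL`
#'   returns raw signed correlations.
#' @return List with elements `structural` and `functional`, each a
#'   [graph_dataset()] with classes `"A"` and `"B"`, plus the generating
#'   `base` matrices.
#' @export
simulate_dataset <- function(params, functional_threshold = 0) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, function() {
    base <- make_base_connectomes_impl(params)
    labels <- base$node_labels
    base_s_b <- base$structural_base
    scale_mask <- if (params$isotropic_effect) {
      matrix(TRUE, params$l, params$l)
    } else {
      base$interhemispheric
    }
    base_s_b[scale_mask] <- (1 - params$delta_s) * base_s_b[scale_mask]
    cov_b <- if (params$isotropic_effect) {
      ensure_pd((1 - params$delta_f) * base$functional_cov +
                  params$delta_f * diag(params$l))
    } else {
      scale_interhemispheric_cov(base$functional_cov, base$interhemispheric,
                                 params$delta_f)
    }
    chol_a <- chol(base$functional_cov)
    chol_b <- chol(cov_b)

    ns <- params$n_per_class_structural
    gs <- c(
      lapply(seq_len(ns), function(i)
        structural_subject(base$structural_base, params$structural_noise,
                           labels, sprintf("sA%02d", i))),
      lapply(seq_len(ns), function(i)
        structural_subject(base_s_b, params$structural_noise,
                           labels, sprintf("sB%02d", i))))
    nf <- params$n_per_class_functional
    gf <- c(
      lapply(seq_len(nf), function(i)
        functional_subject(chol_a, params$functional_timepoints, labels,
                           sprintf("fA%02d", i), functional_threshold)),
      lapply(seq_len(nf), function(i)
        functional_subject(chol_b, params$functional_timepoints, labels,
                           sprintf("fB%02d", i), functional_threshold)))
    list(
      structural = graph_dataset(gs, rep(c("A", "B"), each = ns), labels),
      functional = graph_dataset(gf, rep(c("A", "B"), each = nf), labels),
      base = base)
  })
}

#' Replicate the full testing pipeline over simulated studies
#'
#' Simulates `replicates` independent studies from `params` (fresh base
#' connectomes and subjects each time), runs the kernel two-sample test on
#' each modality and the differential modality test, and summarizes rejection
#' rates and the sign-recovery rate of the differential statistic against the
#' ground truth `sign(delta_s - delta_f)`.
#'
#' @param params A [simulation_params()] (its `seed` seeds the whole study).
#' @param replicates Number of simulated studies.
#' @param alpha Rejection level for the summary.
#' @param iterations Permutations per test (keep modest; 1000 gives p-value
#'   resolution 0.001).
#' @return An object of class `replication_report`: `results` (one tibble row
#'   per replicate), `summary` (one row), `alpha`, `params`. [tidy()] returns
#'   the per-replicate rows, [glance()] the summary.
#' @export
replicate_study <- function(params, replicates = 100, alpha = 0.05,
                            iterations = 1000) {
  stopifnot(inherits(params, "simulation_params"), replicates >= 1)
  seeds <- derive_seeds(params$seed, 3 * replicates)
  rows <- purrr::map(seq_len(replicates), function(r) {
    p_r <- params
    p_r$seed <- seeds[[3 * r - 2]]
    sim <- simulate_dataset(p_r)
    ks <- ktst_test(sim$structural, iterations, seed = seeds[[3 * r - 1]])
    kf <- ktst_test(sim$functional, iterations, seed = seeds[[3 * r - 1]])
    sf <- mmd_sf_test(sim$structural, sim$functional, iterations,
                      seed = seeds[[3 * r]])
    tibble::tibble(
      replicate = r,
      mmd2u_structural = ks$statistic, p_structural = ks$p_value,
      mmd2u_functional = kf$statistic, p_functional = kf$p_value,
      mmd2_s = sf$mmd2_s, mmd2_f = sf$mmd2_f, mmd2_sf = sf$mmd2_sf,
      p_sf = sf$p_value)
  })
  results <- dplyr::bind_rows(rows)
  truth_sign <- sign(params$delta_s - params$delta_f)
  summary <- dplyr::summarise(
    results,
    reject_structural = mean(.data$p_structural <= alpha),
    reject_functional = mean(.data$p_functional <= alpha),
    reject_sf = mean(.data$p_sf <= alpha),
    mean_mmd2u_structural = mean(.data$mmd2u_structural),
    mean_mmd2u_functional = mean(.data$mmd2u_functional),
    mean_mmd2_sf = mean(.data$mmd2_sf),
    sign_recovery = if (truth_sign == 0) NA_real_ else
      mean(sign(.data$mmd2_sf) == truth_sign))
  structure(list(results = results, summary = summary, alpha = alpha,
                 params = params),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf(
    "<replication_report> %d replicates, alpha = %.3g, delta_s = %.2g, delta_f = %.2g\n",
    nrow(x$results), x$alpha, x$params$delta_s, x$params$delta_f))
  print(x$summary)
  invisible(x)
}

#' @rdname replicate_study
#' @param x A `replication_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.replication_report <- function(x, ...) x$results

#' @rdname replicate_study
#' @exportS3Method generics::glance
glance.replication_report <- function(x, ...) x$summary
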