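---
title: "Kernel two-sample testing for connectivity graphs: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel two-sample testing for connectivity graphs: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conntest)
```

## The data model

`conntest` works on simple, undirected, node-labeled, edge-weighted graphs
stored as square symmetric adjacency matrices with a zero diagonal. Absent
edges are exact zeros, so the edge set is implicit in the weights. The one
assumption that everything else rests on is the *fixed-cardinality vertex
sequence* (FCVS) property: every graph in a study has the same node count and
the same ordered node labels, so node `i` means the same brain region in
every subject. Under FCVS the upper triangle of the adjacency matrix, read
row by row, is a lossless vector representation of the graph (the *direct
connection embedding*), and general-purpose graph kernels that solve the
node-correspondence problem from scratch are unnecessary — and would discard
exactly the information that is free here.

Two modalities are distinguished by the nature of the edge weight:

* **structural** — nonnegative streamline-count-like weights from
  tractography; heavy-tailed, integer-valued, genuinely sparse;
* **functional** — Pearson correlations of regional time courses in
  [−1, 1]; dense, bounded, with diagonal 1 in raw files.

On ingestion, matrices are symmetrized as `(A + t(A))/2` only when the
maximum asymmetry is below `1e-9` — larger asymmetries are rejected rather
than silently averaged, since they usually indicate a truncated or corrupted
file. Diagonals are forced to zero (correlation matrices arrive with ones;
self-loops carry no between-region information).

Because correlations are only a similarity when positive, functional graphs
are thresholded before testing: weights below the threshold become 0. The
default threshold is 0 (keep positive correlations); values up to 0.5 are
accepted for sensitivity analyses, since moderate choices in that range tend
to change numbers but not conclusions. Group-level summaries average
structural weights arithmetically on the raw count scale, and functional
weights through the Fisher z-transform (`tanh(mean(atanh(r)))`), with |r|
clipped at `1 − 1e-7` because `atanh` diverges at ±1.

## The single-modality test

The test statistic for comparing two groups of graphs is the unbiased
estimator of the squared maximum mean discrepancy, computed on the kernel
matrix of the pooled sample under the direct embedding kernel
`k_de(G1, G2) = exp(−‖f(G1) − f(G2)‖²/2σ²)`. Since the embedding is a
bijection on FCVS graphs and the Gaussian kernel is characteristic, a zero
population MMD implies equal graph distributions — the test is consistent
against any alternative, not just mean shifts. The unbiased estimator can be
negative; negative values are kept as-is.

The bandwidth σ defaults to the **median** of the pairwise embedded
distances over the whole sample. Both the median and the mean circulate as
"the" distance heuristic; the median is less sensitive to the heavy upper
tail of count-scale distances and is the default, with
`sigma_method = "mean"` available. The heuristic never sees class labels, so
a data-dependent σ does not bias the permutation test: conditionally on the
pooled sample (and hence on σ), the permutation average of the estimator is
exactly zero.

The null distribution is Monte-Carlo: `T` independent uniform shuffles of the
label vector (group sizes preserved) on the fixed kernel matrix. The identity
relabeling is not forced into the sample; instead the p-value

    p = max(#{null ≥ observed}, 1) / T

is floored at `1/T`, the smallest value a Monte-Carlo permutation p-value can
honestly take (with the default `T = 100000`, a statistic exceeding every
null value reports `1e-5`). Comparison is exact `>=` on doubles with no
jittering. The default `T = 100000` gives p-value resolution `1e-5` in about
two seconds at these sample sizes; the package's own simulation studies use
`T = 1000`, which resolves the 0.05 level comfortably.

## The common representation space and the differential statistic

Raw MMD values are not comparable across modalities: streamline counts and
correlations produce kernel matrices on completely different distance scales,
hence statistics with different null distributions. The fix is a rank
transform. For each modality, all nonzero upper-triangle weights of all
subjects (both classes) are pooled into a multiset Ω and each weight is
replaced by the pooled empirical CDF value `F(x) = #{ω ∈ Ω : ω ≤ x}/|Ω|`.
Evaluated on its own sample with all-distinct weights this is exactly the
multiset `{1/N, …, N/N}` — uniform on (0, 1] — so both modalities end up with
identically distributed edge weights, and any strictly increasing rescaling
of the raw weights leaves the transformed dataset bit-identical. With ~1225
node pairs per graph and tens of graphs, |Ω| is in the tens of thousands even
for small cohorts, so the ECDF is a stable estimate.

Three choices here were genuinely open:

* **Zeros are excluded from Ω and stay zero after the transform.** Absent
  edges are topology, not weight; including structural zeros would let edge
  *density* differences dominate the weight distribution, and mapping zeros
  to a positive rank would erase sparsity.
* **One shared bandwidth.** σ is the median pairwise distance over the
  *pooled* embedded transformed graphs of both modalities. Separate
  bandwidths would reintroduce a modality-specific scale through the back
  door and the two statistics would again not share a null distribution;
  `per_modality_sigma = TRUE` exists for sensitivity analysis only.
* **Ties count fully** (the `≤` convention, no midranks). Structural counts
  have many ties; any fixed convention is rank-invariant, and `≤` keeps
  `F(max) = 1`.

The differential statistic is `MMD²_SF = MMD²_S − MMD²_F`, the difference of
the common-space estimators; positive values mean the structural modality
separates the classes more. Its permutation null shuffles class labels
*within* the structural dataset and, independently, *within* the functional
dataset — the four group sizes are preserved, and no subject pairing across
modalities is assumed (cohorts may overlap only partially, and the test does
not use pairing even when it exists). The ECDFs and σ are computed once from
the unpermuted data and reused: their construction ignores class labels, so
they are permutation-invariant, and recomputing them per shuffle would only
add noise and cost. The test is one-sided by default ("structural more
affected"), matching the directional question; `two_sided = TRUE` doubles the
smaller tail. A separate pooled reference null (`shared_null_reference()`,
drawing two-group splits from the union of the transformed graphs with
group sizes alternating between the two designs) is provided purely to plot
MMD²_S and MMD²_F against one scale — the differential p-value never uses it.

## The classifier baseline

The conventional pipeline — a maximum-margin classifier (SVM on the
precomputed direct-embedding kernel, cost `C = 1`) under leave-one-subject-out
cross-validation, with the exact chance-level binomial test
`P(i ≤ r | H0) = Σ_{i=0}^{r} C(n,i) 2^{-n}` on the misclassification count
`r` — is included as a comparator. The kernel bandwidth is recomputed in each
fold from training embeddings only, so the held-out subject never influences
the model.

Two caveats worth knowing. First, cross-validation folds share training data,
so the i.i.d. assumption behind the binomial test is only approximate.
Second, leave-one-out has a *pessimistic* bias under weak or absent signal:
removing the test subject leaves its class in the training minority, and a
margin classifier leans toward the majority class, so null-data accuracies
fall below 0.5 (sometimes near 0) rather than at it. This is a property of
the procedure, not a bug; it is also one reason the kernel two-sample test,
which needs no data splitting, is better suited to cohorts of 8–10 subjects
per group.

## The synthetic study generator

The generator emulates the kind of data the method was designed for: a
two-hemisphere brain of `l = 50` regions, 8+8 structural and 10+10 functional
subjects, and a condition that removes inter-hemispheric connectivity —
the extreme biological case being congenital absence of the corpus callosum,
where structural cross-hemisphere connections largely vanish while functional
homotopy is surprisingly preserved.

* **Structural base connectome:** within-hemisphere edges present with
  probability 0.7 with log-normal count scales (`meanlog 4`, `sdlog 1`);
  every homotopic pair connected (`meanlog 4.5`) plus 10% of other
  inter-hemispheric pairs (`meanlog 3`). These give count magnitudes and
  ~70% density consistent with whole-brain tractography at this parcellation
  (tens of thousands of nonzero edges across a 36-graph study). Subjects are
  the base times independent edge-wise log-normal noise (`sdlog 0.25`,
  ≈25% between-subject count variability), rounded to integers.
* **Functional latent covariance:** correlation 0.3 within hemispheres, 0.5
  for homotopic pairs, 0.15 otherwise, jittered by ±0.05 and
  diagonal-loaded back to a positive-definite correlation matrix. A subject
  is the sample Pearson correlation matrix of 360 multivariate-normal draws
  (the fMRI time-series length), so subject noise has genuine
  correlation-matrix geometry rather than element-wise perturbation.
* **Class effect:** class B scales inter-hemispheric structural weights by
  `1 − delta_s` and inter-hemispheric covariance entries by `1 − delta_f`
  (a convex combination with the block-diagonal part, so positive
  definiteness is preserved analytically). `delta = 1` severs the
  hemispheres; `delta_s = delta_f = 0` is an exact null. An
  `isotropic_effect` mode scales all edges instead, for effects not aligned
  with the callosal biology.

What the generator does **not** emulate: between-subject variability in the
latent functional covariance itself (all subjects of a class share one
latent structure; real cohorts vary), spatially correlated tractography
errors, distance-dependent connection probability, hemispheric asymmetries,
and indirect (multi-synaptic) functional coupling that survives structural
disconnection. Passing calibration and power checks on these simulations
therefore demonstrates the statistical machinery is correct and well-sized
for data of this shape — not that any particular biological effect size will
be detected in real data.

## Numerical and testing choices

* Symmetry tolerance `1e-9` on read; asymmetries above it are errors.
* Fisher clip `1 − 1e-7`; ECDF evaluation by binary search on the sorted
  pooled weights; kernel matrices built from squared distances accumulated in
  double precision, symmetrized, unit diagonal imposed.
* Degenerate inputs fail loudly: an all-identical sample has median distance
  0 and demands an explicit σ; classes with fewer than two members are
  rejected (the unbiased estimator is undefined); empty edge sets cannot
  build an ECDF.
* Every stochastic routine takes an integer seed and restores the caller's
  RNG state; one seed reproduces a full study end to end, including file
  round-trips through the command-line interface.
* The package's simulation studies use 2000 null replicates for the
  unbiasedness check, 500 for size/uniformity (rejection rate asserted in
  [0.03, 0.07] at α = 0.05; Kolmogorov–Smirnov uniformity at the 1% level),
  and 200 for power and sign recovery at effect sizes 0.6 vs 0.1 — sizes at
  which Monte-Carlo error is comfortably inside each asserted band while the
  whole suite runs in minutes.

## Known limitations

The test says *whether* and *how much more* one modality is affected, never
*where*: edge- or region-level localization is out of scope. Subject pairing
across modalities, when present, is ignored by construction — a paired
variant would need a different statistic. Monte-Carlo p-values are bounded
below by `1/T`. And the common space compares weight *distributions* through
ranks; pathologies that reorganize topology while preserving the pooled
weight distribution enter the statistic only through which edges carry which
ranks, which is subtler to interpret.
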