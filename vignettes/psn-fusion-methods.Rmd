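---
title: "Patient similarity network fusion: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient similarity network fusion: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnfuse)
```

This vignette is the package's own account of its methods: the models and
the assumptions behind them, the tunable parameters with their defaults and
rationale, the synthetic study conditions, and the numerical conventions a
maintainer needs to know. It states no empirical claim that the test suite
or `scripts/acceptance.R` does not itself compute.

## The modelling idea

Multi-omics integration faces two obstacles at once: each omics layer is
high-dimensional (features far outnumber patients) and the layers are
heterogeneous (expression intensities, methylation fractions, counts).
`psnfuse` converts every layer into the same kind of object — a complete
weighted graph on the patients — and integrates there. Whatever the omics
type, a patient similarity network (PSN) is a symmetric nonnegative
affinity matrix with zero diagonal, so networks from different layers are
directly comparable, and per-patient *network* features (centralities and
module memberships) have dimension in the tens regardless of how many
thousand features the assay measured.

The prediction target throughout is a binary clinical endpoint with class 1
the event of interest (e.g. death from disease), so F1 and ROC-AUC are
reported alongside accuracy, and class 1 is the F1-positive class.

## From omics matrix to PSN

**Prefilter.** Each feature is screened by a two-sample Mann–Whitney
rank-sum test of class-0 versus class-1 values (normal approximation with
tie correction), all p-values are Benjamini–Hochberg adjusted, and features
with adjusted p below `alpha` (default `0.001`) are kept. A rank test makes
no distributional assumption about the omics values; BH controls the false
discovery rate among the many tested features. The filter is fit on
training patients only wherever a held-out set exists
(`run_pipeline()` does this for its evaluation split).

**Similarity.** The affinity between patients $u$ and $v$ is the Pearson
correlation of their feature profiles, rescaled by the signed
soft-threshold transform
$$a_{uv} = \left(\frac{1 + r_{uv}}{2}\right)^{\beta}.$$
The signed form is used rather than $|r|^\beta$ so that strong
anti-correlation ($r = -1 \Rightarrow a = 0$) is distinguished from
no correlation ($r = 0 \Rightarrow a = 2^{-\beta}$); the transform also
guarantees nonnegative edge weights, which every downstream step assumes.
An important consequence of using correlation: any constant offset of a
patient's whole profile is invisible, because Pearson centres each profile.
Class signal must therefore live in the *pattern* across features, not in a
uniform shift (see the generator section).

**Soft-threshold selection.** $\beta$ is the smallest integer in
`beta_grid` (default `1:20`) whose affinity reaches a scale-free topology
fit of `target_r2` (default 0.9). The fit index bins node connectivities
$k_u = \sum_v a_{uv}$ into `n_bins = 10` equal-width bins and regresses
$\log_{10}$ bin frequency on $\log_{10}$ mean bin connectivity plus a
linear truncation term; the index is the regression $R^2$ when the log-term
slope is negative, and 0 otherwise or when fewer than three bins are
occupied (a regular graph has no tail to fit). If no power qualifies, the
grid argmax is returned with a warning rather than an error: downstream
steps prefer a slightly sub-target network over none. The bin count and the
signed variant are package choices; neither is forced by the construction,
and `n_bins` trades bias (few bins) against variance (many sparse bins) at
the cohort sizes of interest (tens to a few hundred patients).

The complete weighted graph is kept — no hard sparsification — because the
current-flow centralities and the diffusion-based fusion need a connected
graph with meaningful conductances.

## Network features

**Centralities (13 columns, fixed order).** weighted degree; closeness;
current-flow closeness; current-flow betweenness; eigenvector; Katz; HITS
authority; HITS hub; PageRank; load; local clustering coefficient;
iterative weighted degree; iterative local clustering coefficient.
Conventions:

* shortest-path measures (closeness, load) use edge length $1/w$;
* current-flow measures treat weights as conductances and come from the
  Laplacian pseudoinverse (the betweenness inner loop is in C++ via Rcpp;
  an R reference implementation is kept as the test oracle);
* spectral measures (eigenvector, Katz, HITS) act on the weight matrix;
  Katz uses attenuation $\alpha = 0.9/\lambda_{\max}$, which guarantees
  convergence of the resolvent; on an undirected graph HITS authority and
  hub coincide with the principal eigenvector direction, and both columns
  are kept so the feature block has the same width on any input;
* the load column is computed as normalized weighted shortest-path
  betweenness; load and betweenness differ only in how even splits at ties
  are routed, and on the small oracle graphs used in the tests they
  coincide;
* local clustering uses the Onnela geometric-mean weighted form
  $c_u = \frac{1}{k_u (k_u - 1)} \sum_{v,w} (\hat w_{uv} \hat w_{vw}
  \hat w_{wu})^{1/3}$ with $\hat w = w / \max w$, a standard weighted
  generalization;
* the *iterative* variants use a minimum-peeling scheme that generalizes
  k-core ranking: repeatedly compute the base measure on the remaining
  subgraph, record the value for the node(s) attaining the minimum, remove
  them, and repeat. A node's score is its value at removal, so nodes that
  survive deep into the peeling are scored on dense residual cores. No
  standard definition of an "iterative" centrality exists for weighted
  graphs; the peeling scheme was chosen because it is deterministic,
  parameter-free, and reduces to the classical degeneracy ordering on
  unweighted degree.

**Modules.** Two clusterings are run: normalized spectral clustering
(symmetric-normalized Laplacian, row-normalized eigenvector embedding,
k-means with 10 restarts under a fixed seed) and a Gaussian-weight
stochastic block model fit by greedy single-node moves from the spectral
initialization. The SBM objective is the block log-likelihood of edge
weights around block-pair means (equivalently, minus the within-pair sum
of squares); greedy moves never decrease it, and moves that would empty a
block are disallowed so exactly `k` modules come back. This is a
deliberate simplification of exact nested-SBM inference: a full sampler
adds heavy machinery for little benefit at cohort sizes of 100–500, and
the greedy fit recovers planted partitions exactly in the test suite.

The module count for each algorithm is chosen by mean silhouette width on
the spectral embedding (Euclidean distances), with ties broken toward the
smaller `k`. Both algorithms are scored on the same kind of embedding so
their silhouettes are comparable across `k`. The default grid is geometric
— $2, 4, 8, \ldots$ up to $n/2$, refined by $\pm 1$ around the best
candidate — because real cohorts can have module counts from a handful to
hundreds, and a geometric scan reaches large `k` at logarithmic cost.

Memberships are one-hot encoded and concatenated: each patient contributes
13 centrality values plus exactly two 1s across the modularity columns
(one per clustering algorithm). The feature table records per-column
provenance tags (`centrality:<name>`, `modularity:<algorithm>:<index>`).

## Fusing omics

**Network level (SNF).** Each per-omics affinity is normalized to a full
kernel $P$ with $P_{ij} = a_{ij} / (2 \sum_{k \ne i} a_{ik})$ off the
diagonal and $P_{ii} = 1/2$, and to a sparse local kernel $S$ that keeps
each row's `K` largest neighbours (ties toward the lower patient index,
for determinism) renormalized to sum 1. Cross-diffusion then iterates
$$P_v \leftarrow S_v \cdot \operatorname{mean}_{u \ne v}(P_u) \cdot S_v^T,$$
restoring the half-diagonal normalization after every step; after `t`
iterations the kernels are averaged, symmetrized, and the diagonal is
zeroed for downstream PSN use. Defaults `K = min(20, n - 1)` and `t = 20`
are the values commonly used with SNF. The half-diagonal renormalization
matters: plain row normalization lets self-mass drift and degrades the
fused structure. SNF consumes the soft-thresholded affinities directly
(they are already similarity kernels); rebuilding distances with an
exponential kernel would discard the scale-free calibration.

One property worth knowing: cross-diffusion preserves the *rank ordering*
of affinities only on locality-structured networks (graded similarities,
patients near a low-dimensional manifold) — the regime similarity data
actually occupy. On an i.i.d.-random affinity matrix the fused ordering can
even invert, because a large direct edge drains row-normalized mass from
the neighbour-overlap term that dominates the diffusion. The test suite
therefore checks rank preservation on latent-manifold networks, not on
noise matrices.

**Feature level.** The 13-column centrality blocks are averaged
elementwise across omics and the modularity blocks are concatenated with
provenance-tagged metadata. Averaging is meaningful because the centrality
block has identical semantics in every omics; one-hot memberships from
different networks cannot be averaged, so they are stacked. After either
fusion, features are z-scored (training-fold statistics only, applied
unchanged to test folds).

## Classifiers

**MLP.** A feed-forward network with ReLU hidden layers, inverted dropout,
and a 2-unit softmax output, trained with Adam on the cross-entropy loss.
When the class split is more extreme than 60/40 the loss is weighted with
$w_i = \max(n_0, n_1)/n_i$, which gives both classes equal total mass;
with balanced data the weights are exactly 1 and the loss reduces to the
standard one. Defaults mirror the configurations that worked well in
practice on network features: hidden sizes `c(8, 64, 4, 8)` (alternative
`c(4, 4, 4)`), learning rate 0.01, batch size 8 or 32, dropout 0.5. Early
stopping monitors the weighted loss on a 10% stratified validation split
of the training data with patience 20 (in epochs); the weights at the best
validation loss are restored. Every stochastic ingredient — initialization,
the validation split, batch shuffling, dropout masks — runs inside one
seeded RNG stream, so identical configurations and seeds reproduce
identical weights. Ties at the output argmax go to class 0 (the
no-event class), and the true-class probability is clipped at $10^{-12}$
inside the loss rather than erroring.

**RFE.** Recursive feature elimination wraps a linear SVM, logistic
regression, a decision tree, or a random forest: fit, rank features
(absolute coefficient for the linear estimators, impurity importance for
the trees), remove exactly the single lowest-ranked feature, repeat until
`n_select` remain — always `n_features - n_select` iterations. The
estimators themselves come from e1071, stats, rpart, and randomForest;
only the elimination loop and ranking conventions are the package's.

## Integrated Gradients and abridgement

Attributions follow the path-integral definition: for input $x$ and
baseline $x'$,
$$\mathrm{IG}_i(x) = (x_i - x'_i) \int_0^1
\frac{\partial F(x' + \alpha (x - x'))}{\partial x_i}\, d\alpha,$$
discretized by a midpoint Riemann sum with `steps = 300` points by
default. Three package choices:

* $F$ is the *logit* of the model's predicted class, not the softmax
  probability — softmax saturation flattens gradients precisely for
  confident predictions, which is where attributions are most wanted;
* the baseline is the zero vector: features are z-scored, so zero is the
  cohort mean, a neutral reference;
* midpoint (rather than left-endpoint) evaluation makes the linear case
  exact at any step count and halves the error constant for piecewise
  linear networks.

Per-feature saliency is the Euclidean norm of the attribution column
across samples (an L1 norm was the plausible alternative; L2 emphasizes
features that are strongly attributed for at least some patients rather
than mildly attributed everywhere).

The abridgement loop computes saliency once on the model trained with all
features, freezes the ranks, and then removes the least-salient feature
one at a time, retraining with fixed hyperparameters and recording
held-out metrics, down to a single feature. Frozen ranks keep the trace at
$O(p)$ trainings and match the idea of ranking by the full model's
attributions; recomputing ranks after every removal would conflate the
ranking with the shrinking model sequence. The best subset maximizes the
primary metric, ties going to the smaller subset.

## Nested cross-validation

Stratified 3-fold outer and inner loops (class proportions within one
sample per fold). The inner loop grid-searches hyperparameters on the
outer-training data only; the winner is refit on the full outer-training
fold and scored once on the outer-test fold. The procedure repeats over 3
random fold assignments by default to populate the reported mean ± SD.
Model selection uses F1 when the class split is more extreme than 60/40
and accuracy otherwise, matching how an imbalanced endpoint should be
judged. The report retains every fold assignment (outer and inner, in
original sample indices) so leakage can be audited mechanically — the test
suite asserts that no sample index is shared between an outer-test fold
and any inner fold derived from it. AUC is computed by the rank statistic
with midrank tie correction and reported as missing (not 0.5) when a test
fold contains a single class.

One transductive caveat, shared with the method as published: network
features are extracted from a PSN built on *all* patients, so the graph
structure (not the labels) of test patients influences training features.
`run_pipeline()` keeps labels strictly out of the test side — the
prefilter, z-scoring, and the classifier see training folds only — but a
fully inductive variant would need to embed new patients into an existing
network, which is out of scope.

## The synthetic study conditions

`generate_multiomics()` defines the conditions under which every claim in
the test suite is computed:

* cohorts of 100–150 patients with two omics layers of 500 and 400
  features, 50 informative, standardized effect size 2, imbalance 0.55
  (the heterogeneous, near-balanced regime) or 0.77 (the imbalanced
  regime that triggers class weighting);
* background features are i.i.d. Gaussian with `noise_sd = 1`;
  informative features receive a class-1 mean shift of
  `effect_size * noise_sd`, with each feature's shift *direction* drawn
  once at random. The random sign reflects how real differential features
  split into up- and down-regulated sets, and it is also what makes the
  signal detectable by a correlation-based PSN at all: a same-direction
  constant shift is a profile offset, and Pearson correlation removes
  profile offsets exactly, so an all-up signature would be provably
  invisible to the network construction no matter how large the effect;
* homogeneous mode draws one shared latent signal matrix and re-observes
  it in every omics with independent measurement noise at half the
  background SD (two platforms assaying the same transcriptome);
  heterogeneous mode draws independent informative sets per omics
  (distinct molecular layers);
* label counts are exact (`round(imbalance * n)` in the majority class),
  and the planted informative indices are returned as ground truth;
* a preferential-attachment graph generator supplies the scale-free
  fixture for the fit index, and a planted-block affinity generator
  supplies module-recovery ground truth.

What the generator does **not** emulate: count or beta-value marginal
distributions, feature–feature correlation within a layer, batch effects,
missingness, or outliers. Passing tests therefore demonstrate that the
pipeline recovers structure it is designed to see under clean Gaussian
conditions — not that it is robust to the full messiness of real assays.
Real-data performance must be established on real cohorts.

## Numerical conventions

* Affinity symmetry is enforced within $10^{-10}$ and re-symmetrized as
  $(A + A^T)/2$; diagonals are held at exactly 0.
* Top-K and minimum selections break ties toward the lower index; the
  silhouette scan and the abridgement argmax break ties toward smaller
  `k` / fewer features. All tie rules are deterministic.
* The SBM greedy accepts a move only if the objective gain exceeds
  $10^{-12}$; peeling groups nodes within $10^{-12}$ of the minimum.
* Probability clipping at $10^{-12}$ in the loss; degenerate (constant)
  feature columns get unit scale in z-scoring instead of dividing by 0.
* All randomness flows through an explicit seed argument and a
  save/restore RNG helper, so library calls never perturb the caller's
  RNG stream; there is no hidden global state.
* Test-suite problem sizes: oracle graphs of 3–9 nodes, module-recovery
  fixtures of 40–60 nodes, cohorts of 100–150 patients with up to 1000
  features, and a 500-node preferential-attachment graph — sizes at which
  every check runs in seconds while still exercising the same code paths
  as a full-scale analysis.

## Known limitations

* Complete dense PSNs cost $O(n^2)$ memory and the current-flow
  betweenness $O(n^4)$ time (C++ inner loop); cohorts beyond a few
  thousand patients would need sparsification and approximate flows.
* The Gaussian-weight SBM assumes weights scatter symmetrically around
  block means; heavy-tailed weight distributions may favour spectral
  clustering's partition instead.
* The MLP is intentionally small and CPU-bound; it is not a general deep
  learning stack.
* Module one-hot features are not aligned across refits: module 3 of one
  training fold need not correspond to module 3 of another. Within one
  pipeline run this is immaterial (features are extracted once), but
  cross-run comparisons of individual modularity columns are meaningless.
* With `n_bins = 10`, cohorts under ~30 patients often occupy too few
  connectivity bins for a stable scale-free fit; the fallback argmax rule
  then decides $\beta$.
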