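---
title: "Predicting drug-target interactions from heterogeneous networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-target interactions from heterogeneous networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetdti)
```

## The problem

Experimentally mapping which proteins a drug binds is slow and expensive,
so computational ranking of candidate drug-target interactions (DTIs) is a
standard first step in drug discovery and repositioning. The working
assumption is guilt by association: drugs that occupy similar positions in
pharmacological networks tend to share targets, and vice versa. hetdti
implements a network-integration pipeline for this task. Its input is a
heterogeneous network over four node types -- drugs, proteins, diseases
and side-effects -- connected by six binary relations (drug-protein,
drug-drug, protein-protein, drug-disease, drug-side-effect,
protein-disease), optionally augmented with precomputed drug-drug chemical
similarity and protein-protein sequence similarity matrices. Its output is
a score for every drug-protein pair, with the known-interaction matrix
**P** as training signal.

## The model, stage by stage

### 1. Network collections

Diffusion operates per network, never on the union graph, so network-
specific topology is not blurred together. The drug-side collection is the
drug-drug interaction network, the chemical similarity matrix (when
supplied), and Jaccard profile similarities derived from the drug-disease
and drug-side-effect associations; the protein side is the
protein-protein network, the sequence similarity matrix, and the Jaccard
similarity of protein-disease profiles (`build_collections()`). For two
binary association profiles the Jaccard index is
\(J(i,j) = |R_i \cap R_j| / |R_i \cup R_j|\); empty unions score 0 and the
diagonal is 1 by convention so every node has a valid start distribution.
The drug-protein matrix **P** is deliberately excluded from the
collections: it is the quantity being predicted, and it enters only at the
projection stage. A useful side effect is that cross-validation needs to
refit only the projection per fold -- the features depend on the side
networks alone.

### 2. Random walk with restart

Each network is row-normalized into a transition matrix (all-zero rows
become uniform distributions, so the result is exactly row-stochastic) and
diffused by random walk with restart: a walker follows edges with
probability \(1 - p_r\) and teleports to its start node with probability
\(p_r\). Row *i* of the converged matrix **S** is node *i*'s *diffusion
state* -- its probability distribution over all nodes, a fingerprint of
its topological context that mixes local and global connectivity. The
implementation iterates \(S \leftarrow (1-p_r)\,S W + p_r I\) from
\(S = I\) until the largest per-row L1 change falls below `tol`; at
convergence this solves \(S = p_r (I - (1-p_r) W)^{-1}\), and the test
suite checks the iterate against that dense solve.

* `restart_prob` (default 0.5): higher values localize the walk around
  the start node; 0.5 balances local and global structure and is the
  conventional choice for this pipeline family.
* `tol = 1e-8`, `max_iter = 1000`: cheap at the problem sizes involved
  and far tighter than the downstream SVD's sensitivity; hitting the cap
  raises a warning rather than failing silently.

### 3. Compact feature learning

Raw diffusion states are high-dimensional and noisy; using them directly
as features propagates that noise. The pipeline therefore concatenates
each node's diffusion states across the collection's networks into an
\(n \times kn\) matrix, takes \(L = \log(\cdot + \epsilon)\), and computes
the rank-*d* truncated SVD \(L \approx U_d \Sigma_d V_d^\top\). The node
features are \(X = U_d \Sigma_d^{1/2}\). By Eckart-Young this is the
rank-*d* factorization with minimal Frobenius reconstruction error of
*L*, a deterministic closed-form stand-in for fitting multinomial
logistic models to the diffusion states; the log transform converts the
multiplicative scale of visiting probabilities into additive structure.

* `log_offset` \(\epsilon\) (default \(1/n\)): bounds the log of
  near-zero diffusion mass at \(-\log n\).
* `dim_drug = 100`, `dim_protein = 400` by default at database scale;
  requested dimensions above what a collection supports are lowered with
  a warning. Desk-scale benchmarks in this package use 20 per side (see
  below).
* Sign convention: each singular vector's largest-magnitude entry is made
  positive, so repeated runs are bit-identical across numerics backends.

### 4. Bilinear projection and scoring

With drug features *X* and protein features *Y*, the pipeline learns a
projection matrix \(Z = F G^\top\) of rank *k* minimizing
\[
\lVert P - X F G^\top Y^\top \rVert_F^2
  + \lambda (\lVert F \rVert_F^2 + \lVert G \rVert_F^2),
\]
an inductive-matrix-completion formulation in which unobserved pairs are
treated as zeros. Alternating least squares solves each factor's ridge
normal equations exactly (via eigendecompositions of the two Gram
matrices), so the objective is non-increasing; the trace is recorded per
iteration and asserted in the tests. Scores are
\(\hat S = X Z Y^\top\) -- geometrically, how close protein *j*'s feature
vector lies to the projected image of drug *i*. Candidate targets are
ranked per drug in descending score, ties broken by registry index.

* `k` (default `min(50, d_drug, d_protein)`): the effective rank of the
  drug-to-protein map; small values regularize, large values memorize.
* `lambda = 1`: ridge penalty; with `lambda = 0` and rank-deficient
  features the solve is refused with guidance rather than returning
  garbage.
* `loss = "masked"`: an alternative in which the squared loss counts only
  entries flagged in a mask, with the rest handled by EM-style imputation
  from the current fit (a majorize-minimize scheme, so the masked
  objective also descends). The default full loss treats absent edges as
  weak negatives, which matches how the benchmark's evaluation negatives
  are defined.

## Evaluation protocols

`make_cv_splits()` partitions the known interactions into ten folds;
negatives are sampled uniformly from the non-interacting pairs, either
matching the positives in count (`matched`), nine times as many
(`ratio9`, positives are 10% of the test set), or all remaining pairs
(`all`). AUROC uses the rank-sum (Mann-Whitney) form with ties counted
one-half; AUPR is the step-function area with no interpolation, the
preferred metric under class skew. `recall_at_k()` is micro-averaged over
held-out pairs (macro per drug behind a flag).

Redundancy-aware filtering (`apply_redundancy_filter()`) removes from the
test set any pair whose drug or protein is adjacent, in a thresholded
similarity graph, to a node occurring in a training positive --
e.g. proteins above 40% sequence identity or drugs above 60%
Tanimoto/Jaccard similarity, with strict inequality at the threshold.
This guards against inflated scores from near-duplicate entities
straddling the train/test divide.

Two harder protocols probe repositioning realism: `singleton_eval()`
holds out, for every drug with exactly one known target, that single
interaction (leaving the drug with no training targets at all) and
reports the recall curve of the true target's rank; `holdout_split()`
trains on everything except an externally supplied pair list, the shape
of a database-release temporal hold-out. `perturb_network()` adds and/or
deletes an exact count of non-DTI edges to measure robustness to noise
and incompleteness; deletions that would isolate a node are re-sampled.

## The synthetic benchmark

`generate_network()` plants a ground truth the pipeline should recover.
Drugs and proteins receive latent factors \(U \in \mathbb{R}^{n_d \times r}\),
\(V \in \mathbb{R}^{n_p \times r}\) (standard normal, default
\(r = 4\)); the interaction matrix is the top `dti_density` quantile of
\(U V^\top\), so the positive count is exact and tests are
count-deterministic. Twenty of the planted top-quantile pairs are withheld
from **P** as held-out ground truth. Every side network derives from its
own *partial view* of the factors: one latent dimension is blanked
(cycling over dimensions within each side) and independent Gaussian noise
(sd 0.05) is added. Drug-drug and protein-protein edges connect top
latent-cosine pairs (20% density, echoing the high mean degree of curated
interaction databases); disease and side-effect associations are the top
quantile of a planted bilinear model against item latent vectors, so
Jaccard profile similarities correlate with latent proximity; similarity
matrices are latent cosines clipped to \([0,1]\). Finally each non-DTI
relation cell flips with probability 0.01.

The partial-view design is the generator's key feature. With independent
noisy copies of the full factors, one clean network (chemical similarity,
say) carries the entire latent geometry and integrating further networks
cannot help -- contradicting both intuition and practice. With
complementary partial views, no single network can rank the pairs driven
by its missing dimension, while the ensemble covers all dimensions; the
benefit of integration becomes structural rather than an averaging
artifact. This mirrors how real evidence layers behave: chemical
similarity, shared interaction partners and shared side-effects each
reflect different determinants of binding.

What the generator does *not* emulate: the scale-free degree
distributions, size (thousands of nodes, millions of edges) and
inter-relation correlations of real curated databases; weighted or
directed evidence; batch- or literature-driven ascertainment bias, where
well-studied drugs accumulate edges in every relation simultaneously.
Passing the planted benchmark therefore demonstrates that the pipeline
recovers low-rank interaction structure spread across partial,
noisy evidence layers -- not that it matches any particular published
performance figure on real data.

## Problem sizes and the desk-scale configuration

The synthetic benchmark runs at 50 drugs, 40 proteins, 30 diseases and
25 side-effects, sized so the complete pipeline and its ten-fold
cross-validation finish in seconds. At this size the package's
experiments use feature dimension 20 per side, projection rank
\(k = 10\), \(\lambda = 1\) and 60 ALS iterations. Two deliberate
exceptions: the planted-overlap check (how many of the top-ranked 100
pairs of a full-data fit are planted interactions) uses feature dimension
30, because in-sample reconstruction rewards more capacity than held-out
generalization tolerates; and the held-out-pair ranking check averages
over five generator seeds, because single-realization values at this
problem size fluctuate by several AUROC points around their mean of
roughly 0.93.

## Numerical choices and degenerate inputs

* Dangling rows in a transition matrix become uniform distributions;
  a one-node network diffuses to the 1x1 identity.
* Ranking ties break by ascending registry index, everywhere --
  reproducibility over arbitrariness.
* Interaction/association edge weights other than 1 are clamped to 1
  with a warning; undirected relations symmetrize by `max(A, t(A))`, so
  an edge reported once counts once.
* Nodes with no edge in any relation are dropped at read time (with a
  count in a message), since diffusion from an isolated node carries no
  information.
* `d` above the numerical rank of the log-diffusion matrix is an error
  naming the achievable maximum; requested dimensions above the node
  count are lowered with a warning.
* All randomness (initialization, splits, sampling, generation) flows
  from explicit integer seeds; a single pipeline seed is fanned out to
  stages by fixed offsets.

## Design decisions that were genuinely open

* The exact recipe turning bipartite associations into diffusible
  same-type networks is not uniquely determined by the method's public
  description; Jaccard profile similarity was chosen for consistency
  with the Jaccard-based redundancy criteria already in the evaluation
  protocols.
* The dimensionality-reduction objective is implemented as its truncated
  SVD surrogate rather than an iterative KL-divergence optimizer:
  deterministic, exactly optimal in the Frobenius sense, and orders of
  magnitude simpler to verify.
* The matrix-completion loss counts every entry of the binary **P**
  (absent edges as zeros); a masked variant is provided for sensitivity
  analysis. Feature rows are not L2-normalized by default; the projection
  fit handles scale through its ridge penalty.
* Negative sampling is uniform over non-interacting pairs, not stratified
  per drug, matching the benchmark protocols this package implements.
* Cross-validation re-samples negatives per trial; fold metrics are
  summarized as mean and SD across trials.

## Known limitations

* Dense matrix algebra throughout: appropriate up to a few thousand
  nodes per type, not for millions of edges without sparse refactoring.
* The score matrix is unnormalized; scores rank pairs but are not
  calibrated probabilities.
* Diffusion runs per network; cross-type edges influence features only
  through the derived association-profile similarities, not through a
  joint walk on the union graph (by design, but worth stating).
* The masked loss is a sensitivity tool; its statistical behavior under
  extreme sparsity has not been characterized here.
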