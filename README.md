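# hetdti

Drug–target interaction (DTI) prediction from a heterogeneous
pharmacological network.

Mapping which proteins a drug binds is a bottleneck of drug discovery and
repositioning; computational ranking of candidate interactions narrows
the search before any assay is run. `hetdti` scores every drug–protein
pair of a heterogeneous network built from four node types (drugs,
proteins, diseases, side-effects) and six relations (drug–protein,
drug–drug, protein–protein, drug–disease, drug–side-effect,
protein–disease), optionally augmented with precomputed chemical and
sequence similarity matrices.

## The method

Three stages, each exposed as ordinary functions:

1. **Per-network diffusion.** Every drug-side and protein-side network
   (interactions, similarities, and Jaccard similarities of association
   profiles) is diffused with random walk with restart: row *i* of
   *S* = *p*<sub>r</sub>(*I* − (1 − *p*<sub>r</sub>)*W*)<sup>−1</sup>
   is node *i*'s diffusion state, a fingerprint of its topological
   context.
2. **Compact feature learning.** The per-node diffusion states are
   concatenated across networks and reduced by truncated SVD of
   *L* = log(· + ε): features are *X* = *U*<sub>d</sub>Σ<sub>d</sub><sup>1/2</sup>,
   the rank-*d* factorization minimizing the Frobenius reconstruction
   error of *L*.
3. **Bilinear projection.** A low-rank matrix *Z* = *F G*<sup>⊤</sup> is
   learned by alternating ridge-regularized least squares to minimize
   ‖*P* − *X Z Y*<sup>⊤</sup>‖²<sub>F</sub> + λ(‖*F*‖² + ‖*G*‖²) against
   the known interaction matrix *P*; pair (*i*, *j*) is scored as
   *x*<sub>i</sub>*Z y*<sub>j</sub><sup>⊤</sup> and targets are ranked
   per drug.

The package also ships the full evaluation protocol suite (ten-fold CV
with matched / 1:9 / exhaustive negatives, redundancy-aware test
filtering at strict similarity thresholds, singleton-drug and named-pair
hold-outs, recall@top-k, edge-perturbation robustness) and a synthetic
network generator with planted low-rank interaction structure, so the
whole pipeline is testable without any external data. See the methods
vignette (`vignettes/hetdti-methods.Rmd`) for the model, parameter and
generator details.

## Worked example

```r
library(hetdti)

gen <- generate_network(synth_config(seed = 42))
net <- gen$network
net
#> Heterogeneous drug-target network
#>   drug            50 nodes
#>   protein         40 nodes
#>   disease         30 nodes
#>   side_effect     25 nodes
#>   drug_protein       100 edges
#>   drug_drug          250 edges
#>   ...

cfg <- pipeline_config(dim_drug = 20, dim_protein = 20, k = 10,
                       lambda = 1, iters = 60, seed = 42)
fit <- fit_pipeline(net, cfg)
fit$model
#> Bilinear projection model: rank 10, lambda 1, full loss
#>   objective 2.423e+04 -> 59.19 over 40 iteration(s)
```

The monotone objective drop shows the alternating solver converging.
Ranked novel predictions (pairs not in the training matrix, best first):

```r
predictions_table(fit, net$relations$drug_protein, top_n = 3)
#>   drug protein     score rank
#> 1 D023    P040 0.5557816    1
#> 2 D044    P006 0.5491972    2
#> 3 D013    P008 0.5363023    3
```

Scores are unnormalized bilinear proximities — useful for ranking, not
calibrated probabilities. Ten-fold cross-validation with matched
negatives:

```r
res <- evaluate_cv(net, cfg)
round(attr(res, "summary"), 3)
#> auroc_mean   auroc_sd  aupr_mean    aupr_sd
#>      0.934      0.052      0.942      0.040
```

An AUROC of 0.93 means a held-out true interaction outscores a random
non-interacting pair 93% of the time; here that signal is the planted
rank-4 latent structure the generator buried across the side networks.
Candidate targets for one drug, known interactions excluded:

```r
head(rank_targets(fit$S_hat, "D001", exclude_known = TRUE,
                  train_P = net$relations$drug_protein), 3)
#>   protein     score rank
#> 1    P014 0.3569468    1
#> 2    P032 0.2900179    2
#> 3    P007 0.2860859    3
```

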