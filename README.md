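# scNBMF

Negative binomial matrix factorization for single-cell RNA-seq.

## What problem this solves

Identifying cell types from scRNA-seq starts with dimensionality
reduction, but expression is measured in read counts: sparse, over-dispersed,
and with depth varying cell to cell. Pipelines that log-transform and run
PCA discard the count structure; bespoke count models exist but are slow at
even moderate cell numbers. scNBMF factorizes the raw count matrix
directly under a negative binomial likelihood, for analysts who have a
genes × cells count matrix (and optionally cell-type annotations to
evaluate against).

The model, for gene *i* and cell *j*:

    y_ij ~ NB(mu_ij, phi_i),    log mu_ij = log N_j + sum_k W_ik H_kj

* `N_j` — the cell's total read count, a fixed offset (no depth
  normalization of the counts themselves);
* `phi_i` — gene-wise over-dispersion (variance `mu + mu^2/phi`),
  estimated first by method of moments and held fixed;
* `W` (genes × K) — gene loadings, carrying a LASSO penalty;
* `H` (K × cells) — cell factors, the embedding used for clustering.

Fitting minimizes `-loglik + lambda * ||W||_1` with full-batch Adam;
embeddings are evaluated by repeated k-means scored with NMI and ARI
against annotated labels. A synthetic generator with planted cell types
makes the whole pipeline testable end to end.

## Worked example

```r
library(scNBMF)

# synthetic benchmark: 300 cells, 500 genes, 4 planted types
sim    <- simulate_counts(sim_config(n_cells = 300, n_genes = 500,
                                     n_types = 4, seed = 7))
depths <- size_factors(sim$counts)
phi    <- shrink_dispersion(estimate_dispersion(sim$counts, depths))
fit    <- fit_scnbmf(sim$counts, depths, phi,
                     fit_config(n_components = 10, lambda = 1,
                                max_iter = 5000, seed = 7))
fit
#> fit_result: K = 10, 5000 iterations, objective 1.227e+06 -> 4.321e+05

cluster_and_score(fit$model$H, sim$labels, n_repeats = 100, seed = 7)
#> clustering_result over 100 k-means repeats:
#>   NMI mean 0.9981 best 1.0000
#>   ARI mean 0.9964 best 1.0000
```

The objective is the penalized negative log-likelihood (lower is better);
NMI/ARI of 1 mean the k-means partition of the fitted factors matches the
planted cell types exactly, 0 is chance level. Here the embedding recovers
the 4 planted types nearly perfectly in every restart.

The same pipeline from the shell:

```sh
scnbmf simulate --out sim/ --n-cells 300 --n-genes 500 --n-types 4 --seed 7
scnbmf dispersion --counts sim/matrix.mtx --out phi.tsv
scnbmf fit --counts sim/matrix.mtx --phi phi.tsv --k 10 --max-iter 5000 --seed 7 --out run/
scnbmf evaluate --embedding run/embedding.tsv --labels sim/labels.tsv --out metrics.tsv
scnbmf diagnose --counts sim/matrix.mtx --out dropout.tsv   # observed vs NB-expected zeros
```

Every output directory carries a `manifest.json` (config, input checksums,
versions, seed) sufficient to reproduce the run; identical flags and seed
give byte-identical embeddings.

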