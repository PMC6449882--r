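---
title: "Count-native matrix factorization for single-cell RNA-seq: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count-native matrix factorization for single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Single-cell RNA-seq expression is measured in read counts, and counts carry
a mean–variance relationship that log-transform-then-PCA workflows discard.
scNBMF factorizes the count matrix directly. With `p` genes and `n` cells,
each count is modelled as negative binomial,

$$y_{ij} \sim \mathrm{NB}(\mu_{ij}, \phi_i), \qquad
\Pr(y \mid \mu, \phi) = \binom{y+\phi-1}{y}
\left(\frac{\mu}{\mu+\phi}\right)^{y}
\left(\frac{\phi}{\mu+\phi}\right)^{\phi},$$

with a log-linear rate
$$\log \mu_{ij} = \log N_j + \sum_{k=1}^{K} W_{ik} H_{kj},$$

where \(N_j\) is the total read count of cell \(j\) (its sequencing depth,
entering as a fixed offset), \(W\) (genes × K) are gene loadings and \(H\)
(K × cells) are the cell factors — the embedding used to detect cell types.
\(\phi_i\) is the gene-wise over-dispersion: the variance is
\(\mu + \mu^2/\phi\), so *small* \(\phi\) means strong over-dispersion and
\(\phi \to \infty\) recovers the Poisson distribution. (One sometimes sees
the opposite claim — that \(\phi \to 0\) gives Poisson — but under this
parameterization that is incorrect, and `nb_logpmf()` is tested against the
\(\phi \to \infty\) limit.)

Fitting minimizes the LASSO-penalized negative log-likelihood

$$-\ell(W, H) + \lambda \sum_i \lVert W_i \rVert_1 .$$

A likelihood cannot sensibly be *maximized* with a positive penalty added
to it, so the package uses the standard penalized-likelihood minimization
form; the penalty sits on \(W\) only, because sparse gene loadings are what
make factors interpretable (most genes should not load on most factors).

Estimation is two-step: \(\phi_i\) is estimated per gene first and then held
fixed while (W, H) are optimized. Dispersion is a nuisance parameter here —
the factorization is the object of interest — and fixing it keeps the
optimization smooth and fast.

## Dispersion estimation

`estimate_dispersion()` uses depth-normalized method of moments: counts are
rescaled by \(\bar N / N_j\), and \(\hat\phi_i = m_i^2/(v_i - m_i)\) from the
gene's sample mean and variance. Genes with \(v_i \le m_i\) are
Poisson-like and get the upper clamp. Estimates are clamped to
\([10^{-3}, 10^{8}]\), a numerically safe range from near-degenerate
over-dispersion to effectively-Poisson. `shrink_dispersion()` optionally
pulls the noisy per-gene estimates toward their geometric mean in log space
(default weight 0.2 in the pipeline), a lightweight analogue of
empirical-Bayes tagwise shrinkage. This deliberately does **not** reproduce
any particular differential-expression package's common/trended/tagwise
machinery: the factorization only needs a stable per-gene scale for the
likelihood weights, and the test suite verifies rank agreement with an
established tagwise estimator rather than numerical identity. Whether
dispersion should be estimated on raw or depth-normalized counts is
genuinely open; we normalize, since otherwise depth variation masquerades
as biological over-dispersion.

## Optimization

`fit_scnbmf()` runs full-batch Adam (\(\beta_1 = 0.9\), \(\beta_2 = 0.999\),
\(\epsilon = 10^{-8}\) — the canonical values) on (W, H) from a random
initialization of scale \(0.01/\sqrt K\) (so the initial log-rates are near
zero and the starting means are near the depth offsets, whatever K is).
Defaults: learning rate 0.001, up to 18 000 iterations, \(\lambda = 1\).
The l1 term is handled by subgradient with \(\mathrm{sign}(0) = 0\) — which
is exactly what automatic differentiation of the written objective does —
so loadings oscillate within a step-size band of zero rather than landing
on it; `penalty_method = "proximal"` soft-thresholds after each step and
produces exact zeros, for users who want literal sparsity rather than
near-sparsity. Full-batch gradients are used throughout: at the few hundred
to ~1000 cells this model targets, a full gradient costs milliseconds and
minibatching would only add variance.

Two pragmatic guards:

* the log-rate \(\log(\mu_{ij}/N_j)\) is clamped to \(\pm 30\)
  (\(e^{30}\) times depth is beyond any real count); clamped entries
  contribute zero gradient, which is the correct derivative of the clip;
* the objective is logged every iteration and the fit stops early when the
  relative change between consecutive 100-iteration moving averages falls
  below `rel_tol` (default \(10^{-6}\)). Adam is not monotone step to step;
  the smoothed trace is, and the tests assert that.

Fixing the seed fixes the initialization and hence the entire trajectory:
fits are bitwise reproducible, and the command-line tool writes embeddings
with 17 significant digits so repeated runs are byte-identical.

`sgd`, `adagrad` and `momentum` are available behind `optimizer=` for
comparing first-order methods in spirit; only Adam is exercised by the
package's benchmarks, and it is the default for good reason — on the same
budget the alternatives descend far more slowly here.

Factors have no inherent order, so `order_factors()` sorts them by
decreasing variance of the H rows (deterministic tie-break by index) and
`write_embedding(top = m)` keeps the leading m. K defaults to 20; how many
factors to keep downstream is data-dependent and left to the user.

## Evaluation protocol

`cluster_and_score()` implements the standard protocol for scoring an
embedding against annotated cell types: k-means on the cells in factor
space, repeated (default 100 times, seeds `seed..seed+99`), each repeat
scored by NMI and ARI against the annotation. The k-means variant is Lloyd
with k-means++ seeding. Both the mean and the best over repeats are
reported; the package's own benchmarks gate on the **mean**, the
conservative, variance-aware summary. The number of clusters defaults to
the number of distinct true labels, and clustering is done on the factor
matrix directly (not on a further 2-D re-embedding, which would entangle
the evaluation with a second stochastic method).

NMI is \(I(L_e;L)/\sqrt{H(L_e)H(L)}\) from the contingency table, with the
degenerate single-cluster case defined as 0 (1 only when both partitions
are the same single cluster), avoiding 0/0. ARI is the pair-counting
chance-corrected form. Both are verified against brute-force
implementations that enumerate pairs and entropies directly, to 1e-12
absolute — absolute, because chance-level ARIs are numbers of magnitude
1e-5 whose relative float error is meaningless.

`log2_pseudocount_transform()` (log2(y+1)) is provided as the conventional
normalization for handing counts to methods that need continuous input;
the NB factorization itself never uses it.

## The synthetic generator

There is no public benchmark with known ground truth at desk scale, so
`simulate_counts()` draws data *from the model class the method assumes*:
per-type gene log-fold vectors \(\Delta_{\cdot t} \sim N(0, s^2)\) (default
\(s = 1\), well-separated types), per-cell depths
\(\mathrm{round}(\mathrm{lognormal}(\log 5000, 0.3))\), dispersions cycling
through \(\{0.5, 2, 10\}\) (strong to mild over-dispersion), and per-type
share normalization so expected column sums equal the drawn depths. The
default benchmark is 300 cells × 500 genes with 4 types — the shape of a
small published cell-type study, scaled down in genes.

What passing on this generator shows: the estimator and optimizer recover
structure that is really there, under realized over-dispersion, depth
variation 0.3 on the log scale, and NB sparsity. What it does not show:
robustness to zero inflation (no dropout beyond NB sampling by default —
an optional `dropout_rate` exists for robustness experiments), batch
effects, amplification bias, cell-cycle structure, or the gene counts of
real data (10⁴–10⁵). Conclusions about real tissues need real annotated
data.

One subtlety the tests respect: the generator's zero fractions are compared
with the *exact* model expectation — the average of \(\Pr(y=0 \mid
\mu_{ij}, \phi_i)\) over cells — not with \(\Pr(y=0)\) evaluated at the
gene's mean expression. Once cell types separate the means, Jensen's
inequality opens a visible gap (≈0.06 mean absolute deviation at default
settings) between the two, which is a property of the nonlinearity, not a
defect of the generator.

## Numerical choices

* `nb_logpmf()` uses `lgamma` throughout and computes
  \(\phi\log(\phi/(\mu+\phi))\) as \(-\phi\,\mathrm{log1p}(\mu/\phi)\);
  without `log1p` the Poisson-limit regime (\(\phi \sim 10^8\)) loses all
  precision to cancellation.
* Integer-valued input is enforced, never rounded: fractional "counts"
  signal an upstream normalization that would invalidate the model.
* Cells with zero total count have no depth offset and are rejected (or
  dropped with a warning by `read_counts()`).
* The default gene filter (CLI) removes genes expressed in fewer than 2
  cells; published analyses filter "lowly expressed genes" without stating
  thresholds, so the package makes its own rule minimal and configurable.
* Problem sizes in the test suite (300×500 benchmark, 5000-iteration fits,
  20 null replicates) were chosen so the full suite exercises the complete
  pipeline at the scale of a small real study while staying comfortable to
  run on a laptop core.

## Known limitations

* No zero-inflated likelihood: data with heavy technical dropout beyond NB
  sampling will push observed zero fractions above the expected curve
  (`dropout_diagnostic()` makes this visible) and bias the fit.
* No covariates beyond the depth offset (no gene length/GC, no batch
  terms).
* Dispersion is fixed, not jointly estimated; severe misestimation
  propagates into the likelihood weights.
* Subgradient handling of the l1 term yields near-zeros, not exact zeros,
  unless the proximal variant is selected.
* The k-means protocol presumes roughly spherical clusters in factor
  space and is given the true number of clusters by default.
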