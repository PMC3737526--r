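---
title: "Iterative correlation features: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative correlation features: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipcc)
```

## The transform

Given an expression matrix $X \in \mathbb{R}^{n \times m}$ ($n$ genes, $m$
samples), the order-1 correlation features of sample $i$ are its Pearson
correlations with every sample:

$$ r_{ij} \;=\; \frac{\sum_k (x_{ik} - \bar{x}_i)(x_{jk} - \bar{x}_j)}
   {\sqrt{\sum_k (x_{ik} - \bar{x}_i)^2}\,
    \sqrt{\sum_k (x_{jk} - \bar{x}_j)^2}}, $$

collected in the symmetric matrix $C_1 = (r_{ij}) \in [-1,1]^{m\times m}$.
Reading row $i$ of $C_1$ as a new feature vector for sample $i$ and
correlating rows again gives $C_2$, and recursively $C_{t+1} =
\operatorname{corr\_rows}(C_t)$ — the order-$t$ correlation features.
Order 0 denotes the raw expression features.

Two properties make the iteration useful. First, it reduces dimensionality
from thousands of genes to $m$ features, which directly counteracts the
curse of dimensionality for clustering and classification. Second, the map
is sharply contractive toward block structure: off-diagonal entries move
rapidly toward $+1$ (same latent class) or $-1$ (different class), so weak
class signal buried under many irrelevant genes is amplified order by
order. The canonical behaviours are packaged as `toy_fixture()`:

```{r toys}
round(unclass(iterate_features(toy_fixture(1), steps = 5))[3, ], 3)  # weak 0.3 -> ~1
max(abs(iterate_features(toy_fixture(2)) - toy_fixture(2)))          # fixed point
round(sapply(1:6, function(s) iterate_features(toy_fixture(3), s)[4, 1]), 3)
```

Toy 2 shows the other face of the transform: a sample exactly orthogonal to
two opposed samples is a *fixed point* — balanced independence is
preserved, not destroyed. Toy 3 shows structure invisible at order 1
(entry 0) surfacing at order 2 (≈ 0.174) and saturating at 1.

There is no convergence proof for general inputs; the package treats
saturation as an empirical phenomenon and reports it in the `trace` of
`ipcc()` (per-order maximum change, and the fraction of off-diagonal
entries within `eps_pm1` of ±1).

## Parameters that matter

* `max_order` (default 5) is the primary control. Orders 1–5 are the
  informative range in our experiments; beyond saturation additional
  orders only merge the closest classes (on multi-class data the two most
  similar classes eventually fuse — visible on three-class designs as a
  drop of k-means accuracy at orders ≥ 4). The optimal order depends on
  the noise level; features of several orders can be used jointly.
* `tol` (default `1e-9`, on the maximum absolute successive change) is a
  safety stop, triggered in practice only by exact fixed points.
* `kernel` defaults to Pearson. A Spearman kernel is exposed for
  exploration, but rank correlations do not show the same saturation
  behaviour and the package makes no claims for them.
* Constant sample profiles make the correlation undefined; the package
  errors by default (`on_constant = "drop"` discards them instead).
  Emitting 0 silently would corrupt every later order. `m = 2` is
  rejected at iteration time: both rows of a 2×2 correlation matrix are
  length-2 vectors, which are always perfectly correlated, so the first
  iteration is vacuous. Entries are clipped to $[-1,1]$ after each order
  purely to absorb floating-point excursions (≤ 1e-12); anything larger
  aborts.

## Batch adjustment

When the batch assignment (e.g. profiling laboratory) is known, the
order-1 matrix can be corrected before iterating:
$C_1' = C_1 + \lambda B$, with $B_{ij}$ equal to `within` (default −1) for
same-batch pairs and `between` (default +1) otherwise, and λ ≥ 0 (default
0.5). With the default coding $B = -uu^\top$ for the signed batch vector
$u$, so the update subtracts a rank-one batch component of amplitude λ.
Two consequences worth knowing:

* A location shift common to a whole profile never reaches $C_1$ in the
  first place (Pearson correlation is invariant to per-sample affine
  maps). Real laboratory effects act gene-wise, which is exactly what
  inflates same-batch correlations; the simulator below models them that
  way.
* λ should *undershoot* the batch amplitude visible in $C_1$. The
  iteration amplifies whatever residual structure dominates — including an
  over-corrected, sign-reversed batch pattern, which is as damaging as the
  original. The default 0.5 is deliberately conservative; inspect the
  within/between-batch means of $C_1$ when choosing λ for real data.

$C_1'$ is intentionally not re-clipped to $[-1,1]$ and its diagonal is not
reset: the next iteration correlates rows, which is insensitive to both,
and either "repair" would be an undocumented extra transform.

## What the simulators emulate

`simulate_class_data()` generates the benchmark design used throughout:
`n_classes` (3) contiguous classes of `samples_per_class` (50) samples;
per class `relevant_per_class` (2) marker genes distributed
N(1, σ) inside the class; `noise_fold` × (total relevant) irrelevant genes
at N(0, σ) everywhere. σ ranges over 0.1–0.5 and noise folds over
{0, 10, 50, 100}, so the largest setting is 606 genes × 150 samples. One
choice is not pinned down by the design: the distribution of a relevant
gene *outside* its class. We use N(0, σ), identical to the noise genes —
any other centre would be a second marker. `simulate_null_data()` draws
structure-free 150×150 matrices (standard normal, uniform on [0,1], or
discrete uniform on {−1,0,1}) as negative controls.

`simulate_batch_confounded()` crosses the class design with `n_batches`
batches and adds a per-(gene, batch) offset drawn N(0, `batch_shift`).
Defaults (2 classes × 20 samples, 10-fold noise, σ = 0.3,
`batch_shift` = 0.8) put the data firmly in the confounded regime: order-1
features cluster by batch, not class, and the λ = 0.5 adjustment
measurably restores class recovery.

None of the simulators attempt realistic microarray intensity
distributions, probe effects, correlated noise or missingness. Passing
tests on them demonstrates the mechanics of the transform under the stated
noise model, not performance on any particular real data set; real
matrices enter through `read_expression()` and the preprocessing chain.

## Evaluation choices

* **Clustering accuracy.** k-means is run with Lloyd's algorithm, uniform
  random choice of k samples as initial centres (no k-means++), at most
  300 iterations — the behaviour of generic implementations; the spread of
  local optima across restarts is part of what is being measured, so run
  r of `kmeans_runs()` is seeded `seed + r − 1` and every partition is
  returned. Accuracy is the fraction correct under the best one-to-one
  cluster↔class assignment, found exactly by exhaustive search on the
  contingency table (k ≤ 8 everywhere here; the Hungarian optimum and the
  exhaustive optimum coincide).
* **Classification.** Leave-one-out Gaussian naive Bayes with
  maximum-likelihood per-class variances, smoothed by `eps_frac` (1e-9) ×
  the largest per-feature training variance, and empirical priors. LOOCV
  is computed from class sufficient statistics with leave-one-out
  downdates, so the full loop is exact and fast.
* **Similarity statistics.** `intra_inter_similarity()` averages
  off-diagonal entries over same-class and different-class unordered
  pairs; the diagonal is excluded since its constant 1 would inflate the
  intra mean by construction. A perfect two-block ±1 matrix attains the
  maximal difference of 2.
* **Comparing accuracy distributions.** Welch's two-sided t-test; with
  hundreds of runs the equal-variance variant is indistinguishable, and
  Welch is the safer default. Exactly constant inputs (a 0/0 statistic)
  are resolved by convention: equal constants → t = 0, p = 1.
* **Preprocessing.** Flooring/ceiling at 100/16000, filters
  max/min ≥ 5 and max − min ≥ 500, then log10 — the conventional constants
  for two-colour-era leukemia intensities; all four are arguments.
  F-test selection ranks genes by the one-way ANOVA F statistic with
  descending stable order (ties keep input order; perfect separators rank
  first via F = ∞, constant genes last via F = 0).

## Problem sizes in the shipped tests

The test suite reproduces the study's behaviours at sizes chosen for a
laptop-class run: the toy analyses exactly as printed; k-means accuracy at
σ = 0.1 with 100 restarts per (fold, order); naive-Bayes LOOCV pooled over
σ ∈ {0.4, 0.5} with 10 replicate data sets each at 100-fold noise; the
null-data t-test comparison over 50 repeats of 6 data sets per arm with 2
restarts each; and the paired order-3 vs order-0 comparison over 20
replicates for each of σ ∈ {0.3, 0.4, 0.5} × {50, 100}-fold noise. The
batch directional check uses 20 replicates of the confounded design at its
defaults.

## Known limitations

* No convergence theory: saturation at ±1 is empirical, monitored, and not
  guaranteed for arbitrary inputs.
* The transform is unsupervised: it amplifies the *dominant* structure,
  whatever it is. Under known confounding use `ipcc_batch()`; unknown
  confounders will be amplified like signal.
* High orders merge similar classes; choose `max_order` against the
  class granularity you need, or combine orders.
* The Spearman kernel is exploratory only.
* Real-data figures from the original study (leukemia, prostate,
  psoriasis) require third-party downloads and are deliberately outside
  the test surface; the generic reader and preprocessing chain accept such
  matrices.
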