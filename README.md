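# ipcc — iterative Pearson correlation features for expression data

High-throughput expression profiling measures thousands of genes on a few
dozen to a few hundred samples, so the class structure that matters for
disease diagnosis (which samples belong together) is buried in a severely
under-determined feature space. `ipcc` attacks this from the
feature-extraction side: it replaces each sample's gene-expression profile
by its vector of Pearson correlations with all samples, and then *iterates*
that construction.

Given `X` (n genes × m samples), the order-1 features of sample *i* are

    r_ij = cor(x_i, x_j)   (Pearson, over genes k = 1..n)

collected in the symmetric matrix `C1`. Treating the rows of `C1` as new
feature vectors and correlating them again gives `C2`, and recursively
`C_{t+1} = corr_rows(C_t)` — the order-*t* correlation features. The
iteration contracts toward a ±1 block structure: weak sample similarity is
amplified order by order, orthogonal samples stay put, and latent classes
become visible to ordinary clustering and classification algorithms that
struggle on the raw high-dimensional features. When samples come from known
batches (different laboratories), the order-1 matrix can be additively
corrected with a batch-indicator matrix (`C1' = C1 + λB`) before iterating.

The package is aimed at anyone benchmarking feature extraction for
class discovery on expression matrices: it bundles the transform
(`sample_correlation()`, `iterate_features()`, `ipcc()`, `ipcc_batch()`),
the simulation designs used to characterize it (`simulate_class_data()`,
`simulate_null_data()`, `simulate_batch_confounded()`, `toy_fixture()`),
and an evaluation battery (`preprocess_expression()`, `f_test_select()`,
`kmeans_runs()` + `match_accuracy()`, `loocv_gaussian_nb()`,
`intra_inter_similarity()`, `accuracy_ttest()`), plus TSV/JSON readers,
writers and a command-line interface (`inst/exec/ipcc`).

## Worked example

Simulate the hardest benchmark-style setting short of the maximum — 3
classes × 50 samples, 2 marker genes per class, 50-fold noise genes,
σ = 0.3 — and watch the class structure sharpen with the order:

```r
library(ipcc)
d   <- simulate_class_data(noise_fold = 50, sigma = 0.3, seed = 42)
res <- ipcc(d$expression, max_order = 5)
sapply(res$features, function(C) unlist(intra_inter_similarity(C, d$labels)))
#>            order1  order2 order3  order4  order5
#> intra_mean 0.0696  0.1669  0.550  0.8719  0.9002
#> inter_mean 0.0006 -0.0796 -0.274 -0.4278 -0.4342
#> difference 0.0690  0.2465  0.824  1.2997  1.3344
```

At order 1 same-class pairs are barely more similar than different-class
pairs (difference 0.07); by order 5 the separation statistic is 1.33 of a
possible 2. Clustering feels the difference directly:

```r
acc <- function(F) mean(apply(kmeans_runs(F, k = 3, n_runs = 100, seed = 1),
                              1, match_accuracy, truth = as.character(d$labels)))
acc(t(d$expression))          # order 0 (raw features)
#> [1] 0.791
acc(res$features[["order3"]]) # order 3
#> [1] 0.98
```

Mean matched k-means accuracy over 100 random restarts rises from 0.79 on
the raw 306-gene features to 0.98 on the order-3 correlation features.
The same pipeline runs from the shell:

```sh
ipcc simulate --sigma 0.3 --fold 50 --seed 42 --out-prefix sim
ipcc transform --input sim.expression.tsv --max-order 5 --out-prefix feats
ipcc evaluate cluster --features feats.order3.tsv --labels sim.labels.tsv \
     --k 3 --runs 100 --seed 1 --out report.json
```

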