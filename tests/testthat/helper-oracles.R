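# Independent oracles used across the suite.

# naive per-pair Pearson correlation, straight from the definition
naive_pearson_matrix <- function(M) {
  # M: samples x features; returns pairwise correlation of rows
  m <- nrow(M)
  out <- diag(m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      xi <- M[i, ] - mean(M[i, ])
      xj <- M[j, ] - mean(M[j, ])
      out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  out
}

# closed-form one-step map for the 3-sample family [[1,-1,x],[-1,1,-x],[x,-x,1]]
toy1_step <- function(x) (4 * x / 3) / sqrt(x^4 / 3 + 10 * x^2 / 9 + 1 / 3)

# small random expression fixture
random_expression <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  dimnames(X) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(n_samples)))
  X
}

# mean matched k-means accuracy over restarts
mean_kmeans_accuracy <- function(features, truth, k, n_runs, seed) {
  runs <- kmeans_runs(features, k = k, n_runs = n_runs, seed = seed)
  mean(apply(runs, 1L, match_accuracy, truth = as.character(truth)))
}
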