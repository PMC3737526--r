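#' Simulate a class-structured expression data set
#'
#' Generates the class-discovery benchmark design: `n_classes` sample
#' classes laid out contiguously, each marked by `relevant_per_class` genes
#' whose expression is N(`class_mean`, `sigma`) in the class's own samples
#' and N(0, `sigma`) elsewhere, plus `noise_fold` times as many irrelevant
#' genes drawn N(0, `sigma`) for every sample.  The default parameters (3
#' classes of 50 samples, 2 relevant genes per class, noise folds 0/10/50/100
#' and sigma in 0.1-0.5) span the benchmark grid; e.g. the 100-fold setting
#' yields a 606-gene x 150-sample matrix.
#'
#' The distribution of a relevant gene outside its own class is not pinned
#' down by the design beyond "irrelevant there"; N(0, sigma), matching the
#' noise genes, is used so that class structure exists at all.
#'
#' @param n_classes number of sample classes (default 3).
#' @param samples_per_class samples in each class (default 50).
#' @param relevant_per_class class-marker genes per class (default 2).
#' @param noise_fold ratio of irrelevant to relevant genes (default 100;
#'   the benchmark grid uses 0, 10, 50 and 100).
#' @param sigma standard deviation of all gene expression values.
#' @param class_mean in-class mean of the relevant genes (default 1).
#' @param seed optional RNG seed for reproducibility.
#'
#' @return object of class `sim_dataset`: list with `expression` (genes x
#'   samples matrix with gene/sample ids) and `labels` (factor of class
#'   labels named by sample id).
#' @export
simulate_class_data <- function(n_classes = 3L, samples_per_class = 50L,
                                relevant_per_class = 2L, noise_fold = 100L,
                                sigma = 0.3, class_mean = 1, seed = NULL) {
  n_classes <- as.integer(n_classes)
  samples_per_class <- as.integer(samples_per_class)
  relevant_per_class <- as.integer(relevant_per_class)
  noise_fold <- as.integer(noise_fold)
  if (any(is.na(c(n_classes, samples_per_class, relevant_per_class,
                  noise_fold))) ||
      n_classes < 1L || samples_per_class < 1L || relevant_per_class < 1L ||
      noise_fold < 0L)
    stop("invalid simulation specification: counts must be positive ",
         "(noise_fold may be 0)", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0)
    stop("`sigma` must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- n_classes * samples_per_class
  n_rel <- n_classes * relevant_per_class
  n_noise <- noise_fold * n_rel
  n <- n_rel + n_noise
  X <- matrix(stats::rnorm(n * m, mean = 0, sd = sigma), nrow = n, ncol = m)
  classes <- paste0("class", seq_len(n_classes))
  labels <- factor(rep(classes, each = samples_per_class), levels = classes)
  for (c in seq_len(n_classes)) {
    genes <- (c - 1L) * relevant_per_class + seq_len(relevant_per_class)
    X[genes, labels == classes[c]] <- X[genes, labels == classes[c]] +
      class_mean
  }
  gene_ids <- c(paste0(rep(classes, each = relevant_per_class), "_gene",
                       rep(seq_len(relevant_per_class), n_classes)),
                if (n_noise > 0L) paste0("noise_gene", seq_len(n_noise)))
  sample_ids <- paste0("s", seq_len(m))
  dimnames(X) <- list(gene_ids, sample_ids)
  names(labels) <- sample_ids
  structure(list(expression = X, labels = labels), class = "sim_dataset")
}

#' Simulate a completely random (null) expression data set
#'
#' Draws an i.i.d. genes x samples matrix with no sample structure at all,
#' as a negative control: any feature transform should leave clustering and
#' classification at chance level on such data.  Three distributions are
#' supported: standard normal, uniform on \[0, 1\], and discrete uniform on
#' \{-1, 0, 1\}.
#'
#' @param kind `"normal"`, `"uniform01"` or `"discrete3"`.
#' @param n_genes,n_samples matrix dimensions (default 150 x 150).
#' @param seed optional RNG seed.
#'
#' @return numeric genes x samples matrix with ids.
#' @export
simulate_null_data <- function(kind = c("normal", "uniform01", "discrete3"),
                               n_genes = 150L, n_samples = 150L, seed = NULL) {
  kind <- match.arg(kind)
  n_genes <- as.integer(n_genes)
  n_samples <- as.integer(n_samples)
  if (n_genes < 1L || n_samples < 1L)
    stop("dimensions must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- n_genes * n_samples
  vals <- switch(kind,
    normal    = stats::rnorm(n),
    uniform01 = stats::runif(n),
    discrete3 = sample(c(-1, 0, 1), n, replace = TRUE))
  X <- matrix(vals, nrow = n_genes, ncol = n_samples)
  dimnames(X) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(n_samples)))
  X
}

#' Canonical toy correlation-feature matrices
#'
#' Returns the three small first-order correlation matrices that exhibit the
#' characteristic behaviours of the iterated transform:
#' \describe{
#'   \item{toy 1}{3 samples; s3 weakly resembles s1 (entry 0.3).  Iteration
#'     drives corr(s3, s1) to +1 and corr(s3, s2) to -1: weak patterns are
#'     amplified.}
#'   \item{toy 2}{3 samples; s3 is orthogonal to s1 and s2 (entries 0).  The
#'     matrix is an exact fixed point of [iterate_features()]: balanced
#'     independence is preserved.}
#'   \item{toy 3}{4 samples in two unbalanced classes (s1 vs s2, s3), plus
#'     s4 orthogonal to all at order 1.  One iteration reveals weak
#'     similarity of s4 to s1 (about 0.174) which subsequent iterations
#'     drive to 1: structure hidden at order 1 surfaces at higher orders.}
#' }
#'
#' @param id toy data set number, 1, 2 or 3.
#' @return [corr_features][new_corr_features] matrix of order 1.
#' @export
toy_fixture <- function(id) {
  if (length(id) != 1L || !id %in% 1:3)
    stop("unknown toy data set: `id` must be 1, 2 or 3", call. = FALSE)
  M <- switch(as.integer(id),
    rbind(c(1, -1, 0.3),
          c(-1, 1, -0.3),
          c(0.3, -0.3, 1)),
    rbind(c(1, -1, 0),
          c(-1, 1, 0),
          c(0, 0, 1)),
    rbind(c(1, -1, -1, 0),
          c(-1, 1, 1, 0),
          c(-1, 1, 1, 0),
          c(0, 0, 0, 1)))
  ids <- paste0("s", seq_len(nrow(M)))
  dimnames(M) <- list(ids, ids)
  new_corr_features(M, order = 1L)
}

#' Simulate a batch-confounded class-structured data set
#'
#' Adds a laboratory-style batch effect to the design of
#' [simulate_class_data()]: samples of each class are split across
#' `n_batches` batches, and every batch contributes a gene-specific offset
#' drawn once per (gene, batch) from N(0, `batch_shift`) to all of its
#' samples.  Gene-specific offsets are what real inter-laboratory effects
#' look like through the lens of sample correlations: a shared per-gene
#' signature inflates the correlation of every same-batch pair.  (A shift
#' that is constant across genes would be invisible here, because the
#' Pearson correlation of two profiles is invariant to adding a constant to
#' either profile.)
#'
#' With the defaults the batch signature dominates the class signal at order
#' 1 -- samples cluster by laboratory, not by disease class -- which is the
#' regime the supervised adjustment of [ipcc_batch()] is designed for.
#'
#' @param n_classes,samples_per_class,relevant_per_class,noise_fold,sigma,class_mean,seed
#'   as in [simulate_class_data()] (defaults scaled down to 2 classes of 20
#'   samples with 10-fold noise).
#' @param n_batches number of batches (default 2).
#' @param batch_shift standard deviation of the per-gene batch offsets
#'   (default 0.8); 0 gives a data set identical to
#'   [simulate_class_data()] with the same seed.
#'
#' @return object of class `sim_dataset`: list with `expression`, `labels`
#'   and `batch` (factor of batch ids named by sample id).
#' @export
simulate_batch_confounded <- function(n_classes = 2L, n_batches = 2L,
                                      samples_per_class = 20L,
                                      relevant_per_class = 2L,
                                      noise_fold = 10L, class_mean = 1,
                                      batch_shift = 0.8, sigma = 0.3,
                                      seed = NULL) {
  n_batches <- as.integer(n_batches)
  if (is.na(n_batches) || n_batches < 2L)
    stop("`n_batches` must be >= 2", call. = FALSE)
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  if (!is.numeric(batch_shift) || batch_shift < 0)
    stop("`batch_shift` must be non-negative", call. = FALSE)
  base <- simulate_class_data(n_classes = n_classes,
                              samples_per_class = samples_per_class,
                              relevant_per_class = relevant_per_class,
                              noise_fold = noise_fold, sigma = sigma,
                              class_mean = class_mean, seed = seed)
  X <- base$expression
  n <- nrow(X)
  # contiguous batch blocks within each class, so classes are crossed with
  # batches rather than nested in them
  per_class <- rep(seq_len(n_batches),
                   each = ceiling(samples_per_class / n_batches),
                   length.out = samples_per_class)
  batch <- factor(paste0("batch", rep(per_class, n_classes)))
  names(batch) <- colnames(X)
  for (b in levels(batch)) {
    offsets <- stats::rnorm(n, mean = 0, sd = batch_shift)
    X[, batch == b] <- X[, batch == b] + offsets
  }
  structure(list(expression = X, labels = base$labels, batch = batch),
            class = "sim_dataset")
}
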