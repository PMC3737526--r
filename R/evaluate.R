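#' Repeated k-means clustering with random restarts
#'
#' Runs Lloyd's k-means `n_runs` times, each run initialized with `k`
#' distinct samples drawn uniformly at random, and returns every resulting
#' partition.  The spread of solutions across restarts -- k-means is a local
#' optimizer, and on high-dimensional expression data different restarts
#' routinely land in different optima -- is part of what the evaluation
#' measures, so no k-means++ style seeding is used.  Runs are reproducible:
#' run r uses RNG seed `seed + r - 1`.
#'
#' @param features numeric samples x features matrix (e.g. a
#'   correlation-feature matrix, or `t(X)` for raw genes x samples data).
#' @param k number of clusters (`2 <= k <= nrow(features)`).
#' @param n_runs number of random restarts (default 100).
#' @param seed base RNG seed; `NULL` leaves the RNG state alone.
#' @param iter_max Lloyd iteration cap per run (default 300).
#'
#' @return integer matrix of cluster assignments, `n_runs` x m; row r is the
#'   partition from run r.
#' @export
kmeans_runs <- function(features, k, n_runs = 100L, seed = NULL,
                        iter_max = 300L) {
  features <- as.matrix(features)
  m <- nrow(features)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (k > m)
    stop("`k` (", k, ") exceeds the number of samples (", m, ")",
         call. = FALSE)
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 1L)
    stop("`n_runs` must be >= 1", call. = FALSE)
  out <- matrix(NA_integer_, nrow = n_runs, ncol = m,
                dimnames = list(NULL, rownames(features)))
  for (r in seq_len(n_runs)) {
    if (!is.null(seed)) set.seed(seed + r - 1L)
    fit <- NULL
    attempts <- 0L
    # a draw of coincident initial centers, or a center losing all its
    # points mid-iteration, aborts stats::kmeans; redraw and retry
    while (is.null(fit) && attempts < 100L) {
      attempts <- attempts + 1L
      centers <- features[sample.int(m, k), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(features, centers = centers,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
    }
    if (is.null(fit))
      stop("k-means failed to find a valid initialization in run ", r,
           call. = FALSE)
    out[r, ] <- fit$cluster
  }
  out
}

#' Matched clustering accuracy
#'
#' Fraction of samples on which a predicted partition agrees with the true
#' class labels under the best one-to-one mapping between predicted cluster
#' ids and class ids -- the maximum-assignment score on the contingency
#' table.  The optimum is found by exhaustive search over injective
#' mappings, exact for the small cluster counts used here (up to 8).
#'
#' @param predicted vector of predicted cluster ids.
#' @param truth vector of true class labels, same samples in the same order
#'   (named vectors are matched by name).
#'
#' @return accuracy in \[0, 1\].
#' @examples
#' match_accuracy(c(2, 2, 1, 1), c("a", "a", "b", "b"))  # 1: renaming only
#' @export
match_accuracy <- function(predicted, truth) {
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    if (!setequal(names(predicted), names(truth)))
      stop("`predicted` and `truth` cover different samples", call. = FALSE)
    truth <- truth[names(predicted)]
  }
  if (length(predicted) != length(truth))
    stop("`predicted` and `truth` have different lengths", call. = FALSE)
  ct <- unclass(table(predicted, truth))
  r <- nrow(ct)
  c <- ncol(ct)
  if (max(r, c) > 8L)
    stop("exhaustive cluster matching supports at most 8 clusters",
         call. = FALSE)
  # pad to square so the assignment is a permutation
  if (r < c) ct <- rbind(ct, matrix(0L, c - r, c))
  if (c < r) ct <- cbind(ct, matrix(0L, r, r - c))
  best_assignment_score(ct) / length(predicted)
}

# maximum trace over column permutations of a square count matrix,
# by depth-first enumeration (n <= 8)
best_assignment_score <- function(ct) {
  n <- nrow(ct)
  best <- 0
  recurse <- function(row, used, score) {
    if (row > n) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    for (col in seq_len(n)) {
      if (!used[col]) {
        used[col] <- TRUE
        recurse(row + 1L, used, score + ct[row, col])
        used[col] <- FALSE
      }
    }
  }
  recurse(1L, logical(n), 0)
  best
}

#' Leave-one-out Gaussian naive Bayes accuracy
#'
#' For every sample, fits a Gaussian naive Bayes classifier (per-class,
#' per-feature normal densities with maximum-likelihood variance plus a
#' small smoothing term; empirical class priors) on the remaining m - 1
#' samples and predicts the held-out sample by maximum posterior.  The
#' variance smoothing term is `eps_frac` times the largest per-feature
#' variance of the training set, which keeps the log-likelihood finite when
#' a class happens to be constant in some feature.
#'
#' @param features numeric samples x features matrix.
#' @param labels per-sample class labels (named vectors aligned to
#'   `rownames(features)`); every class needs at least 2 samples.
#' @param eps_frac variance smoothing fraction (default 1e-9).
#'
#' @return list with `accuracy` (fraction of held-out samples predicted
#'   correctly) and `predicted` (character vector of per-sample
#'   predictions).
#' @export
loocv_gaussian_nb <- function(features, labels, eps_frac = 1e-9) {
  X <- as.matrix(features)
  if (!is.numeric(X) || anyNA(X))
    stop("`features` must be a numeric matrix without missing values",
         call. = FALSE)
  m <- nrow(X)
  f <- align_labels(labels, rownames(X), n = m, what = "class label")
  counts <- table(f)
  if (nlevels(f) < 2L)
    stop("at least 2 classes are required", call. = FALSE)
  if (any(counts < 2L))
    stop("degenerate class(es) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  lev <- levels(f)
  k <- length(lev)
  S <- rowsum(X, f)      # class sums,        k x p
  S2 <- rowsum(X^2, f)   # class square sums, k x p
  n_c <- as.vector(counts)
  tot <- colSums(X)
  tot2 <- colSums(X^2)
  predicted <- character(m)
  for (i in seq_len(m)) {
    ci <- as.integer(f[i])
    xi <- X[i, ]
    ntr <- n_c
    ntr[ci] <- ntr[ci] - 1L
    Si <- S
    S2i <- S2
    Si[ci, ] <- Si[ci, ] - xi
    S2i[ci, ] <- S2i[ci, ] - xi^2
    mu <- Si / ntr
    v <- pmax(S2i / ntr - mu^2, 0)
    # smoothing from the training set's overall per-feature variance
    t1 <- (tot - xi) / (m - 1L)
    vall <- (tot2 - xi^2) / (m - 1L) - t1^2
    v <- v + eps_frac * max(vall)
    d2 <- (matrix(xi, nrow = k, ncol = ncol(X), byrow = TRUE) - mu)^2
    loglik <- -0.5 * rowSums(log(2 * pi * v) + d2 / v)
    logpost <- loglik + log(ntr / (m - 1L))
    predicted[i] <- lev[which.max(logpost)]
  }
  names(predicted) <- rownames(X)
  list(accuracy = mean(predicted == as.character(f)), predicted = predicted)
}

#' Intra- and inter-class similarity of correlation features
#'
#' Averages the off-diagonal entries of a sample-similarity matrix over
#' unordered same-class pairs (`intra_mean`) and different-class pairs
#' (`inter_mean`); their difference is the separation statistic.  Self-pairs
#' (the diagonal) are excluded -- including the constant-1 diagonal would
#' inflate `intra_mean` by construction.  A perfectly separated two-block
#' matrix (within +1, between -1) attains the maximal difference of 2.
#'
#' @param C square sample-similarity matrix (typically
#'   [corr_features][new_corr_features]).
#' @param labels per-sample class labels; at least 2 classes.
#'
#' @return list with `intra_mean`, `inter_mean` and `difference`
#'   (`intra_mean - inter_mean`).
#' @export
intra_inter_similarity <- function(C, labels) {
  M <- unclass_matrix(C)
  if (nrow(M) != ncol(M)) stop("`C` must be square", call. = FALSE)
  f <- align_labels(labels, rownames(M), n = nrow(M), what = "class label")
  if (nlevels(f) < 2L)
    stop("inter-class similarity is undefined with a single class",
         call. = FALSE)
  same <- outer(as.integer(f), as.integer(f), "==")
  ut <- upper.tri(M)
  intra <- mean(M[ut & same])
  inter <- mean(M[ut & !same])
  list(intra_mean = intra, inter_mean = inter, difference = intra - inter)
}

#' Compare two accuracy distributions by t-test
#'
#' Two-sided Welch t-test between two vectors of per-run (or per-data-set)
#' accuracies, used to ask whether a feature transform changed an
#' algorithm's accuracy distribution.  Degenerate constant inputs, where the
#' t statistic is formally 0/0, are resolved by convention: equal constant
#' vectors give t = 0, p = 1; unequal constant vectors give t = +/-Inf,
#' p = 0.
#'
#' @param acc_a,acc_b numeric vectors of accuracies, each of length >= 2.
#' @return list with `statistic`, `p.value` and `method`.
#' @export
accuracy_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) < 2L || length(acc_b) < 2L)
    stop("need at least 2 accuracy values per group", call. = FALSE)
  if (stats::sd(acc_a) == 0 && stats::sd(acc_b) == 0) {
    delta <- mean(acc_a) - mean(acc_b)
    if (delta == 0)
      return(list(statistic = 0, p.value = 1,
                  method = "Welch two-sample t-test (degenerate)"))
    return(list(statistic = sign(delta) * Inf, p.value = 0,
                method = "Welch two-sample t-test (degenerate)"))
  }
  ht <- stats::t.test(acc_a, acc_b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = ht$method)
}
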