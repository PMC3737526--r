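#' First-order sample correlation features
#'
#' Computes the m x m matrix of pairwise correlations between the expression
#' profiles of all samples.  Entry (i, j) is the Pearson correlation
#' coefficient between the gene-expression vectors of samples i and j
#' (columns of `X`); with `kernel = "spearman"` the rank correlation is used
#' instead (exploratory only -- the iterated transform is designed around
#' the Pearson kernel).
#'
#' A sample whose profile is constant across all genes has zero variance and
#' an undefined correlation with every other sample.  By default this is an
#' error; `on_constant = "drop"` removes the offending samples with a
#' warning instead.
#'
#' @param X numeric matrix, genes in rows and samples in columns.  Column
#'   names, when present, become the sample ids of the result.
#' @param kernel correlation kernel, `"pearson"` (default) or `"spearman"`.
#' @param on_constant what to do with zero-variance sample profiles:
#'   `"error"` (default) or `"drop"`.
#'
#' @return a [corr_features][new_corr_features] matrix of order 1.
#' @examples
#' X <- cbind(s1 = c(1, 2, 3, 4), s2 = c(1, 3, 2, 4))
#' sample_correlation(X)["s1", "s2"]  # 0.8
#' @export
sample_correlation <- function(X, kernel = c("pearson", "spearman"),
                               on_constant = c("error", "drop")) {
  kernel <- match.arg(kernel)
  on_constant <- match.arg(on_constant)
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("expression values must be numeric", call. = FALSE)
  if (anyNA(X)) stop("expression matrix contains missing values", call. = FALSE)
  if (nrow(X) < 2L)
    stop("at least 2 genes are required to correlate sample profiles",
         call. = FALSE)
  if (ncol(X) < 2L) stop("at least 2 samples are required", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    offenders <- colnames(X)[sds == 0] %||% which(sds == 0)
    if (on_constant == "error")
      stop("zero-variance sample profile(s): ",
           paste(offenders, collapse = ", "),
           " (use on_constant = \"drop\" to discard them)", call. = FALSE)
    warning("dropping zero-variance sample profile(s): ",
            paste(offenders, collapse = ", "), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) < 2L)
      stop("fewer than 2 samples remain after dropping constant profiles",
           call. = FALSE)
  }
  C <- stats::cor(X, method = kernel)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  new_corr_features(C, order = 1L)
}

#' Iterate the correlation-of-rows map
#'
#' One iteration replaces a correlation-feature matrix `C` of order t by the
#' matrix of pairwise correlations between its rows, yielding order t + 1.
#' Off-diagonal entries typically converge rapidly to +1 or -1, revealing a
#' two-block (or, for orthogonal feature vectors, invariant) structure; see
#' [toy_fixture()] for the canonical small examples.
#'
#' A 2 x 2 input is rejected: its rows are length-2 vectors of the form
#' (1, r) and (r, 1), whose pairwise correlation is always +/-1 regardless
#' of the data, so iteration is vacuous.
#'
#' @param C square symmetric numeric matrix (usually a
#'   [corr_features][new_corr_features] object; a plain matrix, e.g. a
#'   batch-adjusted order-1 matrix, is also accepted).
#' @param steps number of iterations to apply (positive integer).
#' @param kernel correlation kernel, as in [sample_correlation()].
#'
#' @return a [corr_features][new_corr_features] matrix whose order is the
#'   input order (taken as 1 when `C` carries none) plus `steps`.
#' @export
iterate_features <- function(C, steps = 1L, kernel = c("pearson", "spearman")) {
  kernel <- match.arg(kernel)
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L)
    stop("`steps` must be a positive integer", call. = FALSE)
  M <- unclass_matrix(C)
  if (nrow(M) != ncol(M)) stop("`C` must be square", call. = FALSE)
  if (nrow(M) == 2L)
    stop("iteration is degenerate for m = 2 samples: every pair of ",
         "length-2 rows is perfectly correlated", call. = FALSE)
  if (max(abs(M - t(M))) > 1e-8)
    stop("`C` must be symmetric", call. = FALSE)
  order0 <- feature_order(C)
  if (is.na(order0)) order0 <- 1L
  for (s in seq_len(steps)) {
    rsd <- apply(M, 1L, stats::sd)
    if (any(rsd == 0)) {
      offenders <- rownames(M)[rsd == 0] %||% which(rsd == 0)
      stop("constant row(s) in correlation-feature matrix: ",
           paste(offenders, collapse = ", "),
           "; the correlation-of-rows map is undefined", call. = FALSE)
    }
    M <- stats::cor(t(M), method = kernel)
    M <- (M + t(M)) / 2
    diag(M) <- 1
  }
  new_corr_features(M, order = order0 + steps)
}

# strip corr_features attributes, keep dim/dimnames
unclass_matrix <- function(C) {
  M <- as.matrix(C)
  attributes(M) <- attributes(M)[c("dim", "dimnames")]
  M
}

#' Iterative Pearson correlation features (iPcc)
#'
#' Runs the full transform: order-1 sample correlations via
#' [sample_correlation()], then repeated application of the
#' correlation-of-rows map via [iterate_features()] up to `max_order`,
#' stopping early once the maximum absolute change between successive
#' matrices falls below `tol`.  The paper-style usage is a small fixed
#' `max_order` (orders 1-5 are the informative range on real data; far
#' beyond that the entries saturate at +/-1); `tol` is a safety stop, not
#' the primary control.
#'
#' @param X numeric genes x samples matrix.
#' @param max_order highest order to compute (>= 1).
#' @param tol early-stopping threshold on the maximum absolute change
#'   between successive matrices (> 0, default 1e-9).
#' @param kernel,on_constant passed to [sample_correlation()].
#' @param eps_pm1 tolerance used by the convergence trace when counting
#'   off-diagonal entries that have reached +/-1.
#'
#' @return an object of class `ipcc_result`: a list with
#'   \describe{
#'     \item{features}{list of [corr_features][new_corr_features] matrices,
#'       orders 1..T.}
#'     \item{trace}{data frame with one row per computed order: `order`,
#'       `max_delta` (maximum absolute change from the previous order; `NA`
#'       for order 1) and `frac_pm1` (fraction of off-diagonal entries
#'       within `eps_pm1` of +/-1).}
#'   }
#' @examples
#' d <- simulate_class_data(noise_fold = 10, sigma = 0.2, seed = 1,
#'                          samples_per_class = 10)
#' res <- ipcc(d$expression, max_order = 3)
#' res$trace
#' @export
ipcc <- function(X, max_order = 5L, tol = 1e-9,
                 kernel = c("pearson", "spearman"),
                 on_constant = c("error", "drop"), eps_pm1 = 1e-6) {
  kernel <- match.arg(kernel)
  max_order <- as.integer(max_order)
  if (is.na(max_order) || max_order < 1L)
    stop("`max_order` must be >= 1", call. = FALSE)
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  C1 <- sample_correlation(X, kernel = kernel, on_constant = on_constant)
  res <- iterate_with_trace(C1, max_order = max_order, tol = tol,
                            kernel = kernel, eps_pm1 = eps_pm1)
  res$adjusted <- FALSE
  class(res) <- "ipcc_result"
  res
}

# shared by ipcc() and ipcc_batch(): grow orders 2..max_order from `first`,
# recording the convergence trace and stopping once max_delta < tol
iterate_with_trace <- function(first, max_order, tol, kernel, eps_pm1) {
  features <- vector("list", max_order)
  features[[1L]] <- first
  off <- !diag(nrow(first))
  frac_pm1 <- function(M) mean(abs(abs(M[off]) - 1) <= eps_pm1)
  max_delta <- NA_real_
  fracs <- frac_pm1(unclass_matrix(first))
  t <- 1L
  while (t < max_order) {
    nxt <- iterate_features(features[[t]], steps = 1L, kernel = kernel)
    t <- t + 1L
    features[[t]] <- nxt
    delta <- max(abs(unclass_matrix(nxt) - unclass_matrix(features[[t - 1L]])))
    max_delta <- c(max_delta, delta)
    fracs <- c(fracs, frac_pm1(unclass_matrix(nxt)))
    if (delta < tol) break
  }
  features <- features[seq_len(t)]
  orders <- vapply(features, feature_order, 1L)
  names(features) <- paste0("order", orders)
  list(features = features,
       trace = data.frame(order = orders, max_delta = max_delta,
                          frac_pm1 = fracs))
}
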