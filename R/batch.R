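#' Batch-indicator matrix
#'
#' Encodes known batch membership (e.g. which laboratory profiled each
#' sample) as an m x m matrix `B` with `B[i, j] = within` when samples i and
#' j belong to the same batch and `B[i, j] = between` otherwise.  Diagonal
#' entries are within-batch by definition.  With the defaults
#' (`within = -1`, `between = +1`) adding `lambda * B` to a correlation
#' matrix penalizes same-batch similarity and rewards cross-batch
#' similarity.
#'
#' @param batch vector of batch ids, one per sample; a named vector is
#'   reordered to `sample_ids`.
#' @param sample_ids sample ids the design must cover (default: the names of
#'   `batch`).  A sample without a batch id is an error.
#' @param within,between values for same-batch / different-batch pairs.
#'
#' @return symmetric numeric m x m matrix with sample ids as dimnames.
#' @export
batch_indicator <- function(batch, sample_ids = names(batch),
                            within = -1, between = 1) {
  if (!is.null(sample_ids)) {
    if (is.null(names(batch))) {
      if (length(batch) != length(sample_ids))
        stop("`batch` length does not match `sample_ids`", call. = FALSE)
      names(batch) <- sample_ids
    } else {
      missing <- setdiff(sample_ids, names(batch))
      if (length(missing))
        stop("sample(s) without a batch label: ",
             paste(missing, collapse = ", "), call. = FALSE)
      batch <- batch[sample_ids]
    }
  }
  b <- as.character(batch)
  B <- ifelse(outer(b, b, "=="), within, between)
  dimnames(B) <- list(names(batch), names(batch))
  B
}

#' Adjust first-order correlation features for batch effects
#'
#' Additively updates the first-order correlation matrix with a weighted
#' batch-indicator matrix: `C1' = C1 + lambda * B`.  The result is not
#' clipped back to \[-1, 1\] and the diagonal is left as computed: the
#' subsequent correlation-of-rows iterations are insensitive to both, and
#' forcing them would be an undocumented extra transformation.
#'
#' Because `B` with the default coding equals `-u %*% t(u)` for the signed
#' batch vector `u`, the update subtracts a rank-one batch component of
#' amplitude `lambda` from `C1`.  Undershooting the true batch amplitude is
#' safer than overshooting: iteration amplifies whatever residual structure
#' dominates, including an over-corrected (sign-reversed) batch pattern.
#'
#' @param C1 order-1 [corr_features][new_corr_features] matrix (or plain
#'   m x m matrix).
#' @param B batch-indicator matrix from [batch_indicator()], same shape.
#' @param lambda non-negative adjustment weight (default 0.5).
#'
#' @return plain numeric m x m matrix with an `order` attribute of 1;
#'   entries may lie outside \[-1, 1\].
#' @export
adjust_first_order <- function(C1, B, lambda = 0.5) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("`lambda` must be a single non-negative number", call. = FALSE)
  M <- unclass_matrix(C1)
  B <- as.matrix(B)
  if (!all(dim(M) == dim(B)))
    stop("`C1` and `B` have different shapes", call. = FALSE)
  A <- M + lambda * B
  attr(A, "order") <- 1L
  attr(A, "adjusted") <- TRUE
  A
}

#' Batch-adjusted iPcc
#'
#' Computes first-order sample correlations, applies the additive
#' batch-effect adjustment of [adjust_first_order()], then iterates the
#' correlation-of-rows map on the adjusted matrix.  With `lambda = 0` this
#' reduces exactly to [ipcc()].
#'
#' @param X numeric genes x samples matrix.
#' @param batch per-sample batch ids; a named vector is aligned to
#'   `colnames(X)`.
#' @param max_order highest order to compute (default 7, the informative
#'   range on batch-confounded data).
#' @param lambda,within,between adjustment parameters, see
#'   [adjust_first_order()] and [batch_indicator()].
#' @param tol,kernel,on_constant,eps_pm1 as in [ipcc()].
#'
#' @return an `ipcc_result` (see [ipcc()]); `features[[1]]` is the adjusted
#'   order-1 matrix (a plain matrix, since the adjustment may push entries
#'   outside \[-1, 1\]), higher orders are
#'   [corr_features][new_corr_features].
#' @export
ipcc_batch <- function(X, batch, max_order = 7L, lambda = 0.5,
                       within = -1, between = 1, tol = 1e-9,
                       kernel = c("pearson", "spearman"),
                       on_constant = c("error", "drop"), eps_pm1 = 1e-6) {
  kernel <- match.arg(kernel)
  max_order <- as.integer(max_order)
  if (is.na(max_order) || max_order < 1L)
    stop("`max_order` must be >= 1", call. = FALSE)
  C1 <- sample_correlation(X, kernel = kernel, on_constant = on_constant)
  B <- batch_indicator(batch, sample_ids = colnames(C1),
                       within = within, between = between)
  A <- adjust_first_order(C1, B, lambda = lambda)
  res <- iterate_with_trace(A, max_order = max_order, tol = tol,
                            kernel = kernel, eps_pm1 = eps_pm1)
  res$adjusted <- TRUE
  class(res) <- "ipcc_result"
  res
}
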