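#' Correlation-feature matrices
#'
#' A `corr_features` object is an m x m symmetric matrix whose entry (i, j)
#' is the Pearson (or Spearman) correlation between the feature vectors of
#' samples i and j, carrying the order `t` of the transform as an attribute.
#' Order 1 correlates the raw expression profiles; order t correlates the
#' rows of the order t-1 matrix.  Order 0 conventionally denotes the raw
#' features and is never stored in this class.
#'
#' Invariants enforced at construction: symmetry and unit diagonal within
#' 1e-12, and all entries in \[-1, 1\] (up to the same rounding slack, which
#' is clipped away).
#'
#' @param values numeric m x m matrix of pairwise correlations.
#' @param order non-negative integer, the number of times the
#'   correlation-of-rows map has been applied.
#' @param validate check the class invariants (default `TRUE`).
#'
#' @return `values` with class `corr_features` and an `order` attribute.
#' @seealso [sample_correlation()], [iterate_features()], [ipcc()]
#' @export
new_corr_features <- function(values, order, validate = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) != ncol(values))
    stop("correlation-feature matrices are square", call. = FALSE)
  order <- as.integer(order)
  if (is.na(order) || order < 0L)
    stop("`order` must be a non-negative integer", call. = FALSE)
  values <- clip_unit(values)
  attr(values, "order") <- order
  class(values) <- c("corr_features", class(values))
  if (validate) validate_corr_features(values)
  values
}

validate_corr_features <- function(C, tol = 1e-12) {
  if (max(abs(C - t(C))) > tol)
    stop("correlation-feature matrix is not symmetric", call. = FALSE)
  if (max(abs(diag(C) - 1)) > tol)
    stop("correlation-feature matrix diagonal differs from 1", call. = FALSE)
  if (min(C) < -1 - tol || max(C) > 1 + tol)
    stop("correlation-feature entries outside [-1, 1]", call. = FALSE)
  invisible(C)
}

# absorb floating-point excursions beyond +/-1; anything larger than `slack`
# outside the unit interval indicates a real defect and is reported upstream
clip_unit <- function(x, slack = 1e-8) {
  bad <- abs(x) > 1 + slack
  if (any(bad, na.rm = TRUE))
    stop("correlation entries exceed 1 by more than rounding error",
         call. = FALSE)
  pmin(pmax(x, -1), 1)
}

#' Order of a correlation-feature matrix
#'
#' @param C a [corr_features][new_corr_features] object (or any matrix with
#'   an `order` attribute).
#' @return integer order, or `NA` if the matrix carries none.
#' @export
feature_order <- function(C) {
  as.integer(attr(C, "order") %||% NA_integer_)
}

#' @export
print.corr_features <- function(x, ...) {
  cat(sprintf("corr_features: %d samples, order %d\n", nrow(x),
              feature_order(x)))
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(head(y[, seq_len(min(ncol(y), 6L)), drop = FALSE], 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... (%d rows total)\n", nrow(x)))
  invisible(x)
}

#' @export
print.ipcc_result <- function(x, ...) {
  cat(sprintf("ipcc_result: %d samples, orders %s%s\n",
              nrow(x$features[[1]]),
              paste(range(vapply(x$features, feature_order, 1L)),
                    collapse = "-"),
              if (isTRUE(x$adjusted)) " (batch-adjusted order 1)" else ""))
  print(x$trace, row.names = FALSE)
  invisible(x)
}
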