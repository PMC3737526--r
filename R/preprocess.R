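#' Floor/ceiling, filter and log10-transform an expression matrix
#'
#' The standard microarray intensity preprocessing chain: values are clamped
#' to `[floor, ceiling]`; genes are kept only if, across samples after
#' clamping, `max/min >= min_ratio` and `max - min >= min_diff`; the
#' surviving values are log10-transformed.  The defaults (100, 16000, 5,
#' 500) are the conventional constants for two-colour-era leukemia
#' intensity data; all four are tunable.
#'
#' @param X numeric genes x samples matrix of positive intensities.
#' @param floor,ceiling clamping bounds (`0 < floor < ceiling`).
#' @param min_ratio,min_diff variation filters on the clamped values.
#'
#' @return filtered, log10-transformed genes x samples matrix.
#' @export
preprocess_expression <- function(X, floor = 100, ceiling = 16000,
                                  min_ratio = 5, min_diff = 500) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X))
    stop("`X` must be a numeric matrix without missing values", call. = FALSE)
  if (floor <= 0 || floor >= ceiling)
    stop("need 0 < floor < ceiling", call. = FALSE)
  Xc <- pmin(pmax(X, floor), ceiling)
  mx <- apply(Xc, 1L, max)
  mn <- apply(Xc, 1L, min)
  keep <- (mx / mn >= min_ratio) & (mx - mn >= min_diff)
  if (!any(keep))
    stop("no genes pass the variation filters", call. = FALSE)
  log10(Xc[keep, , drop = FALSE])
}

#' Per-gene one-way ANOVA F statistics
#'
#' For each gene (row), the one-way ANOVA F statistic of its expression
#' across the sample classes: between-class mean square over within-class
#' mean square.  A gene with zero within-class variance but non-zero
#' between-class variance (a perfect separator) gets `Inf`; a gene constant
#' across all samples gets 0.
#'
#' @param X numeric genes x samples matrix.
#' @param labels per-sample class labels (a named vector is aligned to
#'   `colnames(X)`); at least 2 classes with at least 2 samples each.
#'
#' @return numeric vector of F statistics, one per gene.
#' @export
f_statistics <- function(X, labels) {
  X <- as.matrix(X)
  f <- align_labels(labels, colnames(X), n = ncol(X))
  if (nlevels(f) < 2L)
    stop("at least 2 classes are required", call. = FALSE)
  counts <- table(f)
  if (any(counts < 2L))
    stop("degenerate class(es) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  m <- ncol(X)
  k <- nlevels(f)
  n_c <- as.numeric(counts)
  group_sum <- t(rowsum(t(X), f))              # genes x k
  tot <- rowSums(X)
  sst <- rowSums(X^2) - tot^2 / m
  ssb <- rowSums(sweep(group_sum^2, 2L, n_c, "/")) - tot^2 / m
  ssw <- sst - ssb
  # guard against tiny negative values from cancellation
  ssb <- pmax(ssb, 0)
  ssw <- pmax(ssw, 0)
  Fstat <- (ssb / (k - 1)) / (ssw / (m - k))
  # conventions for degenerate genes: constant -> 0, perfect separator -> Inf
  eps <- 1e-12 * pmax(sst, 1)
  Fstat[ssw <= eps & ssb > eps] <- Inf
  Fstat[sst <= eps] <- 0
  Fstat[is.nan(Fstat)] <- 0
  unname(Fstat)
}

#' Select the top-k genes by F-test
#'
#' Ranks genes by the one-way ANOVA F statistic of [f_statistics()]
#' (descending, ties broken by input order) and keeps the `top_k` best --
#' the standard supervised filter for building an informative-gene subset
#' before clustering or classification.
#'
#' @inheritParams f_statistics
#' @param top_k number of genes to keep (`<= nrow(X)`).
#'
#' @return the `top_k`-row submatrix of `X`, in rank order, with the F
#'   statistics attached as attribute `"f_statistic"`.
#' @export
f_test_select <- function(X, labels, top_k) {
  X <- as.matrix(X)
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1L || top_k > nrow(X))
    stop("`top_k` must be between 1 and nrow(X)", call. = FALSE)
  Fstat <- f_statistics(X, labels)
  ord <- order(-Fstat, seq_along(Fstat))[seq_len(top_k)]
  out <- X[ord, , drop = FALSE]
  attr(out, "f_statistic") <- Fstat[ord]
  out
}
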