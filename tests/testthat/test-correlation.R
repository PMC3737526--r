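test_that("order-1 correlations match the hand-computed definition", {
  X <- cbind(s1 = c(1, 2, 3, 4), s2 = c(1, 3, 2, 4))
  C <- sample_correlation(X)
  expect_equal(C["s1", "s2"], 0.8, tolerance = 1e-12)
  expect_identical(feature_order(C), 1L)

  # identical profiles are perfectly similar, negated profiles opposite
  Y <- cbind(a = c(1, 5, 2), b = c(1, 5, 2), c = -c(1, 5, 2))
  Cy <- sample_correlation(Y)
  expect_equal(Cy["a", "b"], 1, tolerance = 1e-12)
  expect_equal(Cy["a", "c"], -1, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected or dropped as requested", {
  X <- cbind(s1 = c(1, 2, 3), s2 = c(3, 3, 3), s3 = c(2, 1, 3))
  expect_error(sample_correlation(X), "zero-variance.*s2")
  expect_warning(C <- sample_correlation(X, on_constant = "drop"),
                 "dropping")
  expect_identical(colnames(C), c("s1", "s3"))

  expect_error(sample_correlation(matrix(1:4, nrow = 1)), "2 genes")
  expect_error(sample_correlation(matrix(1:4, ncol = 1)), "2 samples")
  # m = 2 gives a valid order-1 matrix but cannot be iterated
  C2 <- sample_correlation(cbind(a = c(1, 2, 4), b = c(2, 1, 5)))
  expect_error(iterate_features(C2), "degenerate")
})

test_that("iterating one step reproduces the closed-form toy-1 map", {
  for (x in c(0.1, 0.3, 0.7)) {
    C <- new_corr_features(rbind(c(1, -1, x), c(-1, 1, -x), c(x, -x, 1)),
                           order = 1L)
    C2 <- iterate_features(C)
    expect_equal(C2[1, 3], toy1_step(x), tolerance = 1e-12)
    # and the closed form itself agrees with the naive definition
    expect_equal(toy1_step(x), naive_pearson_matrix(unclass(C))[1, 3],
                 tolerance = 1e-12)
    expect_identical(feature_order(C2), 2L)
  }
})

test_that("the orthogonal toy-2 matrix is an exact fixed point", {
  C <- toy_fixture(2)
  C2 <- iterate_features(C, steps = 1)
  expect_lt(max(abs(unclass(C2)[1:3, 1:3] - unclass(C)[1:3, 1:3])), 1e-12)
  C5 <- iterate_features(C, steps = 4)
  expect_lt(max(abs(unclass(C5)[1:3, 1:3] - unclass(C)[1:3, 1:3])), 1e-12)
})

test_that("toy-1 entries converge to +/-1 and toy-3 absorbs s4 into s1", {
  C <- iterate_features(toy_fixture(1), steps = 30)
  expect_equal(C[3, 1], 1, tolerance = 1e-6)
  expect_equal(C[3, 2], -1, tolerance = 1e-6)
  C5 <- iterate_features(toy_fixture(1), steps = 4)  # order 5
  off <- abs(unclass(C5))[upper.tri(C5)]
  expect_true(all(off >= 0.99))

  D <- iterate_features(toy_fixture(3), steps = 30)
  expect_equal(D[4, 1], 1, tolerance = 1e-6)
})

test_that("the scalar toy-1 map increases monotonically to 1", {
  for (x0 in c(0.01, 0.1, 0.5, 0.9)) {
    x <- x0
    reached <- FALSE
    for (i in 1:20) {
      nxt <- toy1_step(x)
      expect_gt(nxt, x)
      x <- nxt
      if (x >= 1 - 1e-6) {
        reached <- TRUE
        break
      }
    }
    expect_true(reached)
  }
})

test_that("ipcc composes order 1 with iteration and traces convergence", {
  X <- random_expression(25, 12, seed = 41)
  res <- ipcc(X, max_order = 4)
  expect_identical(
    unclass_matrix(res$features[[1]]),
    unclass_matrix(sample_correlation(X)))
  expect_identical(
    unclass_matrix(res$features[[3]]),
    unclass_matrix(iterate_features(sample_correlation(X), steps = 2)))
  expect_identical(res$trace$order, 1:4)
  expect_true(is.na(res$trace$max_delta[1]))
  expect_true(all(res$trace$max_delta[-1] >= 0))

  # max_order = 1 is exactly the first-order matrix
  res1 <- ipcc(X, max_order = 1)
  expect_length(res1$features, 1L)

  # a fixed-point order-1 matrix stops the iteration with zero deltas:
  # these three profiles have pairwise correlations (-1, 0, 0)
  Xfix <- cbind(s1 = c(1, 2, 3), s2 = c(3, 2, 1), s3 = c(1, 3, 1))
  resfix <- ipcc(Xfix, max_order = 5)
  expect_lt(max(abs(unclass_matrix(resfix$features[[1]]) - toy_fixture(2))),
            1e-12)
  expect_length(resfix$features, 2L)  # stopped at the first zero delta
  expect_equal(resfix$trace$max_delta[2], 0, tolerance = 1e-12)
})

test_that("every order keeps symmetry, unit diagonal and the [-1,1] range", {
  for (seed in 1:3) {
    X <- random_expression(15, 10, seed = seed)
    res <- ipcc(X, max_order = 4)
    for (C in res$features) {
      M <- unclass_matrix(C)
      expect_lt(max(abs(M - t(M))), 1e-12)
      expect_lt(max(abs(diag(M) - 1)), 1e-12)
      expect_true(all(M >= -1 & M <= 1))
    }
  }
})

test_that("features are permutation-equivariant in the samples", {
  X <- random_expression(20, 8, seed = 7)
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  for (ord in c(1, 3)) {
    A <- unclass_matrix(ipcc(X, max_order = ord)$features[[ord]])
    B <- unclass_matrix(ipcc(X[, perm], max_order = ord)$features[[ord]])
    expect_identical(B, A[perm, perm])
  }
})

test_that("per-sample positive affine rescaling leaves features unchanged", {
  X <- random_expression(20, 9, seed = 11)
  Y <- X
  set.seed(12)
  for (j in seq_len(ncol(Y)))
    Y[, j] <- runif(1, 0.5, 3) * Y[, j] + runif(1, -2, 2)
  A <- unclass_matrix(ipcc(X, max_order = 3)$features[[3]])
  B <- unclass_matrix(ipcc(Y, max_order = 3)$features[[3]])
  expect_lt(max(abs(A - B)), 1e-12)
})

test_that("the vectorized transform matches the naive per-pair loop", {
  X <- random_expression(20, 30, seed = 13)
  C1 <- unclass_matrix(sample_correlation(X))
  expect_lt(max(abs(C1 - naive_pearson_matrix(t(X)))), 1e-12)
  C2 <- unclass_matrix(iterate_features(sample_correlation(X)))
  expect_lt(max(abs(C2 - naive_pearson_matrix(C1))), 1e-12)
})

test_that("the spearman kernel is rank-invariant and self-consistent", {
  X <- random_expression(12, 6, seed = 19)
  # strictly monotone per-sample transforms leave rank correlations alone
  Y <- exp(X)
  A <- unclass_matrix(sample_correlation(X, kernel = "spearman"))
  B <- unclass_matrix(sample_correlation(Y, kernel = "spearman"))
  expect_lt(max(abs(A - B)), 1e-12)
  expect_lt(max(abs(diag(A) - 1)), 1e-12)
  expect_error(sample_correlation(X, kernel = "kendall"))
  # the pearson kernel, not spearman, is what drives toy-1 to +/-1
  Cp <- iterate_features(toy_fixture(1), steps = 10, kernel = "pearson")
  expect_equal(Cp[3, 1], 1, tolerance = 1e-6)
})
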