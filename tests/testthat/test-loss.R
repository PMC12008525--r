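test_that("row softmax is stable and row-stochastic", {
  expect_equal(row_softmax(matrix(0, 5, 5)), matrix(0.2, 5, 5))
  P <- row_softmax(rbind(c(1000, 0, 0), c(0, 0, 0)))
  expect_true(all(is.finite(P)))
  expect_equal(P[1, ], c(1, 0, 0), tolerance = 1e-12)
  set.seed(31)
  for (k in 1:20) {
    P <- row_softmax(matrix(rnorm(64, sd = 10), 8, 8))
    expect_equal(rowSums(P), rep(1, 8), tolerance = 1e-9)
    expect_true(all(P >= 0 & P <= 1))
  }
  expect_error(row_softmax(matrix(c(1, Inf, 0, 0), 2, 2)), "finite")
})

test_that("weighted cross-entropy matches the scalar-loop oracle", {
  Sh <- modify_label(pairs_to_matrix(pair_map(5, rbind(c(1, 5)))))
  Pr <- matrix(0.2, 5, 5)
  expect_equal(weighted_cross_entropy(Pr, Sh), 4 / 5 * log(5), tolerance = 1e-9)
  expect_equal(weighted_cross_entropy(Pr, Sh), ref_weighted_ce(list(Pr), list(Sh)),
               tolerance = 1e-12)

  # perfect prediction
  expect_equal(weighted_cross_entropy(Sh, Sh), 0)

  set.seed(32)
  for (k in 1:20) {
    L <- sample(c(6, 9, 13), 1)
    Sh1 <- modify_label(random_structure(L))
    Sh2 <- modify_label(random_structure(L))
    P1 <- row_softmax(matrix(rnorm(L * L), L, L))
    P2 <- row_softmax(matrix(rnorm(L * L), L, L))
    expect_equal(weighted_cross_entropy(list(P1, P2), list(Sh1, Sh2)),
                 ref_weighted_ce(list(P1, P2), list(Sh1, Sh2)),
                 tolerance = 1e-12)
    # invariant under permutation of sub-samples within membership class:
    # swapping whole samples permutes sub-samples without changing D
    expect_equal(weighted_cross_entropy(list(P1, P2), list(Sh1, Sh2)),
                 weighted_cross_entropy(list(P2, P1), list(Sh2, Sh1)),
                 tolerance = 1e-12)
  }
})

test_that("degenerate unpaired-set sizes fall back as documented", {
  # all bases unpaired: the weighted formula would vanish; unweighted mean used
  Sh <- diag(5)
  Pr <- matrix(0.2, 5, 5)
  expect_message(l <- weighted_cross_entropy(Pr, Sh), "unweighted mean")
  expect_equal(l, log(5), tolerance = 1e-12)

  # no unpaired bases at all (fully paired rows only, via padding mask)
  Sh2 <- modify_label(pairs_to_matrix(pair_map(5, rbind(c(1, 5)))))
  mask <- c(TRUE, FALSE, FALSE, FALSE, TRUE)  # keep only the paired rows
  expect_message(l2 <- weighted_cross_entropy(Pr, Sh2, pad_mask = mask),
                 "paired terms")
  expect_equal(l2, log(5), tolerance = 1e-12)
})

test_that("padding exclusion makes the loss batch-layout invariant", {
  set.seed(33)
  L <- 10
  Sh <- modify_label(random_structure(L))
  P <- row_softmax(matrix(rnorm(L * L), L, L))
  # embedding the same rows in a larger padded matrix must not change D or bL
  Lp <- 14
  Pp <- matrix(1 / Lp, Lp, Lp)
  Pp[1:L, 1:L] <- P  # padded rows carry junk that the mask must exclude
  Shp <- diag(Lp)
  Shp[1:L, 1:L] <- Sh
  expect_equal(weighted_cross_entropy(Pp, Shp,
                                      pad_mask = c(rep(TRUE, L), rep(FALSE, 4))),
               weighted_cross_entropy(P, Sh),
               tolerance = 1e-12)
})

test_that("half-unpaired batches reduce to the plain average", {
  # 10 sub-samples, 5 unpaired: weight (bL - |D|)/|D| = 1
  Sh <- modify_label(pairs_to_matrix(pair_map(10, cbind(1:5, 6:10))))
  stopifnot(sum(diag(Sh)) == 0)  # fully paired
  Sh2 <- diag(10)
  set.seed(34)
  P1 <- row_softmax(matrix(rnorm(100), 10, 10))
  P2 <- row_softmax(matrix(rnorm(100), 10, 10))
  li <- -log(c(P1[cbind(1:10, max.col(Sh))], P2[cbind(1:10, 1:10)]))
  expect_equal(weighted_cross_entropy(list(P1, P2), list(Sh, Sh2)), mean(li),
               tolerance = 1e-12)
})

test_that("row-labelled and column-labelled training objectives agree on symmetric scores", {
  set.seed(35)
  for (k in 1:50) {
    L <- sample(8:24, 1)
    Mhat <- symmetrize(matrix(rnorm(L * L), L, L))
    Sh <- modify_label(random_structure(L))
    lr <- weighted_cross_entropy(row_softmax(Mhat), Sh)
    lc <- weighted_cross_entropy_cols(col_softmax(t(Mhat)), Sh)
    expect_equal(lr, lc, tolerance = 1e-9)
  }
})

test_that("the training-path loss/gradient agrees with the public loss and flows to every row", {
  set.seed(36)
  L <- 12
  S <- random_structure(L)
  Sh <- modify_label(S)
  Mhat <- symmetrize(matrix(rnorm(L * L), L, L))
  lg <- rowfold:::wce_scores_grad(Mhat, Sh)
  expect_equal(lg$loss, weighted_cross_entropy(row_softmax(Mhat), Sh),
               tolerance = 1e-12)
  # numeric gradient check on a handful of entries
  eps <- 1e-6
  for (idx in sample(L * L, 8)) {
    Mp <- Mhat; Mp[idx] <- Mp[idx] + eps
    Mm <- Mhat; Mm[idx] <- Mm[idx] - eps
    num <- (rowfold:::wce_scores_grad(Mp, Sh)$loss -
              rowfold:::wce_scores_grad(Mm, Sh)$loss) / (2 * eps)
    expect_equal(lg$grad[idx], num, tolerance = 1e-5)
  }
  expect_true(all(rowSums(abs(lg$grad)) > 0))
})
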