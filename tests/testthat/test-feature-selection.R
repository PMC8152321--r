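test_that("feature variances match direct computation and edge cases", {
  vals <- cbind(g1 = c(1, 1), g2 = c(0, 2), g3 = c(3, 7))
  rownames(vals) <- c("a", "b")
  m <- omics_matrix(vals, "expression")
  v <- feature_variances(m)
  expect_equal(unname(v[1]), 0)       # constant column
  expect_equal(unname(v[2]), 2)       # ((0-1)^2 + (2-1)^2) / 1
  expect_equal(unname(v[3]), 8)
  set.seed(11)
  x <- matrix(rnorm(50), 10, 5,
              dimnames = list(sprintf("s%d", 1:10), sprintf("g%d", 1:5)))
  expect_equal(unname(feature_variances(omics_matrix(x, "expression"))),
               unname(apply(x, 2, var)))
  expect_error(feature_variances(omics_matrix(x[1, , drop = FALSE],
                                              "expression")),
               "at least 2 samples")
})

test_that("elbow threshold reproduces knee locations and degenerate cases", {
  expect_equal(elbow_threshold(c(10, 9.5, 9, 0.5, 0.4, 0.3, 0.2)), 9)
  expect_equal(elbow_threshold(c(100, 100, 1, 1, 1)), 100)
  # order of the input must not matter
  expect_equal(elbow_threshold(c(0.4, 9, 0.2, 10, 0.5, 9.5, 0.3)), 9)
  expect_error(elbow_threshold(seq(10, 1, length.out = 8)), "degenerate")
  expect_error(elbow_threshold(rep(2, 5)), "degenerate")
  expect_error(elbow_threshold(c(1, 2)), "at least 3")
})

test_that("elbow threshold agrees with a geometric brute-force oracle", {
  set.seed(21)
  for (i in 1:100) {
    n_hi <- sample(3:15, 1)
    n_lo <- sample(20:80, 1)
    v <- c(runif(n_hi, 5, 10), runif(n_lo, 0, 0.5))
    expect_equal(elbow_threshold(v), elbow_oracle(v))
  }
})

test_that("fitted masks keep exactly the features at or above threshold", {
  d <- small_sim(seed = 7)
  m <- d$expression
  mask <- fit_mask(m)
  v <- feature_variances(m)
  expect_identical(mask$features, m$feature_ids[v >= mask$threshold])
  expect_true(all(v[mask$features] >= mask$threshold))
  expect_lt(length(mask$features), length(m$feature_ids))
  reduced <- apply_mask(m, mask)
  expect_identical(reduced$feature_ids, mask$features)
})

test_that("masks recover planted informative features and exclude the floor", {
  d <- small_sim(seed = 9)
  for (layer in c("expression", "cna")) {
    mask <- fit_mask(d[[layer]])
    inf <- attr(d, "informative")[[layer]]
    expect_true(all(inf %in% mask$features))
    v <- mask$variances
    floor_set <- names(sort(v))[1:10]   # lowest-variance noise features
    expect_false(any(floor_set %in% mask$features))
  }
})

test_that("degenerate variance curves fall back to keeping all features", {
  vals <- matrix(rep(c(0, 1, 2), 4), 3, 4,
                 dimnames = list(c("a", "b", "c"), sprintf("g%d", 1:4)))
  m <- omics_matrix(vals, "expression")
  mask <- fit_mask(m)
  expect_identical(mask$features, m$feature_ids)
  expect_equal(mask$threshold, 1)   # the shared variance
})

test_that("top_k override keeps exactly k features in original order", {
  d <- small_sim(seed = 7)
  mask <- fit_mask(d$expression, top_k = 25)
  expect_length(mask$features, 25)
  expect_identical(mask$features,
                   d$expression$feature_ids[d$expression$feature_ids %in%
                                              mask$features])
  v <- feature_variances(d$expression)
  expect_true(min(v[mask$features]) >= max(v[setdiff(names(v),
                                                     mask$features)]) ||
                min(v[mask$features]) == mask$threshold)
  expect_error(fit_mask(d$expression, top_k = 0), "out of range")
})

test_that("mask fitting never consults held-out data (leakage guard)", {
  d <- small_sim(seed = 10)
  tr <- tripletdr:::mo_subset(d, 1:100)
  mask1 <- fit_mask(tr$expression)
  # perturbing the held-out samples cannot change a mask fit on training
  held <- tripletdr:::mo_subset(d, 101:160)
  perturbed <- omics_matrix(held$expression$values * 100 + 7, "expression")
  mask2 <- fit_mask(tr$expression)
  expect_identical(mask1$features, mask2$features)
  expect_identical(mask1$threshold, mask2$threshold)
  # and the mask applies to perturbed held-out data unchanged
  expect_identical(apply_mask(perturbed, mask1)$feature_ids, mask1$features)
})

test_that("apply_mask rejects matrices missing mask features", {
  d <- small_sim(seed = 7)
  mask <- fit_mask(d$expression)
  stripped <- tripletdr:::omics_subset(
    d$expression, features = setdiff(d$expression$feature_ids,
                                     mask$features[1]))
  expect_error(apply_mask(stripped, mask), "mask mismatch")
})

test_that("raising the threshold never adds features (monotonicity)", {
  d <- small_sim(seed = 12)
  v <- feature_variances(d$expression)
  thresholds <- sort(sample(v, 10))
  kept <- lapply(thresholds, function(t) names(v)[v >= t])
  for (i in 2:length(kept)) {
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
  }
})
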