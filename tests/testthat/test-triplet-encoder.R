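make_batch <- function(anchor, positive, negative) {
  structure(list(anchor = as.integer(anchor),
                 positive = as.integer(positive),
                 negative = as.integer(negative)),
            class = "triplet_batch")
}

test_that("encode equals ReLU of the matrix product and clamps negatives", {
  set.seed(3)
  W <- matrix(rnorm(12), 4, 3)
  model <- structure(list(weights = W, feature_ids = sprintf("g%d", 1:4)),
                     class = "triplet_encoder")
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(encode(model, x), pmax(x %*% W, 0))
  expect_true(all(encode(model, x) >= 0))

  model0 <- structure(list(weights = matrix(0, 4, 3)),
                      class = "triplet_encoder")
  expect_true(all(encode(model0, x) == 0))
  # all-negative projections collapse to zero
  modeln <- structure(list(weights = matrix(-1, 4, 2)),
                      class = "triplet_encoder")
  expect_true(all(encode(modeln, matrix(abs(rnorm(8)), 2, 4)) == 0))
  expect_error(encode(model, x[, 1:3]), "expects")
})

test_that("batch-all triplet enumeration has the combinatorial counts", {
  cases <- list(
    list(labels = c(1, 1, 0, 0), count = 8),
    list(labels = c(1, 1, 1, 0, 0), count = 18),   # 3*2*2 + 2*1*3
    list(labels = c(1, 0), count = 0),
    list(labels = c(1, 1, 0), count = 2)
  )
  for (cs in cases) {
    trip <- suppressWarnings(make_triplets(cs$labels))
    expect_length(trip, cs$count)
    if (cs$count > 0) {
      y <- cs$labels
      expect_true(all(y[trip$anchor] == y[trip$positive]))
      expect_true(all(y[trip$anchor] != y[trip$negative]))
      expect_true(all(trip$anchor != trip$positive))
    }
  }
  expect_warning(make_triplets(c(1, 1, 1)), "no valid triplet")
})

test_that("triplet loss matches the hinge definition on constructed cases", {
  # anchor == positive, d(a,n) = 2, margin 1 -> max(0 - 2 + 1, 0) = 0
  z <- rbind(c(0, 0), c(0, 0), c(2, 0))
  expect_equal(triplet_loss(z, make_batch(1, 2, 3), margin = 1), 0)
  # d(a,p) = 1, d(a,n) = 1, margin 0.5 -> 0.5
  z2 <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(triplet_loss(z2, make_batch(1, 2, 3), margin = 0.5), 0.5)
  expect_warning(
    expect_equal(triplet_loss(z2, make_batch(integer(0), integer(0),
                                             integer(0)), 1), 0),
    "empty")
})

test_that("batch-all loss equals the exhaustive enumeration oracle", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    z <- matrix(rnorm(n * 3), n, 3)
    margin <- runif(1, 0.2, 2)
    trip <- make_triplets(y)
    expect_equal(triplet_loss(z, trip, margin),
                 triplet_loss_oracle(z, y, margin), tolerance = 1e-6)
  }
})

test_that("loss is zero when every margin is satisfied and is permutation-invariant", {
  # two tight clusters separated by much more than the margin
  z <- rbind(matrix(rnorm(10, 0, 0.01), 5, 2),
             matrix(rnorm(10, 50, 0.01), 5, 2))
  y <- rep(c(1, 0), each = 5)
  expect_equal(triplet_loss(z, make_triplets(y), margin = 1), 0)

  set.seed(5)
  n <- 12
  y2 <- rep(c(0, 1), 6)
  z2 <- matrix(rnorm(n * 4), n, 4)
  perm <- sample(n)
  expect_equal(triplet_loss(z2, make_triplets(y2), 1),
               triplet_loss(z2[perm, ], make_triplets(y2[perm]), 1))
})

test_that("squared-distance variant uses squared Euclidean distances", {
  z <- rbind(c(0, 0), c(1, 0), c(0, 3))
  # d2(a,p) = 1, d2(a,n) = 9, margin 1 -> max(1 - 9 + 1, 0) = 0
  expect_equal(triplet_loss(z, make_batch(1, 2, 3), 1,
                            squared_distance = TRUE), 0)
  # margin 9 -> 1
  expect_equal(triplet_loss(z, make_batch(1, 2, 3), 9,
                            squared_distance = TRUE), 1)
})

test_that("encoder training is seeded-deterministic and respects max_epochs = 0", {
  d <- small_sim(seed = 13)
  mask <- fit_mask(d$expression)
  x <- apply_mask(d$expression, mask)$values
  y <- d$labels$labels
  tr <- 1:120
  va <- 121:160
  cfg0 <- encoder_config(output_dim = 8, max_epochs = 0, patience = 0,
                         seed = 42)
  e0a <- train_encoder(x[tr, ], y[tr], x[va, ], y[va], cfg0)
  e0b <- train_encoder(x[tr, ], y[tr], x[va, ], y[va], cfg0)
  expect_identical(e0a$weights, e0b$weights)
  expect_identical(e0a$best_epoch, 0L)

  cfg <- encoder_config(output_dim = 8, max_epochs = 8, patience = 8,
                        seed = 42)
  e1 <- train_encoder(x[tr, ], y[tr], x[va, ], y[va], cfg)
  e2 <- train_encoder(x[tr, ], y[tr], x[va, ], y[va], cfg)
  expect_identical(e1$weights, e2$weights)
  expect_false(identical(e1$weights, e0a$weights))
  expect_identical(nrow(e1$weights), ncol(x))
  expect_identical(ncol(e1$weights), 8L)

  expect_error(train_encoder(x[tr, ], rep(0, length(tr)), x[va, ], y[va],
                             cfg),
               "single class")
})

test_that("training tightens classes: inter/intra distance ratio increases", {
  d <- small_sim(seed = 14, n = 200)
  mask <- fit_mask(d$expression)
  x <- scale(apply_mask(d$expression, mask)$values)
  y <- d$labels$labels
  tr <- 1:150
  va <- 151:200
  cfg <- encoder_config(output_dim = 16, max_epochs = 25, patience = 25,
                        seed = 7)
  init <- train_encoder(x[tr, ], y[tr], x[va, ], y[va],
                        encoder_config(output_dim = 16, max_epochs = 0,
                                       patience = 0, seed = 7))
  trained <- train_encoder(x[tr, ], y[tr], x[va, ], y[va], cfg)
  r0 <- class_distance_ratio(encode(init, x[tr, ]), y[tr])
  r1 <- class_distance_ratio(encode(trained, x[tr, ]), y[tr])
  expect_gt(r1, r0)
  # history records both losses per epoch
  expect_true(all(c("train_loss", "val_loss") %in% names(trained$history)))
  expect_true(all(trained$history$val_loss >= 0))
})

test_that("encoder config validation rejects inconsistent settings", {
  expect_error(encoder_config(output_dim = 0), "output_dim")
  expect_error(encoder_config(margin = -1), "margin")
  expect_error(encoder_config(dropout_rate = 1), "dropout_rate")
  expect_error(encoder_config(max_epochs = 5, patience = 10), "patience")
})
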