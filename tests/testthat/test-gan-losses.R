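test_that("source loss matches its closed forms and is monotone", {
  expect_lt(source_loss(rep(1, 5), rep(0, 5)), 1e-6)
  expect_equal(source_loss(rep(0.5, 4), rep(0.5, 4)), 2 * log(2),
               tolerance = 1e-9)
  l1 <- source_loss(c(0.6, 0.7), c(0.3, 0.2))
  expect_gt(source_loss(c(0.5, 0.7), c(0.3, 0.2)), l1)   # worse on real
  expect_gt(source_loss(c(0.6, 0.7), c(0.4, 0.2)), l1)   # worse on fake
  expect_gte(source_loss(runif(10), runif(10)), 0)
})

test_that("class loss matches its closed forms and is order-invariant", {
  probs <- rbind(c(1, 0, 1), c(0, 1, 0))
  expect_lt(class_loss(probs, c("left", "right", "left")), 1e-6)
  u <- matrix(0.5, 2, 6)
  expect_equal(class_loss(u, rep(c("left", "right"), 3)), log(2),
               tolerance = 1e-9)
  set.seed(61)
  p <- softmax_cols_oracle(matrix(rnorm(2 * 8), 2))
  y <- sample(c("left", "right"), 8, replace = TRUE)
  perm <- sample(8)
  expect_equal(class_loss(p, y), class_loss(p[, perm], y[perm]),
               tolerance = 1e-12)
})

test_that("losses agree with a straight-line reimplementation", {
  clamp <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)
  set.seed(62)
  for (i in 1:25) {
    pr <- runif(8); pf <- runif(8)
    oracle <- -(mean(log(clamp(pr))) + mean(log(1 - clamp(pf))))
    expect_equal(source_loss(pr, pf), oracle, tolerance = 1e-6)
    probs <- softmax_cols_oracle(matrix(rnorm(16), 2))
    y <- sample(c("left", "right"), 8, replace = TRUE)
    idx <- ifelse(y == "left", 1, 2)
    oracle_c <- -mean(log(clamp(probs[cbind(idx, 1:8)])))
    expect_equal(class_loss(probs, y), oracle_c, tolerance = 1e-6)
  }
})
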