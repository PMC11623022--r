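test_that("classification metrics follow the standard formulas", {
  m <- classification_metrics(list(TP = 90, FP = 10, FN = 10, TN = 90,
                                   total = 200))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f_score, 0.9)
  expect_equal(m$accuracy, 0.9)
  expect_false(m$degenerate)
  perfect <- classification_metrics(list(TP = 5, FP = 0, FN = 0, TN = 5,
                                         total = 10))
  expect_true(all(unlist(perfect[1:4]) == 1))
  nopos <- classification_metrics(confusion_counts(rep("right", 4),
                                                   c("left", "left",
                                                     "right", "right")))
  expect_identical(nopos$precision, 0)
  expect_true(nopos$degenerate)
})

test_that("metrics agree with an independent confusion oracle", {
  set.seed(81)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    truth <- sample(c("left", "right"), n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.7, truth,
                   sample(c("left", "right"), n, replace = TRUE))
    cc <- confusion_counts(pred, truth)
    tp <- sum(pred == "left" & truth == "left")
    fp <- sum(pred == "left" & truth == "right")
    fn <- sum(pred == "right" & truth == "left")
    m <- classification_metrics(cc)
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
    expect_equal(m$accuracy, mean(pred == truth))
  }
})

test_that("similarity metrics hit their identity cases", {
  maps <- fixture_dataset()$maps[1:20]
  s <- similarity_metrics(maps, maps)
  expect_equal(s$ED, 0, tolerance = 1e-9)
  expect_equal(s$PCC, 1, tolerance = 1e-9)
  expect_equal(s$KLD, 0, tolerance = 1e-9)
  shifted <- lapply(maps, function(m) { m$grid <- m$grid + 0.2; m })
  expect_equal(similarity_metrics(maps, shifted)$PCC, 1, tolerance = 1e-9)
})

test_that("KLD equals a hand-summed histogram divergence on toy sets", {
  a <- ssf_map(matrix(c(0, 0.25, 0.5, 1), 2), label = "left")
  b <- ssf_map(matrix(c(0, 0.5, 0.75, 1), 2), label = "left")
  s <- similarity_metrics(list(a), list(b), bins = 4, eps = 1e-8)
  # brute-force oracle over the 4 equal bins of [0, 1]
  brk <- seq(0, 1, length.out = 5)
  p <- tabulate(findInterval(c(0, 0.25, 0.5, 1), brk,
                             rightmost.closed = TRUE, all.inside = TRUE), 4) / 4
  q <- tabulate(findInterval(c(0, 0.5, 0.75, 1), brk,
                             rightmost.closed = TRUE, all.inside = TRUE), 4) / 4
  p <- (p + 1e-8) / sum(p + 1e-8); q <- (q + 1e-8) / sum(q + 1e-8)
  expect_equal(s$KLD, sum(p * log(p / q)), tolerance = 1e-12)
  expect_gte(s$KLD, 0)
})

test_that("perturbation follows n*X + m*noise with [0, 255] clipping", {
  img <- matrix(200, 10, 10)
  expect_true(all(perturb(img, n = 0.5, m = 0) == 100))
  out <- perturb(matrix(128, 50, 50), n = 1, m = 50, seed = 82)
  expect_true(all(out >= 0 & out <= 255))
  big <- matrix(128, 120, 120)
  d <- perturb(big, n = 1, m = 5, seed = 83) - big
  expect_equal(var(as.vector(d)), 25, tolerance = 0.05 * 25)
  expect_identical(perturb(big, 0.5, 3, seed = 84),
                   perturb(big, 0.5, 3, seed = 84))
})

test_that("traditional augmentation preserves shape and labels", {
  maps <- fixture_dataset()$maps[1:4]
  rot <- traditional_augment(maps, "rotate")
  expect_length(rot, 20L)
  expect_identical(ssf_labels(rot), rep(ssf_labels(maps), each = 5))
  expect_true(all(vapply(rot, function(m) all(dim(m$grid) == 28), TRUE)))
  sca <- traditional_augment(maps, "scale")
  expect_length(sca, 4L)
  expect_identical(dim(sca[[1]]$grid), c(28L, 28L))
  both <- traditional_augment(maps, "both")
  expect_length(both, 4L + 20L + 4L)
  # 180-degree rotation is an exact involution
  g <- maps[[1]]$grid
  expect_identical(ssfgan:::rotate_nn(ssfgan:::rotate_nn(g, 180), 180), g)
})

test_that("McNemar exact p equals brute-force binomial summation", {
  mk <- function(b, cc, extra = 5) {
    n <- b + cc + extra
    truth <- rep("left", n)
    pred_a <- rep("left", n); pred_b <- rep("left", n)
    if (cc > 0) pred_a[seq_len(cc)] <- "right"           # only B right
    if (b > 0) pred_b[cc + seq_len(b)] <- "right"        # only A right
    list(a = pred_a, b = pred_b, t = truth)
  }
  for (b in 0:10) for (cc in 0:(20 - b)) {
    if (b + cc == 0) next
    v <- mk(b, cc)
    res <- mcnemar_test(v$a, v$b, v$t)
    expect_identical(c(res$b, res$c), c(b, cc))
    k <- min(b, cc); n <- b + cc
    brute <- min(1, 2 * sum(choose(n, 0:k) * 0.5^n))
    expect_equal(res$p_value, brute, tolerance = 1e-12)
  }
  v <- mk(10, 10)
  expect_gte(mcnemar_test(v$a, v$b, v$t)$p_value, 0.99)
  v <- mk(20, 0)
  expect_equal(mcnemar_test(v$a, v$b, v$t)$p_value, 2 * 0.5^20,
               tolerance = 1e-9)
  expect_identical(mcnemar_test(v$a, v$a, v$t)$p_value, 1)
  # large-sample branch switches to chi-square
  v <- mk(20, 10)
  expect_identical(mcnemar_test(v$a, v$b, v$t)$method,
                   "chi-square with continuity correction")
})

test_that("robustness curve anchors at clean accuracy and is reproducible", {
  ds <- fixture_dataset()
  sp <- split_by_trial(ds, seed = 85)
  model <- train_classifier(sp$train[1:80],
                            train_config(epochs = 3L, width_scale = 0.25,
                                         seed = 86))
  te <- sp$test[1:40]
  rc <- robustness_curve(model, te, levels = c(3, 11), seed = 87)
  clean <- mean(classify_maps(model, te)$labels == ssf_labels(te))
  expect_identical(rc$accuracy[rc$m == 0], clean)
  expect_identical(robustness_curve(model, te, levels = c(3, 11), seed = 87),
                   rc)
  expect_lte(rc$accuracy[rc$m == 11], rc$accuracy[rc$m == 0] + 0.02)
})

test_that("intra-subject cross-validation partitions and recovers", {
  ds <- fixture_dataset()
  maps <- ds$maps[1:114]                      # 6 trials, 3 per class
  for (i in seq_along(maps)) maps[[i]]$subject_id <- "S1"
  seen <- new.env(); seen$n <- 0
  train_fun <- function(tr) {
    seen$n <- seen$n + length(tr)
    train_classifier(tr, train_config(epochs = 2L, width_scale = 0.25))
  }
  cv <- crossval_intra_subject(maps, k = 5, seed = 88, train_fun = train_fun)
  expect_identical(nrow(cv), 1L)
  # every map sits in exactly one test fold: total trained = 4/5 of n per fold
  expect_equal(seen$n, 4 * length(maps))
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))
  expect_gte(cv$accuracy, 0.9)               # high-SNR recovery
  expect_error(crossval_intra_subject(maps[1:8], k = 5), "fewer than k")
})
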