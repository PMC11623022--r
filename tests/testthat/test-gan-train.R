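test_that("smoke training keeps losses finite and the generator alive", {
  maps <- fixture_dataset()$maps[1:48]
  m <- train_adgan(maps, train_config(epochs = 2L, width_scale = 0.125,
                                      seed = 71))
  expect_true(all(is.finite(as.matrix(m$history[, -1]))))
  gen <- generate_maps(m, 8, seed = 72)
  expect_length(gen, 8L)
  expect_true(all(vapply(gen, function(g) g$synthetic, TRUE)))
  expect_identical(table(ssf_labels(gen))[["left"]], 4L)
  expect_gt(sd(ssf_stack(gen)), 0.01)      # no degenerate collapse
  expect_true(all(abs(ssf_stack(gen)) < 1))
})

test_that("each adversarial step updates only its own network", {
  updated <- list()
  real_update <- ssfgan:::adam_update
  testthat::local_mocked_bindings(
    adam_update = function(layers, state) {
      updated[[length(updated) + 1L]] <<- layers
      real_update(layers, state)
    },
    .package = "ssfgan")
  maps <- fixture_dataset()$maps[c(1:8, 20:27)]   # balanced 8 + 8
  m <- train_adgan(maps, train_config(epochs = 1L, batch_size = 8L,
                                      width_scale = 0.125, seed = 73))
  # alternating D, G, D, G ... with disjoint layer sets
  expect_identical(length(updated), 4L)   # 2 batches x 2 updates
  d_ids <- lapply(updated[[1]], identity)
  g_ids <- lapply(updated[[2]], identity)
  expect_false(any(vapply(g_ids, function(l)
    any(vapply(d_ids, identical, TRUE, l)), TRUE)))
  # and D layers are the same set in both D updates
  expect_true(all(vapply(seq_along(updated[[1]]), function(i)
    identical(updated[[1]][[i]], updated[[3]][[i]]), TRUE)))
})

test_that("training is deterministic given a seed", {
  maps <- fixture_dataset()$maps[1:24]
  a <- train_adgan(maps, train_config(epochs = 2L, width_scale = 0.125,
                                      seed = 74))
  b <- train_adgan(maps, train_config(epochs = 2L, width_scale = 0.125,
                                      seed = 74))
  expect_identical(a$history, b$history)
  expect_identical(generate_maps(a, 4, seed = 9)[[1]]$grid,
                   generate_maps(b, 4, seed = 9)[[1]]$grid)
})

test_that("label-free noise never yields above-chance class accuracy", {
  maps <- noise_maps(120, seed = 75)
  tr <- maps[1:60]; te <- maps[61:120]
  m <- train_classifier(tr, train_config(epochs = 3L, width_scale = 0.125,
                                         seed = 76))
  acc <- mean(classify_maps(m, te)$labels == ssf_labels(te))
  expect_gt(acc, 0.3)
  expect_lt(acc, 0.7)
})

test_that("classification is batch-consistent and breaks ties to 'left'", {
  set.seed(77)
  d <- build_discriminator(discriminator_spec(width_scale = 0.125))
  maps <- noise_maps(6, seed = 78)
  batch <- classify_maps(d, maps)
  single <- unlist(lapply(maps, function(m) classify_maps(d, list(m))$labels))
  expect_identical(batch$labels, single)
  expect_identical(which.max(c(0.5, 0.5)), 1L)   # tie convention
  probs <- rbind(c(0.9, 0.1))
  expect_identical(c("left", "right")[apply(rbind(c(0.9, 0.4),
                                                  c(0.1, 0.6)), 2,
                                            which.max)],
                   c("left", "right"))
})

test_that("training refuses unlabeled or single-class data", {
  maps <- fixture_dataset()$maps[1:6]
  maps[[2]]$label <- NA_character_
  expect_error(train_adgan(maps, train_config(epochs = 1L)), "labeled")
  lab <- fixture_dataset()$maps
  onecls <- lab[ssf_labels(lab) == "left"][1:6]
  expect_error(train_adgan(onecls, train_config(epochs = 1L)), "per class")
})
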