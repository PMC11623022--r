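test_that("generator layer parameter counts reproduce the design table", {
  g <- build_generator()
  counts <- count_params(g)
  expect_identical(counts$params[counts$layer == "FC"], 1266944)
  expect_identical(counts$params[counts$layer == "BN"],
                   c(50176, 512, 256, 128))
  expect_identical(counts$params[counts$layer == "Conv2D Transpose"],
                   c(819328, 73792, 18464, 289))
})

test_that("discriminator trunk and source head match the design table", {
  d <- build_discriminator()
  counts <- count_params(d)
  expect_identical(counts$params[counts$layer == "Conv2D"],
                   c(640, 73856, 295168, 1180160))
  expect_identical(counts$params[counts$layer == "FC(sigmoid)"], 8193)
  expect_identical(4L * 4L * d$spec$channels[4], 8192L)   # flatten width
})

test_that("the latent dimension is pinned by the printed FC count", {
  # 12544 * (d + 1) = 1,266,944 has the unique solution d = 100
  sol <- which(vapply(1:512, function(d) 12544 * (d + 1) == 1266944,
                      logical(1)))
  expect_identical(sol, 100L)
  expect_identical(generator_spec()$latent_dim, 100L)
})

test_that("generator forward produces bounded 28x28 images", {
  set.seed(51)
  g <- build_generator(generator_spec(width_scale = 0.25))
  lat <- sample_latent(g, 4, c("left", "right"))
  expect_identical(dim(lat$z), c(100L, 4L))
  expect_true(all(lat$z > -1 & lat$z < 1))
  x <- generator_forward(g, lat$zc, training = TRUE)
  expect_identical(dim(x), c(28L, 28L, 1L, 4L))
  expect_true(all(is.finite(x)) && all(abs(x) < 1))
  # zero latent vector is still a valid input
  x0 <- generator_forward(g, matrix(0, 100, 2), training = TRUE)
  expect_true(all(is.finite(x0)))
})

test_that("discriminator outputs calibrated probability heads", {
  set.seed(52)
  d <- build_discriminator(discriminator_spec(width_scale = 0.25))
  x <- array(runif(28 * 28 * 3, -1, 1), c(28, 28, 1, 3))
  out <- discriminator_forward(d, x)
  expect_true(all(out$source > 0 & out$source < 1))
  expect_equal(unname(colSums(out$class_probs)), rep(1, 3),
               tolerance = 1e-6)
})

test_that("latent conditioning multiplies by the label embedding", {
  set.seed(53)
  g <- build_generator(generator_spec(width_scale = 0.1))
  z <- matrix(runif(100 * 3, -1, 1), 100, 3)
  g$embedding$params$E[] <- 1
  expect_identical(condition_latent(g, z, c("left", "right", "left")), z)
  g$embedding$params$E[2, ] <- 2
  zc <- condition_latent(g, z, c("left", "right", "left"))
  expect_identical(zc[, 1], z[, 1])
  expect_identical(zc[, 2], 2 * z[, 2])
  expect_identical(nrow(zc), 100L)
  expect_error(condition_latent(g, z, c("left", "up", "left")), "unknown")
})
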