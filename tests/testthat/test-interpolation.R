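test_that("interpolation reproduces constant and linear fields in-hull", {
  mont <- fixture_montage()
  g <- ssfgan:::ssf_grid_axes(mont, 28)
  ct <- ct_interpolator(mont$pos2d, g, g, fill = NA)
  m <- ct$eval(rep(2.5, 64))
  expect_true(all(abs(m[ct$inside] - 2.5) < 1e-9))
  expect_true(all(is.na(m[!ct$inside])))
  f <- 1.5 * mont$pos2d[, "u"] - 0.7 * mont$pos2d[, "v"] + 0.2
  m <- ct$eval(f)
  tru <- outer(g, g, function(u, v) 1.5 * u - 0.7 * v + 0.2)
  expect_true(max(abs(m[ct$inside] - tru[ct$inside])) < 1e-6)
})

test_that("interpolation honors the data points themselves", {
  pts <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1), c(0.25, 0),
               c(-0.5, 0.25), c(0.5, 0.75), c(0, -0.5))
  set.seed(41)
  vals <- rnorm(8)
  # grid axes that pass exactly through electrode 5 at (0.25, 0)
  gu <- seq(-1, 1, by = 0.25)
  ct <- ct_interpolator(pts, gu, gu, fill = 0)
  m <- ct$eval(vals)
  expect_equal(m[which(gu == 0.25), which(gu == 0)], vals[5],
               tolerance = 1e-9)
})

test_that("the macro-element reproduces quadratics given exact gradients", {
  # pins down the control-net construction: the reduced Clough-Tocher
  # element with exact values and gradients is exact on quadratics
  set.seed(42)
  pts <- cbind(runif(12, -1, 1), runif(12, -1, 1))
  tris <- delaunay_triangulation(pts)
  quad <- function(p) p[, 1]^2 + 0.5 * p[, 1] * p[, 2] - p[, 2]^2 + p[, 1]
  dquad <- function(p) cbind(2 * p[, 1] + 0.5 * p[, 2] + 1,
                             0.5 * p[, 1] - 2 * p[, 2])
  for (t in seq_len(min(5, nrow(tris)))) {
    P <- pts[tris[t, ], ]
    net <- ssfgan:::ct_control_net(P, quad(P), dquad(P))
    for (r in 1:4) {
      l <- runif(3); l <- l / sum(l)
      x <- colSums(P * l)
      k <- which.min(l)
      uvw <- switch(k,
                    c(l[2] - l[1], l[3] - l[1], 3 * l[1]),
                    c(l[3] - l[2], l[1] - l[2], 3 * l[2]),
                    c(l[1] - l[3], l[2] - l[3], 3 * l[3]))
      patch <- switch(k, 2L, 3L, 1L)
      val <- sum(ssfgan:::ct_bernstein(uvw[1], uvw[2], uvw[3]) * net[patch, ])
      expect_equal(val, unname(quad(rbind(x))), tolerance = 1e-10)
    }
  }
})

test_that("interpolation is invariant to electrode ordering", {
  set.seed(43)
  pts <- cbind(runif(20, -1, 1), runif(20, -1, 1))
  vals <- rnorm(20)
  g <- seq(-0.8, 0.8, length.out = 15)
  m1 <- ct_interpolator(pts, g, g)$eval(vals)
  perm <- sample(20)
  m2 <- ct_interpolator(pts[perm, ], g, g)$eval(vals[perm])
  expect_equal(m1, m2, tolerance = 1e-8)
})

test_that("degenerate electrode sets are refused", {
  line <- cbind(seq(0, 1, length.out = 6), seq(0, 2, length.out = 6))
  expect_error(ct_interpolator(line, 0:1, 0:1), "collinear|degenerate")
  expect_error(ct_interpolator(line[1:3, ], 0:1, 0:1), "at least 4")
})

test_that("interpolate_map wires the montage path and approximates smooth fields", {
  mont <- fixture_montage()
  f <- sin(mont$pos2d[, "u"]) * cos(mont$pos2d[, "v"])
  m <- interpolate_map(f, mont)
  expect_identical(dim(m), c(28L, 28L))
  g <- ssfgan:::ssf_grid_axes(mont, 28)
  ct <- ct_interpolator(mont$pos2d, g, g, fill = NA)
  tru <- outer(g, g, function(u, v) sin(u) * cos(v))
  inside <- ct$inside
  expect_lt(max(abs(m[inside] - tru[inside])), 0.1)
  expect_error(interpolate_map(f, standard_montage(64)), "pos2d|project")
  expect_error(interpolate_map(f[1:10], mont), "length")
})
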