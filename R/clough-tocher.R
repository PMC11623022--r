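# Reduced Hsieh-Clough-Tocher (HCT) C1 piecewise-cubic interpolation over a
# Delaunay triangulation of scattered points.
#
# Each macro triangle is split at its centroid into three cubic Bezier
# patches. Corner values and gradients fix the boundary control net; the
# interior point of each mini-patch comes from requiring the cross-boundary
# (normal) derivative to vary linearly along the outer edge (the "reduced"
# condition, which makes neighboring macro triangles join C1); C1 across the
# internal edges then yields the second-ring points s_i and the center
# ordinate. With exact corner gradients the element reproduces quadratics
# exactly; with the least-squares gradient estimation used here it reproduces
# linear fields exactly, which is the property the feature maps rely on.
#
# Vertex gradients are estimated per vertex by inverse-distance-weighted
# least squares over the triangulation neighbors (exact for linear fields).

# Estimate per-vertex gradients of values over pts; returns n x 2 matrix.
estimate_gradients <- function(pts, values, nb) {
  n <- nrow(pts)
  g <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    j <- nb[[i]]
    d <- pts[j, , drop = FALSE] - rep(pts[i, ], each = length(j))
    w <- 1 / pmax(rowSums(d^2), 1e-300)
    A <- crossprod(d * sqrt(w))
    b <- crossprod(d * w, values[j] - values[i])
    sol <- tryCatch(solve(A, b), error = function(e) c(0, 0))
    g[i, ] <- sol
  }
  g
}

# Barycentric-direction coordinates of direction vector d wrt triangle
# (p1, p2, p3): delta with sum 0 and d = delta1 p1 + delta2 p2 + delta3 p3.
bary_direction <- function(p1, p2, p3, d) {
  M <- rbind(c(p1[1], p2[1], p3[1]), c(p1[2], p2[2], p3[2]), c(1, 1, 1))
  as.numeric(solve(M, c(d, 0)))
}

# Interior ("e") ordinate of the mini-patch on outer edge pa -> pb of the
# macro triangle with centroid p0, from the linear-normal-derivative
# condition. fa, fb corner values; da(), db() directional derivatives
# (precomputed dot products); aa, ab the first-ring ordinates toward p0.
ct_edge_interior <- function(pa, pb, p0, fa, fb, dab, dba, aa, ab) {
  v <- pb - pa
  nrm <- c(-v[2], v[1])
  delta <- bary_direction(pa, pb, p0, nrm)
  b300 <- fa; b030 <- fb
  b210 <- fa + dab / 3; b120 <- fb + dba / 3
  b201 <- aa; b021 <- ab
  (0.5 * (delta[1] * (b300 + b120) + delta[2] * (b210 + b030) +
          delta[3] * (b201 + b021)) -
     delta[1] * b210 - delta[2] * b120) / delta[3]
}

# Full control net (3 patches x 10 ordinates) for one macro triangle.
# f: 3 values; g: 3x2 gradients; P: 3x2 corner coordinates.
ct_control_net <- function(P, f, g) {
  p0 <- colMeans(P)
  d <- function(i, vec) sum(g[i, ] * vec)
  a <- vapply(1:3, function(i) f[i] + d(i, p0 - P[i, ]) / 3, numeric(1))
  eA <- ct_edge_interior(P[1, ], P[2, ], p0, f[1], f[2],
                         d(1, P[2, ] - P[1, ]), d(2, P[1, ] - P[2, ]),
                         a[1], a[2])
  eB <- ct_edge_interior(P[2, ], P[3, ], p0, f[2], f[3],
                         d(2, P[3, ] - P[2, ]), d(3, P[2, ] - P[3, ]),
                         a[2], a[3])
  eC <- ct_edge_interior(P[3, ], P[1, ], p0, f[3], f[1],
                         d(3, P[1, ] - P[3, ]), d(1, P[3, ] - P[1, ]),
                         a[3], a[1])
  s1 <- (eC + eA + a[1]) / 3
  s2 <- (eA + eB + a[2]) / 3
  s3 <- (eB + eC + a[3]) / 3
  cc <- (s1 + s2 + s3) / 3
  # each patch: ordinates b300 b030 b003 b210 b120 b201 b021 b102 b012 b111
  rbind(
    A = c(f[1], f[2], cc, f[1] + d(1, P[2, ] - P[1, ]) / 3,
          f[2] + d(2, P[1, ] - P[2, ]) / 3, a[1], a[2], s1, s2, eA),
    B = c(f[2], f[3], cc, f[2] + d(2, P[3, ] - P[2, ]) / 3,
          f[3] + d(3, P[2, ] - P[3, ]) / 3, a[2], a[3], s2, s3, eB),
    C = c(f[3], f[1], cc, f[3] + d(3, P[1, ] - P[3, ]) / 3,
          f[1] + d(1, P[3, ] - P[1, ]) / 3, a[3], a[1], s3, s1, eC))
}

# Cubic Bernstein basis over ordinates ordered as in ct_control_net.
ct_bernstein <- function(u, v, w) {
  c(u^3, v^3, w^3, 3 * u^2 * v, 3 * u * v^2, 3 * u^2 * w, 3 * v^2 * w,
    3 * u * w^2, 3 * v * w^2, 6 * u * v * w)
}

#' Clough-Tocher interpolator for scattered planar data
#'
#' Builds the triangulation, gradient-estimation and point-location machinery
#' once, returning an object whose `$eval(values)` interpolates any value
#' vector over the same points onto the same grid. Evaluation is linear in
#' the values, so repeated maps reduce to a single matrix product.
#'
#' @param pts numeric matrix of point coordinates (two columns); at least 4
#'   non-collinear points.
#' @param grid_u,grid_v grid node coordinates along each axis.
#' @param fill value assigned outside the convex hull of `pts`.
#' @return List with `eval(values)` (returns `length(grid_u)` x
#'   `length(grid_v)` matrix), the `inside` mask, and triangulation details.
#' @export
ct_interpolator <- function(pts, grid_u, grid_v, fill = 0) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 electrodes to interpolate")
  tris <- delaunay_triangulation(pts)
  nb <- triangulation_neighbors(tris, n)
  grid <- cbind(rep(grid_u, times = length(grid_v)),
                rep(grid_v, each = length(grid_u)))
  m <- nrow(grid)
  tri_of <- rep(NA_integer_, m)
  lam <- matrix(NA_real_, m, 3)
  tol <- -1e-9
  for (t in seq_len(nrow(tris))) {
    un <- which(is.na(tri_of))
    if (!length(un)) break
    P <- pts[tris[t, ], ]
    Tm <- cbind(P[1, ] - P[3, ], P[2, ] - P[3, ])
    rel <- grid[un, , drop = FALSE] - rep(P[3, ], each = length(un))
    ab <- t(solve(Tm, t(rel)))
    l3 <- 1 - ab[, 1] - ab[, 2]
    ok <- ab[, 1] >= tol & ab[, 2] >= tol & l3 >= tol
    if (any(ok)) {
      tri_of[un[ok]] <- t
      lam[un[ok], ] <- cbind(ab[ok, 1], ab[ok, 2], l3[ok])
    }
  }
  inside <- !is.na(tri_of)
  # per-node patch selection and Bernstein weights (independent of values)
  Wrow <- matrix(0, m, 10)
  patch <- integer(m)
  for (i in which(inside)) {
    l <- lam[i, ]
    k <- which.min(l)   # opposite patch: min lambda_3 -> A, etc.
    if (k == 3) { patch[i] <- 1; uvw <- c(l[1] - l[3], l[2] - l[3], 3 * l[3]) }
    else if (k == 1) { patch[i] <- 2; uvw <- c(l[2] - l[1], l[3] - l[1], 3 * l[1]) }
    else { patch[i] <- 3; uvw <- c(l[3] - l[2], l[1] - l[2], 3 * l[2]) }
    Wrow[i, ] <- ct_bernstein(uvw[1], uvw[2], uvw[3])
  }
  eval_fun <- function(values) {
    stopifnot(length(values) == n)
    grads <- estimate_gradients(pts, values, nb)
    out <- rep(fill, m)
    for (t in unique(tri_of[inside])) {
      net <- ct_control_net(pts[tris[t, ], ], values[tris[t, ]],
                            grads[tris[t, ], , drop = FALSE])
      sel <- which(tri_of == t)
      out[sel] <- rowSums(Wrow[sel, , drop = FALSE] *
                          net[patch[sel], , drop = FALSE])
    }
    matrix(out, length(grid_u), length(grid_v))
  }
  list(eval = eval_fun, inside = matrix(inside, length(grid_u)),
       tris = tris, pts = pts, grid_u = grid_u, grid_v = grid_v, fill = fill)
}

#' Interpolate per-electrode values onto a topographic grid
#'
#' Clough-Tocher (C1 piecewise-cubic) interpolation of one value per
#' projected electrode onto a regular `grid_n` x `grid_n` grid spanning the
#' electrode bounding square (`[-r, r]^2` with `r` = 1.05 x the largest
#' projected radius). Grid nodes outside the electrode convex hull are set to
#' `fill`.
#'
#' @param values numeric vector, one value per electrode.
#' @param montage a projected [electrode_montage()] (see
#'   [project_montage()]).
#' @param grid_n grid resolution per axis (default 28).
#' @param fill off-hull fill value.
#' @return A `grid_n` x `grid_n` numeric matrix; rows follow the u (front)
#'   axis, columns the v (left) axis.
#' @export
interpolate_map <- function(values, montage, grid_n = 28, fill = 0) {
  stopifnot(inherits(montage, "electrode_montage"))
  if (is.null(montage$pos2d))
    stop("montage has no 2D coordinates; call project_montage() first")
  if (length(values) != length(montage$names))
    stop("values length does not match electrode count")
  g <- ssf_grid_axes(montage, grid_n)
  ct <- ct_interpolator(montage$pos2d, g, g, fill)
  ct$eval(values)
}

# Common grid axes for a projected montage.
ssf_grid_axes <- function(montage, grid_n = 28, margin = 1.05) {
  r <- max(sqrt(rowSums(montage$pos2d^2))) * margin
  seq(-r, r, length.out = grid_n)
}

# Interpolator construction is pure in (pos2d, grid); cache it so repeated
# extractions over the same montage skip triangulation and point location.
.ct_cache <- new.env(parent = emptyenv())

ct_interpolator_cached <- function(pos2d, grid_u, grid_v, fill = 0) {
  key <- paste(fill, length(grid_u), grid_u[1], grid_u[length(grid_u)],
               paste(signif(as.vector(pos2d), 12), collapse = ","),
               sep = "|")
  hit <- .ct_cache[[key]]
  if (!is.null(hit)) return(hit)
  ct <- ct_interpolator(pos2d, grid_u, grid_v, fill)
  assign(key, ct, envir = .ct_cache)
  ct
}
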