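# Planar geometry primitives used by the spatial-niche module. All
# coordinates are micrometres, Cartesian, arbitrary origin. Polygons are
# two-column (x, y) matrices of vertices without a repeated closing vertex.

polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- length(x)
  abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
}

polygon_perimeter <- function(poly) {
  d <- poly[c(2:nrow(poly), 1L), , drop = FALSE] - poly
  sum(sqrt(rowSums(d^2)))
}

# signed area > 0 for counter-clockwise vertex order
polygon_signed_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- length(x)
  sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y) / 2
}

# boundary-inclusive point-in-polygon (ray casting + on-segment test),
# vectorised over points: one pass per polygon edge
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  xs <- poly[, 1L]; ys <- poly[, 2L]
  xe <- xs[c(2:n, 1L)]; ye <- ys[c(2:n, 1L)]
  cross <- integer(length(px))
  onb <- logical(length(px))
  for (j in seq_len(n)) {
    dx <- xe[j] - xs[j]; dy <- ye[j] - ys[j]
    len2 <- max(dx^2 + dy^2, eps)
    t <- pmin(1, pmax(0, ((px - xs[j]) * dx + (py - ys[j]) * dy) / len2))
    d2 <- (xs[j] + t * dx - px)^2 + (ys[j] + t * dy - py)^2
    onb <- onb | d2 <= eps
    cond <- (ys[j] > py) != (ye[j] > py)
    if (any(cond)) {
      xint <- xs[j] + (py - ys[j]) * dx / if (dy == 0) 1 else dy
      cross <- cross + (cond & px < xint)
    }
  }
  (cross %% 2L == 1L) | onb
}

points_in_any_polygon <- function(px, py, polys) {
  inside <- rep(FALSE, length(px))
  for (poly in polys) {
    todo <- which(!inside)
    if (!length(todo)) break
    inside[todo] <- point_in_polygon(px[todo], py[todo], poly)
  }
  inside
}

segments_intersect <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  if (abs(denom) < eps) return(FALSE)   # parallel: treated as non-crossing
  t <- ((p3[1L] - p1[1L]) * d2[2L] - (p3[2L] - p1[2L]) * d2[1L]) / denom
  u <- ((p3[1L] - p1[1L]) * d1[2L] - (p3[2L] - p1[2L]) * d1[1L]) / denom
  t > eps && t < 1 - eps && u > eps && u < 1 - eps
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(FALSE)
  idx <- cbind(seq_len(n), c(2:n, 1L))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(poly[idx[i, 1L], ], poly[idx[i, 2L], ],
                             poly[idx[j, 1L], ], poly[idx[j, 2L], ]))
        return(TRUE)
    }
  }
  FALSE
}

# regular polygon approximating a disc (inscribed n-gon)
disc_polygon <- function(cx, cy, r, n_arc = 64L) {
  th <- seq(0, 2 * pi, length.out = n_arc + 1L)[-(n_arc + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Minkowski dilation of the convex hull of a point set by a disc of
# radius r; arcs approximated with segments at ~2*pi/n_arc resolution.
# Handles degenerate hulls (single point, collinear points).
dilate_hull <- function(pts, r, n_arc = 64L) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  if (nrow(pts) == 1L)
    return(disc_polygon(pts[1L, 1L], pts[1L, 2L], r, n_arc))
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  if (nrow(hull) >= 3L && polygon_signed_area(hull) != 0) {
    if (polygon_signed_area(hull) < 0)
      hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]   # force CCW
  } else {
    # collinear: reduce to the two extreme points (capsule)
    d <- as.matrix(stats::dist(pts))
    ext <- which(d == max(d), arr.ind = TRUE)[1L, ]
    hull <- pts[ext, , drop = FALSE]
  }
  n <- nrow(hull)
  nxt <- c(2:n, 1L)
  out <- list()
  step <- 2 * pi / n_arc
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[nxt[i], ]
    e <- b - a; len <- sqrt(sum(e^2))
    nrm <- c(e[2L], -e[1L]) / len       # outward normal for CCW order
    out[[length(out) + 1L]] <- rbind(a + r * nrm, b + r * nrm)
    # arc at vertex b from this edge's normal to the next edge's normal
    cnext <- hull[nxt[nxt[i]], ]                 # vertex after b
    e2 <- cnext - b; len2 <- sqrt(sum(e2^2))
    nrm2 <- c(e2[2L], -e2[1L]) / len2
    a1 <- atan2(nrm[2L], nrm[1L]); a2 <- atan2(nrm2[2L], nrm2[1L])
    dth <- (a2 - a1) %% (2 * pi)
    if (dth > 1e-9) {
      k <- max(1L, ceiling(dth / step))
      th <- a1 + dth * seq_len(k - 1L) / k
      if (length(th))
        out[[length(out) + 1L]] <-
          cbind(b[1L] + r * cos(th), b[2L] + r * sin(th))
    }
  }
  poly <- do.call(rbind, out)
  colnames(poly) <- c("x", "y")
  # drop near-duplicate consecutive vertices
  keep <- c(TRUE, rowSums((poly[-1L, , drop = FALSE] -
                             poly[-nrow(poly), , drop = FALSE])^2) > 1e-12)
  poly[keep, , drop = FALSE]
}

# Sutherland-Hodgman clip of a polygon to an axis-aligned rectangle
clip_polygon_rect <- function(poly, xmin, ymin, xmax, ymax) {
  clip_half <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- list()
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prev <- pts[if (i == 1L) n else i - 1L, ]
      ci <- inside(cur); pi_ <- inside(prev)
      if (ci) {
        if (!pi_) out[[length(out) + 1L]] <- intersect(prev, cur)
        out[[length(out) + 1L]] <- cur
      } else if (pi_) {
        out[[length(out) + 1L]] <- intersect(prev, cur)
      }
    }
    if (!length(out)) return(poly[0, , drop = FALSE])
    do.call(rbind, out)
  }
  ix <- function(p, q, val, coord) {
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  p <- poly
  p <- clip_half(p, function(v) v[1L] >= xmin,
                 function(a, b) ix(a, b, xmin, 1L))
  p <- clip_half(p, function(v) v[1L] <= xmax,
                 function(a, b) ix(a, b, xmax, 1L))
  p <- clip_half(p, function(v) v[2L] >= ymin,
                 function(a, b) ix(a, b, ymin, 2L))
  p <- clip_half(p, function(v) v[2L] <= ymax,
                 function(a, b) ix(a, b, ymax, 2L))
  colnames(p) <- c("x", "y")
  p
}

# area of the union of a list of polygons by deterministic grid counting
polygon_union_area <- function(polys, step = 0.5) {
  polys <- polys[vapply(polys, nrow, 0L) >= 3L]
  if (!length(polys)) return(0)
  bb <- do.call(rbind, polys)
  xs <- seq(min(bb[, 1L]) + step / 2, max(bb[, 1L]), by = step)
  ys <- seq(min(bb[, 2L]) + step / 2, max(bb[, 2L]), by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  sum(points_in_any_polygon(gx, gy, polys)) * step^2
}
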