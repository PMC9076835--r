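# Small computational-geometry toolkit used by the geometry, meshing and
# strain-mapping modules. Polygons are two-column matrices of vertices in
# order, without a repeated closing vertex.

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param poly two-column matrix of vertices in order.
#' @param signed return the signed area (positive for counter-clockwise)?
#' @return area in squared input units.
#' @export
polygon_area <- function(poly, signed = FALSE) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  a <- sum(x * y2 - x2 * y) / 2
  if (signed) a else abs(a)
}

polygon_perimeter <- function(poly) {
  poly <- as.matrix(poly)
  d <- sqrt(rowSums((poly[c(2:nrow(poly), 1), , drop = FALSE] - poly)^2))
  sum(d)
}

polygon_centroid <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

# Vectorized even-odd (ray casting) point-in-polygon test. Points on an
# edge may land on either side at floating-point resolution; callers that
# care use distances instead.
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

# Minimum distance from points to a polygon boundary, vectorized over
# points with a loop over edges.
dist_to_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  sqrt(d2)
}

# Signed distance: negative inside the polygon.
signed_dist_to_polygon <- function(px, py, poly) {
  d <- dist_to_polygon(px, py, poly)
  ifelse(point_in_polygon(px, py, poly), -d, d)
}

is_convex_polygon <- function(poly, tol = 1e-9) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  c_ <- poly[c(3:n, 1, 2), , drop = FALSE]
  cr <- (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
    (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1])
  scale <- max(abs(cr), 1e-30)
  all(cr >= -tol * scale) || all(cr <= tol * scale)
}

# Sutherland-Hodgman clipping of an arbitrary subject polygon against a
# CONVEX clip polygon. Returns a polygon matrix (possibly with 0 rows).
clip_polygon_convex <- function(subject, clip) {
  clip <- as.matrix(clip)
  if (polygon_area(clip, signed = TRUE) < 0) clip <- clip[nrow(clip):1, , drop = FALSE]
  out <- as.matrix(subject)
  n <- nrow(clip)
  j <- n
  for (i in seq_len(n)) {
    if (nrow(out) == 0L) break
    ax <- clip[j, 1]; ay <- clip[j, 2]
    bx <- clip[i, 1]; by <- clip[i, 2]
    # inside = left of directed edge a->b
    side <- function(px, py) (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    inp <- out
    m <- nrow(inp)
    res <- matrix(numeric(0), ncol = 2)
    sprev <- side(inp[m, 1], inp[m, 2])
    prev <- inp[m, ]
    for (k in seq_len(m)) {
      cur <- inp[k, ]
      scur <- side(cur[1], cur[2])
      if (scur >= 0) {
        if (sprev < 0) {
          t <- sprev / (sprev - scur)
          res <- rbind(res, prev + t * (cur - prev))
        }
        res <- rbind(res, cur)
      } else if (sprev >= 0) {
        t <- sprev / (sprev - scur)
        res <- rbind(res, prev + t * (cur - prev))
      }
      prev <- cur
      sprev <- scur
    }
    out <- res
    j <- i
  }
  out
}

# Area of the intersection of a polygon with a convex polygon.
intersection_area_convex <- function(subject, clip) {
  p <- clip_polygon_convex(subject, clip)
  if (nrow(p) < 3) 0 else polygon_area(p)
}

# Do segments (a1,a2) and (b1,b2) properly intersect (crossing interiors)?
segments_cross <- function(a1, a2, b1, b2, tol = 1e-12) {
  o <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- o(b1, b2, a1); d2 <- o(b1, b2, a2)
  d3 <- o(a1, a2, b1); d4 <- o(a1, a2, b2)
  (d1 * d2 < -tol) && (d3 * d4 < -tol)
}

# Is a triangle entirely inside a (possibly non-convex) simple polygon?
# All vertices inside (or within tol of the boundary), centroid inside,
# and no triangle edge properly crossing a polygon edge.
triangle_in_polygon <- function(tri_xy, poly, tol = 1e-9) {
  poly <- as.matrix(poly)
  px <- tri_xy[, 1]; py <- tri_xy[, 2]
  inside <- point_in_polygon(px, py, poly)
  near <- dist_to_polygon(px, py, poly) <= tol
  if (!all(inside | near)) return(FALSE)
  cen <- colMeans(tri_xy)
  if (!point_in_polygon(cen[1], cen[2], poly) &&
      dist_to_polygon(cen[1], cen[2], poly) > tol) return(FALSE)
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    b1 <- poly[j, ]; b2 <- poly[i, ]
    for (e in 1:3) {
      a1 <- tri_xy[e, ]; a2 <- tri_xy[if (e == 3) 1 else e + 1, ]
      if (segments_cross(a1, a2, b1, b2)) return(FALSE)
    }
    j <- i
  }
  TRUE
}
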