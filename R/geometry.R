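# Plain planar-polygon primitives for BrdU region-of-interest work.
# Polygons are n x 2 numeric matrices (x, y), implicitly closed.

#' Polygon area by the shoelace formula
#'
#' @param poly n x 2 numeric matrix of vertices (implicitly closed).
#' @return absolute enclosed area.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3, all(is.finite(poly)))
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:nrow(poly), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# TRUE when p lies on the closed segment a-b (within eps).
on_segment <- function(p, a, b, eps = 1e-9) {
  cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  if (abs(cross) > eps * (1 + max(abs(c(a, b, p))))) return(FALSE)
  dot <- (p[1] - a[1]) * (b[1] - a[1]) + (p[2] - a[2]) * (b[2] - a[2])
  len2 <- sum((b - a)^2)
  dot >= -eps && dot <= len2 + eps
}

#' Points inside or on the boundary of a polygon
#'
#' Ray-casting with an explicit boundary check, so points exactly on an edge
#' or vertex count as inside.
#'
#' @param pts m x 2 matrix of points.
#' @param poly n x 2 polygon matrix.
#' @return logical vector of length m.
#' @export
points_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  poly <- as.matrix(poly)
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  vapply(seq_len(nrow(pts)), function(k) {
    p <- pts[k, ]
    for (i in seq_len(n)) {
      if (on_segment(p, poly[i, ], poly[j[i], ])) return(TRUE)
    }
    inside <- FALSE
    for (i in seq_len(n)) {
      yi <- poly[i, 2]; yj <- poly[j[i], 2]
      if ((yi > p[2]) != (yj > p[2])) {
        xint <- poly[i, 1] + (p[2] - yi) / (yj - yi) * (poly[j[i], 1] - poly[i, 1])
        if (p[1] < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# A polygon is simple when no two non-adjacent edges cross.
is_simple_polygon <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      if (k == i || k == nxt[i] || nxt[k] == i) next
      if (segments_intersect(poly[i, ], poly[nxt[i], ], poly[k, ], poly[nxt[k], ]))
        return(FALSE)
    }
  }
  TRUE
}

validate_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || nrow(poly) < 3 || !all(is.finite(poly)))
    stop("degenerate polygon: need an n x 2 finite matrix with n >= 3")
  if (polygon_area(poly) <= 0) stop("degenerate polygon: zero area")
  if (!is_simple_polygon(poly)) stop("degenerate polygon: self-intersecting")
  poly
}
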