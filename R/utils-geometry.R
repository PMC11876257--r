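# Plain 2D polygon utilities on open rings: an n x 2 matrix of (x, y) vertex
# coordinates, 0-based pixel units, y-down, last vertex NOT repeating the first.

.asRing <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L)
    stop("polygon must be an n x 2 coordinate matrix with n >= 3")
  # drop a duplicated closing vertex if present
  n <- nrow(poly)
  if (isTRUE(all.equal(poly[1L, ], poly[n, ], check.attributes = FALSE)))
    poly <- poly[-n, , drop = FALSE]
  storage.mode(poly) <- "double"
  unname(poly)
}

.polygonSignedArea <- function(poly) {
  poly <- .asRing(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

.polygonArea <- function(poly) abs(.polygonSignedArea(poly))

.polygonPerimeter <- function(poly) {
  poly <- .asRing(poly)
  d <- rbind(poly[-1L, , drop = FALSE], poly[1L, , drop = FALSE]) - poly
  sum(sqrt(rowSums(d^2)))
}

# Area, centroid and second-order central moments of a simple polygon via
# Green's theorem (exact, no rasterization).
.polygonMoments <- function(poly) {
  poly <- .asRing(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps)
    stop("degenerate polygon: zero area")
  cx <- sum((x + xn) * cross) / (6 * a)
  cy <- sum((y + yn) * cross) / (6 * a)
  # raw second moments about the origin
  ixx <- sum((y^2 + y * yn + yn^2) * cross) / 12
  iyy <- sum((x^2 + x * xn + xn^2) * cross) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cross) / 24
  s <- sign(a)
  list(
    area = abs(a), centroid = c(cx, cy),
    # covariance of the uniform distribution over the polygon interior
    cov = matrix(c(
      s * iyy / a - cx^2, s * ixy / a - cx * cy,
      s * ixy / a - cx * cy, s * ixx / a - cy^2), 2L, 2L)
  )
}

# eccentricity of the equivalent-covariance ellipse
.polygonEccentricity <- function(poly) {
  ev <- eigen(.polygonMoments(poly)$cov, symmetric = TRUE, only.values = TRUE)$values
  lam <- sort(pmax(ev, 0), decreasing = TRUE)
  if (lam[1L] <= 0) return(0)
  sqrt(max(0, 1 - lam[2L] / lam[1L]))
}

.polygonSolidity <- function(poly) {
  poly <- .asRing(poly)
  hull <- poly[rev(grDevices::chull(poly[, 1L], poly[, 2L])), , drop = FALSE]
  ha <- .polygonArea(hull)
  if (ha <= 0) return(NA_real_)
  min(.polygonArea(poly) / ha, 1)
}

# Even-odd rule point-in-polygon test, vectorized over query points.
# Points exactly on an edge may fall on either side; callers that need
# inclusive behaviour should not rely on boundary points.
.pointsInPolygon <- function(px, py, poly) {
  poly <- .asRing(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Sutherland-Hodgman clipping of an arbitrary subject polygon against a
# CONVEX clip polygon. Returns NULL when the intersection is empty.
.clipPolygonConvex <- function(subject, clip) {
  subject <- .asRing(subject)
  clip <- .asRing(clip)
  if (.polygonSignedArea(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3L) return(NULL)
    a <- clip[e, ]; b <- clip[if (e == nc) 1L else e + 1L, ]
    # inside = left of directed edge a->b (clip is counter-clockwise in y-down
    # sign convention after orientation fix above)
    side <- function(p) (b[1L] - a[1L]) * (p[, 2L] - a[2L]) -
      (b[2L] - a[2L]) * (p[, 1L] - a[1L])
    s <- side(out)
    keep <- s >= 0
    res <- list()
    n <- nrow(out)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      p1 <- out[i, ]; p2 <- out[j, ]
      if (keep[i]) res[[length(res) + 1L]] <- p1
      if (keep[i] != keep[j]) {
        t <- s[i] / (s[i] - s[j])
        res[[length(res) + 1L]] <- p1 + t * (p2 - p1)
      }
    }
    if (length(res) < 3L) return(NULL)
    out <- do.call(rbind, res)
    # drop consecutive duplicates introduced by touching vertices
    d <- c(TRUE, rowSums(abs(diff(out))) > 1e-9)
    out <- out[d, , drop = FALSE]
    if (nrow(out) >= 2L &&
        sum(abs(out[1L, ] - out[nrow(out), ])) < 1e-9)
      out <- out[-nrow(out), , drop = FALSE]
    if (nrow(out) < 3L) return(NULL)
  }
  out
}

# Integer pixel indices (row = y + 1, col = x + 1) whose centers fall inside
# the polygon; bounded by the image extent when width/height are given.
.rasterizePolygon <- function(poly, width = NULL, height = NULL) {
  poly <- .asRing(poly)
  x0 <- max(0L, floor(min(poly[, 1L])))
  x1 <- ceiling(max(poly[, 1L]))
  y0 <- max(0L, floor(min(poly[, 2L])))
  y1 <- ceiling(max(poly[, 2L]))
  if (!is.null(width)) x1 <- min(x1, width - 1L)
  if (!is.null(height)) y1 <- min(y1, height - 1L)
  if (x1 < x0 || y1 < y0) return(cbind(row = integer(0), col = integer(0)))
  gx <- seq.int(x0, x1); gy <- seq.int(y0, y1)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  inside <- .pointsInPolygon(px, py, poly)
  cbind(row = py[inside] + 1L, col = px[inside] + 1L)
}

# Exact area of the intersection ("lens") of two discs with radii r1, r2 and
# center distance d; used as a conservative bound on polygon overlap.
.circleLensArea <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos(pmin(1, pmax(-1, (d^2 + r1^2 - r2^2) / (2 * d * r1))))
  a2 <- r2^2 * acos(pmin(1, pmax(-1, (d^2 + r2^2 - r1^2) / (2 * d * r2))))
  s <- 0.5 * sqrt(max(0, (-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2)))
  a1 + a2 - s
}

# axis-aligned rectangular ring helper
.rectRing <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}
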