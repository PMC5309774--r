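# Small geometric utilities shared across modules.

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# Rodrigues rotation matrix: angle in degrees about unit axis
.rotationAbout <- function(axis, angleDeg) {
  u <- .unit(axis)
  th <- .deg2rad(angleDeg)
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Least-squares plane through points (N x 3): returns centroid, unit normal
# and the two in-plane basis vectors (from the SVD of the centered cloud).
.fitPlane <- function(p) {
  ctr <- colMeans(p)
  s <- svd(sweep(p, 2L, ctr))
  list(centroid = ctr, normal = s$v[, 3L], e1 = s$v[, 1L], e2 = s$v[, 2L])
}

# Shoelace area of a 2D polygon given as an (ordered) N x 2 matrix.
.polygonArea <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(p[, 1L] * p[i2, 2L] - p[i2, 1L] * p[, 2L])) / 2
}

# Sutherland-Hodgman clipping of polygon `subject` by convex polygon `clip`
# (both counter-clockwise N x 2). Returns the intersection polygon (M x 2,
# possibly 0 rows).
.clipConvex <- function(subject, clip) {
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (is.null(out) || nrow(out) == 0L) return(matrix(numeric(0), 0L, 2L))
    a <- clip[i, ]
    b <- clip[if (i == n) 1L else i + 1L, ]
    edge <- b - a
    inside <- function(p) edge[1L] * (p[2L] - a[2L]) - edge[2L] * (p[1L] - a[1L]) >= -1e-12
    inp <- out
    out <- matrix(numeric(0), 0L, 2L)
    m <- nrow(inp)
    for (j in seq_len(m)) {
      cur <- inp[j, ]
      prv <- inp[if (j == 1L) m else j - 1L, ]
      curIn <- inside(cur)
      prvIn <- inside(prv)
      if (curIn) {
        if (!prvIn) out <- rbind(out, .segIntersect(prv, cur, a, b))
        out <- rbind(out, cur)
      } else if (prvIn) {
        out <- rbind(out, .segIntersect(prv, cur, a, b))
      }
    }
  }
  out
}

# Intersection of segment p1-p2 with the infinite line a-b.
.segIntersect <- function(p1, p2, a, b) {
  d1 <- p2 - p1
  d2 <- b - a
  den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  if (abs(den) < 1e-14) return(p2)
  t <- ((a[1L] - p1[1L]) * d2[2L] - (a[2L] - p1[2L]) * d2[1L]) / den
  p1 + t * d1
}

# Counter-clockwise convex hull of 2D points, as an ordered matrix.
.hull2d <- function(p) {
  idx <- grDevices::chull(p[, 1L], p[, 2L])  # chull returns clockwise
  h <- p[rev(idx), , drop = FALSE]
  h
}

# Moving-average smoothing with window truncation at the ends.
.movingAverage <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(j)
    mean(x[max(1L, j - half):min(n, j + half)]), numeric(1))
}
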