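# Independent reference implementations used as oracles. These stay
# deliberately separate from the package's code paths: rotations are built
# and decomposed through unit quaternions, never through the package's
# Rodrigues/trace formulas.

# quaternion (w, x, y, z) -> rotation matrix
quatToMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rotation matrix -> quaternion, Shepperd's method (case split on the
# largest diagonal term keeps it stable over the whole angle range)
matrixToQuat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

# quaternion-route decomposition of a rotation: angle (deg) and unit axis
quatDecompose <- function(R) {
  q <- matrixToQuat(R)
  ang <- 2 * atan2(sqrt(sum(q[2:4]^2)), q[1])
  ax <- if (sqrt(sum(q[2:4]^2)) < 1e-12) c(0, 0, 1)
        else q[2:4] / sqrt(sum(q[2:4]^2))
  list(angle = ang * 180 / pi, axis = ax)
}

randomUnitVector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# A random screw motion built through the quaternion route: returns the
# generating parameters and the 3x3 + 3 transform they imply.
randomScrew <- function(angleRange = c(1, 179)) {
  u <- randomUnitVector()
  ang <- stats::runif(1, angleRange[1], angleRange[2])
  p <- stats::rnorm(3, sd = 20)
  h <- stats::rnorm(1, sd = 5)
  half <- ang * pi / 360
  R <- quatToMatrix(c(cos(half), sin(half) * u))
  tr <- as.vector((diag(3) - R) %*% p) + h * u
  list(axis = u, angle = ang, point = p, pitch = h, R = R, t = tr)
}

pointToLineDistance <- function(x, linePoint, lineDir) {
  # cross-product form avoids cancellation for points far along the line
  d <- x - linePoint
  cr <- c(d[2] * lineDir[3] - d[3] * lineDir[2],
          d[3] * lineDir[1] - d[1] * lineDir[3],
          d[1] * lineDir[2] - d[2] * lineDir[1])
  sqrt(sum(cr^2)) / sqrt(sum(lineDir^2))
}
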