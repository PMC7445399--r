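# Internal geometry and angle helpers.

# Wrap angles (degrees) to (-180, 180].
wrapAngle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

# Shortest signed angular difference a - b on the circle, in (-180, 180].
angDiff <- function(a, b) wrapAngle(a - b)

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product for n x 3 matrices.
.crossRows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.rowNorm <- function(m) sqrt(rowSums(m^2))

# NeRF (natural extension reference frame) placement: position atom D given
# positions of A, B, C, the bond length C-D, the angle B-C-D (degrees) and the
# torsion A-B-C-D (degrees, IUPAC sign).
placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate reference frame in atom placement")
  n <- n / nn
  m <- .cross3(n, bc)
  # columns: bc, m, n map local coords to lab frame
  c + c(bc[1] * d2[1] + m[1] * d2[2] + n[1] * d2[3],
        bc[2] * d2[1] + m[2] * d2[2] + n[2] * d2[3],
        bc[3] * d2[1] + m[3] * d2[2] + n[3] * d2[3])
}

# Random rigid transform (rotation + translation) of an n x 3 matrix; used in
# invariance tests and exported nowhere.
rigidTransform <- function(xyz, rot = NULL, shift = NULL) {
  if (is.null(rot)) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    rot <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
      3, 3, byrow = TRUE)
  }
  if (is.null(shift)) shift <- stats::rnorm(3, sd = 5)
  sweep(xyz %*% t(rot), 2, shift, "+")
}

.fmtNum <- function(x, digits = 6) formatC(x, format = "f", digits = digits)
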