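# Independent oracles used across the suite. These deliberately use
# different constructions from the package implementation.

# Dihedral by projection onto the plane perpendicular to the central bond:
# the signed angle from the projected p2->p1 bond image to the projected
# p3->p4 bond, measured around the bond axis.
oracleDihedral <- function(p1, p2, p3, p4) {
  axis <- p3 - p2
  axis <- axis / sqrt(sum(axis^2))
  u <- (p1 - p2) - sum((p1 - p2) * axis) * axis
  v <- (p4 - p3) - sum((p4 - p3) * axis) * axis
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sum(axis * cr), sum(u * v)) * 180 / pi
}

# Random non-degenerate dihedral quadruple.
randomQuadruple <- function() {
  repeat {
    p <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    if (sqrt(sum(n1^2)) > 0.1 && sqrt(sum(n2^2)) > 0.1) return(p)
  }
}

# Toroidal nearest-mean assignment: the population oracle for well-separated
# mixtures.
nearestMeanAssign <- function(values, means) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (is.null(dim(means))) means <- matrix(means, ncol = 1)
  d2 <- matrix(0, nrow(values), nrow(means))
  for (j in seq_len(ncol(values))) {
    dif <- abs(outer(values[, j], means[, j], "-")) %% 360
    dif <- pmin(dif, 360 - dif)
    d2 <- d2 + dif^2
  }
  max.col(-d2)
}

# Random rigid transform of an n x 3 matrix (quaternion rotation + shift).
randomRigid <- function(xyz) {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
  sweep(xyz %*% t(R), 2, stats::rnorm(3, sd = 10), "+")
}

# Mirror an n x 3 coordinate matrix through the xy plane.
mirrorZ <- function(xyz) {
  xyz[, 3] <- -xyz[, 3]
  xyz
}

registryNames <- function() names(glycanRegistry())

`%||%` <- function(a, b) if (is.null(a)) b else a
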