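# Pyranose ring pucker classification (Cremer-Pople) and (1-6)-arm state
# classification.

# Cremer-Pople puckering coordinates of one six-membered ring.
# xyz: 6 x 3 matrix ordered O5, C1, C2, C3, C4, C5 (j = 1..6).
.cremerPopleOne <- function(xyz) {
  ctr <- colMeans(xyz)
  r <- sweep(xyz, 2, ctr)
  j <- 0:5
  Rp <- colSums(r * sin(2 * pi * j / 6))
  Rpp <- colSums(r * cos(2 * pi * j / 6))
  n <- .cross3(Rp, Rpp)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8) stop("degenerate ring geometry (collapsed mean plane)")
  n <- n / nn
  z <- as.numeric(r %*% n)
  q2c <- sqrt(1 / 3) * sum(z * cos(4 * pi * j / 6))
  q2s <- -sqrt(1 / 3) * sum(z * sin(4 * pi * j / 6))
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  q2 <- sqrt(q2c^2 + q2s^2)
  Q <- sqrt(q2^2 + q3^2)
  c(Q = Q,
    theta = if (Q > 0) atan2(q2, q3) * 180 / pi else NA_real_,
    phi = if (q2 > 0) wrapAngle(atan2(q2s, q2c) * 180 / pi) else NA_real_)
}

#' Cremer-Pople puckering coordinates
#'
#' Total puckering amplitude Q (Angstrom), polar angle theta and azimuth phi
#' (degrees) of a six-membered ring, with the ring oxygen as the first atom
#' of the traversal (the pyranose convention: O5, C1, C2, C3, C4, C5). A
#' theta of 0 is the 4C1 chair, 180 the 1C4 chair and 90 the boat/twist-boat
#' band.
#'
#' @param xyz a 6 x 3 coordinate matrix, or a 6 x 3 x n array for a
#'   trajectory.
#' @param origin index (1-6) of the ring oxygen within the supplied atom
#'   order; the ring is rolled to the canonical origin before analysis so
#'   that the result does not depend on where the traversal started.
#' @return named vector (Q, theta, phi), or an n x 3 matrix for arrays.
#' @export
cremerPople <- function(xyz, origin = 1L) {
  roll <- function(m) if (origin == 1L) m else
    m[c(origin:6, seq_len(origin - 1L)), , drop = FALSE]
  if (length(dim(xyz)) == 2L) return(.cremerPopleOne(roll(xyz)))
  t(apply(xyz, 3, function(m) .cremerPopleOne(roll(m))))
}

#' Classify pyranose ring pucker per frame
#'
#' Canonical classification through Cremer-Pople coordinates: theta <= 45
#' degrees is the 4C1 chair, theta >= 135 the 1C4 chair, anything between
#' (boats, twist-boats) or rings of negligible amplitude is \code{other}.
#' The two ring torsions t1 = C1-C2-C3-C4 and t2 = C2-C3-C4-C5 are reported
#' alongside for projection-style pucker plots.
#'
#' @param ring 6 x 3 x n coordinate array (or 6 x 3 matrix for one frame)
#'   ordered O5, C1, C2, C3, C4, C5 (see \code{origin}).
#' @param origin index of the ring oxygen in the supplied order (default 1).
#' @param ampMin minimum puckering amplitude (Angstrom) below which a ring is
#'   \code{other} regardless of theta (default 0.1).
#' @return a [PuckerSeries-class].
#' @export
classifyPucker <- function(ring, origin = 1L, ampMin = 0.1) {
  if (length(dim(ring)) == 2L) ring <- array(ring, c(dim(ring), 1L))
  if (origin != 1L) {
    ord <- c(origin:6, seq_len(origin - 1L))
    ring <- ring[ord, , , drop = FALSE]
  }
  nf <- dim(ring)[3]
  cp <- t(apply(ring, 3, .cremerPopleOne))
  t1 <- dihedralAngle(t(ring[2, , , drop = TRUE]), t(ring[3, , , drop = TRUE]),
                      t(ring[4, , , drop = TRUE]), t(ring[5, , , drop = TRUE]))
  t2 <- dihedralAngle(t(ring[3, , , drop = TRUE]), t(ring[4, , , drop = TRUE]),
                      t(ring[5, , , drop = TRUE]), t(ring[6, , , drop = TRUE]))
  if (nf == 1L) { t1 <- t1[1]; t2 <- t2[1] }
  st <- rep("other", nf)
  ok <- cp[, "Q"] >= ampMin & is.finite(cp[, "theta"])
  st[ok & cp[, "theta"] <= 45] <- "4C1"
  st[ok & cp[, "theta"] >= 135] <- "1C4"
  new("PuckerSeries",
      states = factor(st, levels = c("4C1", "1C4", "other")),
      t1 = t1, t2 = t2, Q = cp[, "Q"], theta = cp[, "theta"],
      phi = cp[, "phi"])
}

#' Chair assignment from the two-torsion projection
#'
#' The sign-quadrant heuristic behind ring-flip projection maps: a 4C1 chair
#' has t1 = C1-C2-C3-C4 negative and t2 = C2-C3-C4-C5 positive, the 1C4
#' chair the reverse; any other sign combination (or near-zero torsions) is
#' \code{other}. A documented cross-check of [classifyPucker()], not the
#' canonical classifier.
#'
#' @param t1,t2 numeric ring torsions in degrees.
#' @param minAbs torsions below this magnitude are treated as unresolved
#'   (default 10 degrees).
#' @return factor with levels 4C1, 1C4, other.
#' @export
puckerQuadrant <- function(t1, t2, minAbs = 10) {
  st <- rep("other", length(t1))
  st[t1 < -minAbs & t2 > minAbs] <- "4C1"
  st[t1 > minAbs & t2 < -minAbs] <- "1C4"
  factor(st, levels = c("4C1", "1C4", "other"))
}

#' @describeIn PuckerSeries-class per-frame states accessor
#' @param x a PuckerSeries
#' @export
puckerStates <- function(x) x@states

#' Pucker state populations
#'
#' @param series a [PuckerSeries-class] (or a factor of states).
#' @return named numeric vector of state fractions (summing to 1 exactly),
#'   restricted to occupied states.
#' @export
puckerPopulations <- function(series) {
  st <- if (is(series, "PuckerSeries")) series@states else series
  if (!length(st)) stop("empty pucker series")
  tab <- table(st)
  out <- as.numeric(tab) / length(st)
  names(out) <- names(tab)
  out[out > 0]
}

setMethod("show", "PuckerSeries", function(object) {
  cat(sprintf("PuckerSeries: %d frames\n", length(object@states)))
  print(round(puckerPopulations(object), 4))
})

# Extract the 6 x 3 x n ring-atom array of one residue.
ringCoordinates <- function(ensemble, map, node) {
  names6 <- c("O5", "C1", "C2", "C3", "C4", "C5")
  idx <- vapply(names6, function(a) resolveAtom(map, node, a), integer(1))
  ensemble@coords[idx, , , drop = FALSE]
}

.armPath <- function(tree) {
  edges <- tree@edges
  childAt <- function(id, pos) {
    e <- edges[edges$parent_id == id & edges$parent_pos == pos, ]
    if (nrow(e)) e$child_id[1] else NA_integer_
  }
  root <- tree@root_id
  chito2 <- childAt(root, 4L)
  if (is.na(chito2)) stop("tree has no beta(1-4)-linked second GlcNAc")
  bman <- childAt(chito2, 4L)
  if (is.na(bman) || .nodeName(tree, bman) != "Man")
    stop("tree has no core beta-mannose")
  man6 <- childAt(bman, 6L)
  if (is.na(man6) || .nodeName(tree, man6) != "Man")
    stop("tree contains no Man-a(1-6)-Man linkage; no (1-6) arm to classify")
  # arm terminus: follow the deepest chain from the alpha(1-6) mannose
  term <- man6
  repeat {
    ch <- .childrenOf(tree, term)
    if (!nrow(ch)) break
    depth <- vapply(ch$child_id, function(c) .subtreeDepth(tree, c), 1L)
    term <- ch$child_id[order(-depth, ch$parent_pos)][1]
  }
  list(root = root, chito2 = chito2, bman = bman, man6 = man6, term = term)
}

#' Classify the (1-6)-arm conformational state per frame
#'
#' Labels every frame as \code{open}, \code{front_fold}, \code{back_fold} or
#' \code{rotated_core}:
#' \itemize{
#'   \item \code{rotated_core} (checked first, taking precedence) when the
#'     core Man-beta(1-4)-GlcNAc psi deviates more than \code{psiTol} from
#'     its reference mode -- the rotation of the whole trimannose group
#'     relative to the chitobiose;
#'   \item otherwise \code{open} when the distance from the arm-terminus
#'     ring centroid to the chitobiose centroid exceeds \code{dOpen};
#'   \item otherwise \code{front_fold} or \code{back_fold} by the side of
#'     the root-GlcNAc ring mean plane the arm centroid occupies. The plane
#'     normal follows the right-hand rule around the ring traversal
#'     O5 -> C1 -> C2 of the root GlcNAc; the positive side is "front".
#' }
#'
#' @param ensemble a [GlycanEnsemble-class].
#' @param map an [AtomMap-class].
#' @param tree a [GlycanTree-class] containing a Man-a(1-6)-Man linkage.
#' @param dOpen open/folded boundary distance in Angstrom (default 8).
#' @param psiTol rotated-core deviation threshold in degrees (default 90).
#' @param psiRef reference psi mode in degrees; default: KDE mode of the
#'   observed core psi series.
#' @return an [ArmStateSeries-class].
#' @export
classifyArmState <- function(ensemble, map, tree, dOpen = 8, psiTol = 90,
                             psiRef = NULL) {
  path <- .armPath(tree)
  nf <- nFrames(ensemble)
  armRing <- ringCoordinates(ensemble, map, path$term)
  rootRing <- ringCoordinates(ensemble, map, path$root)
  chitoRing2 <- ringCoordinates(ensemble, map, path$chito2)

  armC <- t(apply(armRing, 3, colMeans))
  rootC <- t(apply(rootRing, 3, colMeans))
  chitoC <- (rootC + t(apply(chitoRing2, 3, colMeans))) / 2
  dist <- sqrt(rowSums((armC - chitoC)^2))

  signed <- numeric(nf)
  for (f in seq_len(nf)) {
    r <- sweep(rootRing[, , f], 2, colMeans(rootRing[, , f]))
    j <- 0:5
    n <- .cross3(colSums(r * sin(2 * pi * j / 6)),
                 colSums(r * cos(2 * pi * j / 6)))
    n <- n / sqrt(sum(n^2))
    signed[f] <- sum((armC[f, ] - rootC[f, ]) * n)
  }

  # core Man-beta(1-4)-GlcNAc psi
  psi <- dihedralAngle(
    t(ensemble@coords[resolveAtom(map, path$bman, "C1"), , , drop = TRUE]),
    t(ensemble@coords[resolveAtom(map, path$chito2, "O4"), , , drop = TRUE]),
    t(ensemble@coords[resolveAtom(map, path$chito2, "C4"), , , drop = TRUE]),
    t(ensemble@coords[resolveAtom(map, path$chito2, "C3"), , , drop = TRUE]))
  if (nf == 1L) psi <- psi[1]
  if (is.null(psiRef)) {
    kd <- kdeLandscape(psi, bandwidth = 10, gridSize = 180)
    psiRef <- kd$x[which.max(kd$grid)]
  }

  om <- tryCatch({
    o <- dihedralAngle(
      t(ensemble@coords[resolveAtom(map, path$bman, "O6"), , , drop = TRUE]),
      t(ensemble@coords[resolveAtom(map, path$bman, "C6"), , , drop = TRUE]),
      t(ensemble@coords[resolveAtom(map, path$bman, "C5"), , , drop = TRUE]),
      t(ensemble@coords[resolveAtom(map, path$bman, "O5"), , , drop = TRUE]))
    if (nf == 1L) o <- o[1]
    omegaRotamer(o)
  }, error = function(e) factor(rep(NA, nf), levels = c("gg", "gt", "tg")))

  st <- ifelse(abs(angDiff(psi, psiRef)) > psiTol, "rotated_core",
               ifelse(dist > dOpen, "open",
                      ifelse(signed > 0, "front_fold", "back_fold")))
  new("ArmStateSeries",
      states = factor(st, levels = c("open", "front_fold", "back_fold",
                                     "rotated_core")),
      distance = dist, signed_offset = signed, psi_core = psi,
      omega_rotamer = om,
      params = list(dOpen = dOpen, psiTol = psiTol, psiRef = psiRef))
}

#' @describeIn ArmStateSeries-class per-frame states accessor
#' @param x an ArmStateSeries
#' @export
armStates <- function(x) x@states

#' Arm state populations
#' @param series an [ArmStateSeries-class].
#' @return named fractions over all four states (summing to 1 exactly).
#' @export
armStatePopulations <- function(series) {
  st <- series@states
  tab <- table(st)
  stats::setNames(as.numeric(tab) / length(st), names(tab))
}

setMethod("show", "ArmStateSeries", function(object) {
  cat(sprintf("ArmStateSeries: %d frames (dOpen = %.1f A)\n",
              length(object@states), object@params$dOpen))
  print(round(armStatePopulations(object), 4))
})
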