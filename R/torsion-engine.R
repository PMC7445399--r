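# Dihedral computation and torsion-series extraction over ensembles.

#' Dihedral angle of four points
#'
#' IUPAC sign convention: sighting from \code{p2} towards \code{p3}, the
#' torsion is positive when the far bond (\code{p3}-\code{p4}) is rotated
#' clockwise from the near bond (\code{p2}-\code{p1}). Inputs may be single
#' points (length-3 vectors) or \code{n x 3} matrices for a whole trajectory.
#'
#' @param p1,p2,p3,p4 length-3 numeric vectors, or matrices with one row per
#'   frame.
#' @return angle(s) in degrees in (-180, 180].
#' @examples
#' dihedralAngle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(-1, 0, 1))  # 180
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  if (is.null(dim(p1))) {
    p1 <- matrix(p1, 1); p2 <- matrix(p2, 1)
    p3 <- matrix(p3, 1); p4 <- matrix(p4, 1)
    scalar <- TRUE
  } else scalar <- FALSE
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .crossRows(b1, b2)
  n2 <- .crossRows(b2, b3)
  ln1 <- .rowNorm(n1); ln2 <- .rowNorm(n2)
  bad <- ln1 < 1e-10 | ln2 < 1e-10
  if (any(bad))
    stop("degenerate dihedral geometry (collinear atoms) at frame(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  b2u <- b2 / .rowNorm(b2)
  y <- rowSums(.crossRows(n1, n2) * b2u)
  x <- rowSums(n1 * n2)
  out <- wrapAngle(atan2(y, x) * 180 / pi)
  if (scalar) out[1] else out
}

#' Extract torsion angle series from an ensemble
#'
#' Computes, for every requested torsion definition, the per-frame dihedral
#' over all frames of the ensemble, using an [AtomMap-class] to resolve atoms.
#'
#' @param ensemble a [GlycanEnsemble-class].
#' @param map an [AtomMap-class] covering the atoms the definitions need.
#' @param definitions data.frame from [torsionDefinitions()]; may be a subset
#'   of rows.
#' @return a [TorsionSet-class]; columns of \code{torsionValues()} are named
#'   by the definition labels.
#' @seealso [circularSummary()], [clusterTorsions()]
#' @export
torsionSeries <- function(ensemble, map, definitions) {
  stopifnot(is(ensemble, "GlycanEnsemble"), is(map, "AtomMap"))
  xyz <- ensemble@coords
  nf <- dim(xyz)[3]
  vals <- matrix(NA_real_, nf, nrow(definitions),
                 dimnames = list(NULL, definitions$label))
  for (i in seq_len(nrow(definitions))) {
    d <- definitions[i, ]
    idx <- vapply(1:4, function(k)
      resolveAtom(map, d[[paste0("res", k)]], d[[paste0("atom", k)]]),
      integer(1))
    pts <- lapply(idx, function(j) t(xyz[j, , , drop = TRUE]))
    if (nf == 1L) pts <- lapply(pts, function(p) matrix(p, 1, 3))
    vals[, i] <- tryCatch(
      dihedralAngle(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
      error = function(e) stop("torsion ", d$label, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  new("TorsionSet", values = vals, definitions = definitions)
}

#' @describeIn TorsionSet-class frame-by-torsion value matrix (degrees)
#' @param x a TorsionSet
#' @export
torsionValues <- function(x) x@values

#' @describeIn TorsionSet-class torsion definition table
#' @export
torsionInfo <- function(x) x@definitions

setMethod("show", "TorsionSet", function(object) {
  cat(sprintf("TorsionSet: %d frames x %d torsions\n",
              nrow(object@values), ncol(object@values)))
  if (ncol(object@values))
    cat(" ", paste(utils::head(colnames(object@values), 4), collapse = ", "),
        if (ncol(object@values) > 4) "..." else "", "\n")
})

#' Export a torsion set as a long-format table
#'
#' @param x a [TorsionSet-class].
#' @return data.frame with columns frame, linkage, torsion, value.
#' @export
torsionLong <- function(x) {
  defs <- x@definitions
  nf <- nrow(x@values)
  data.frame(
    frame = rep(seq_len(nf), ncol(x@values)),
    linkage = rep(defs$linkage, each = nf),
    torsion = rep(defs$torsion, each = nf),
    value = as.vector(x@values))
}

#' Classify omega rotamers (gg / gt / tg)
#'
#' Assigns each omega angle to the nearest of the three staggered rotamers of
#' a 1-6 linkage: gg at -60, gt at +60 and tg at 180 degrees.
#'
#' @param omega numeric vector of omega angles in degrees.
#' @return factor with levels gg, gt, tg.
#' @export
omegaRotamer <- function(omega) {
  ref <- c(gg = -60, gt = 60, tg = 180)
  d <- vapply(ref, function(r) abs(angDiff(omega, r)), numeric(length(omega)))
  if (length(omega) == 1L) d <- matrix(d, 1)
  factor(names(ref)[max.col(-d)], levels = names(ref))
}
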