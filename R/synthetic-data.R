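# Ground-truth-known synthetic inputs: von Mises torsion mixtures,
# dwell-structured state-flip series, and Cartesian builders (rings,
# linked-residue ensembles, arm-state scaffolds) via internal-coordinate
# construction. Every generator returns its ground truth alongside the data.

#' Sample a (possibly multi-dimensional) von Mises torsion mixture
#'
#' Draws per-frame torsion values from a mixture of independent von Mises
#' components, the synthetic stand-in for the multi-modal periodic torsion
#' distributions of a simulated glycan linkage. The true component label of
#' every frame is returned with the data.
#'
#' @param spec list with elements \code{dimensions} (character),
#'   \code{components} (list of \code{list(mean, kappa, weight)}; \code{mean}
#'   has one entry per dimension), \code{n_frames} and \code{seed}.
#' @return list with \code{values} (n_frames x dimensions matrix, degrees),
#'   \code{labels} (true component per frame), \code{weights} (true weights)
#'   and \code{spec}.
#' @examples
#' spec <- list(dimensions = c("phi", "psi"),
#'              components = list(list(mean = c(60, 180), kappa = 50, weight = 0.7),
#'                                list(mean = c(-60, -120), kappa = 50, weight = 0.3)),
#'              n_frames = 1000, seed = 7)
#' mx <- sampleTorsionMixture(spec)
#' table(mx$labels) / 1000
#' @export
sampleTorsionMixture <- function(spec) {
  stopifnot(is.list(spec), length(spec$components) >= 1, spec$n_frames >= 1)
  w <- vapply(spec$components, function(cc) as.numeric(cc$weight), numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop("component weights must sum to 1")
  if (any(vapply(spec$components, function(cc) cc$kappa <= 0, logical(1))))
    stop("component concentrations must be positive")
  d <- length(spec$dimensions %||% spec$components[[1]]$mean)
  dims <- spec$dimensions %||% paste0("dim", seq_len(d))
  n <- as.integer(spec$n_frames)
  if (!is.null(spec$seed)) set.seed(as.integer(spec$seed))
  labels <- sample.int(length(w), n, replace = TRUE, prob = w)
  values <- matrix(NA_real_, n, d, dimnames = list(NULL, dims))
  for (k in seq_along(spec$components)) {
    idx <- which(labels == k)
    if (!length(idx)) next
    comp <- spec$components[[k]]
    mu <- rep_len(as.numeric(comp$mean), d)
    for (j in seq_len(d))
      values[idx, j] <- rvonmises(length(idx), mu[j], comp$kappa)
  }
  list(values = values, labels = labels, weights = w, spec = spec)
}

#' Dwell-structured two-state (or k-state) flip series
#'
#' Emulates ring-flip or arm-fold dynamics: a Markov chain whose dwell time
#' in state i is geometric with the requested mean, giving stationary
#' fractions proportional to the mean dwells (a 3:1 dwell ratio yields
#' 0.75/0.25).
#'
#' @param states character vector of state names.
#' @param meanDwell numeric vector of mean dwell lengths (frames) per state.
#' @param nFrames number of frames.
#' @param seed RNG seed.
#' @return list with \code{states} (factor series), \code{trueFractions}
#'   (stationary fractions implied by the dwells).
#' @export
sampleDwellSeries <- function(states, meanDwell, nFrames, seed = 1) {
  stopifnot(length(states) >= 2, length(meanDwell) == length(states),
            all(meanDwell >= 1), nFrames >= 1)
  set.seed(as.integer(seed))
  k <- length(states)
  out <- integer(nFrames)
  cur <- 1L
  i <- 1L
  while (i <= nFrames) {
    dwell <- 1L + stats::rgeom(1, 1 / meanDwell[cur])
    j <- min(nFrames, i + dwell - 1L)
    out[i:j] <- cur
    i <- j + 1L
    cur <- if (cur == k) 1L else cur + 1L
  }
  list(states = factor(states[out], levels = states),
       trueFractions = stats::setNames(meanDwell / sum(meanDwell), states))
}

# --- ring construction ------------------------------------------------------

.ringAtomNames <- c("O5", "C1", "C2", "C3", "C4", "C5")

# Synthesize a six-membered ring realizing exact Cremer-Pople coordinates.
# Atoms are placed clockwise in the xy projection so that the analysis normal
# (right-hand rule over the O5 -> C1 -> C2 traversal) is +z.
.ringFromCP <- function(Q, theta, phi, bondCC = 1.52, bondCO = 1.43) {
  j <- 0:5
  q2 <- Q * sin(theta * pi / 180)
  q3 <- Q * cos(theta * pi / 180)
  z <- sqrt(1 / 3) * q2 * cos(phi * pi / 180 + 4 * pi * j / 6) +
    sqrt(1 / 6) * q3 * (-1)^j
  lbar <- (4 * bondCC + 2 * bondCO) / 6
  dz2 <- mean(diff(c(z, z[1]))^2)
  if (lbar^2 <= dz2) stop("puckering amplitude too large for the bond lengths")
  rad <- sqrt(lbar^2 - dz2)
  ang <- -2 * pi * j / 6
  xyz <- cbind(rad * cos(ang), rad * sin(ang), z)
  rownames(xyz) <- .ringAtomNames
  xyz
}

#' Build an idealised pyranose ring at a requested pucker
#'
#' Constructs a six-atom ring (O5, C1..C5) whose Cremer-Pople coordinates
#' equal the request exactly; \code{[classifyPucker()]} on the result
#' recovers the requested state. Bond lengths are near the standard 1.52 A
#' C-C / 1.43 A C-O values (the ring radius is set from their mean, so the
#' CP coordinates, not the individual bonds, are exact).
#'
#' @param pucker \code{"4C1"} (theta = 0), \code{"1C4"} (theta = 180), or a
#'   list/vector with elements \code{Q} (Angstrom), \code{theta}, \code{phi}
#'   (degrees).
#' @param Q amplitude used for the chair shorthands (default 0.57 A, a
#'   typical pyranose value); must lie in (0, 1].
#' @param phi azimuth used for the shorthands (default 0).
#' @return list with \code{xyz} (6 x 3 named matrix) and \code{record} (the
#'   requested internal coordinates).
#' @export
buildPyranose <- function(pucker = "4C1", Q = 0.57, phi = 0) {
  if (is.character(pucker)) {
    theta <- switch(pucker, "4C1" = 0, "1C4" = 180,
                    stop("unknown pucker request: ", pucker))
    if (Q <= 0 || Q > 1)
      stop("amplitude must lie in (0, 1] Angstrom for chair requests")
    req <- c(Q = Q, theta = theta, phi = phi)
  } else {
    req <- c(Q = as.numeric(pucker[["Q"]] %||% Q),
             theta = as.numeric(pucker[["theta"]]),
             phi = as.numeric(pucker[["phi"]] %||% phi))
    if (req["Q"] <= 0 || req["Q"] > 1)
      stop("amplitude must lie in (0, 1] Angstrom")
  }
  xyz <- .ringFromCP(req["Q"], req["theta"], req["phi"])
  list(xyz = xyz, record = as.list(req))
}

#' Build a ring-pucker trajectory from a state series
#'
#' One ring per frame at theta = 0 (4C1), 180 (1C4) or 90 (boat band) by
#' state; used to test pucker classification and population recovery.
#'
#' @param states character or factor vector of per-frame states (levels among
#'   4C1, 1C4, other).
#' @param Q,phi passed to the ring builder.
#' @return 6 x 3 x n array of ring coordinates.
#' @export
buildPuckerEnsemble <- function(states, Q = 0.57, phi = 0) {
  states <- as.character(states)
  theta <- c("4C1" = 0, "1C4" = 180, "other" = 90)[states]
  if (anyNA(theta)) stop("states must be among 4C1, 1C4, other")
  out <- array(NA_real_, c(6, 3, length(states)),
               dimnames = list(.ringAtomNames, NULL, NULL))
  for (f in seq_along(states))
    out[, , f] <- .ringFromCP(Q, theta[f], phi)
  out
}

# --- residue templates and linked construction ------------------------------

# Exocyclic atom placements (NeRF references are template atom names):
# list(atom, C (bond ref), B (angle ref), A (dihedral ref), bond, angle, tor)
.exoDefs <- function(name) {
  base <- list(
    list("O2", "C2", "C1", "O5", 1.43, 109.5, 120),
    list("O3", "C3", "C2", "C1", 1.43, 109.5, 120),
    list("O4", "C4", "C3", "C2", 1.43, 109.5, 120))
  if (name == "Xyl") return(base)
  base <- c(base, list(list("C6", "C5", "C4", "C3", 1.52, 109.5, -120)))
  if (name == "Fuc") return(base)
  c(base, list(list("O6", "C6", "C5", "O5", 1.43, 109.5, 60)))
}

.templateResidue <- function(name) {
  ring <- .ringFromCP(0.57, 0, 0)
  xyz <- ring
  for (e in .exoDefs(name)) {
    p <- placeAtom(xyz[e[[4]], ], xyz[e[[3]], ], xyz[e[[2]], ],
                   e[[5]], e[[6]], e[[7]])
    xyz <- rbind(xyz, matrix(p, 1, dimnames = list(e[[1]])))
  }
  xyz
}

# Exact 3-point superposition (the point triples are congruent by
# construction): returns function mapping template coords to lab frame.
.frameFit <- function(fromPts, toPts) {
  frameOf <- function(p) {
    e1 <- p[2, ] - p[1, ]; e1 <- e1 / sqrt(sum(e1^2))
    v <- p[3, ] - p[1, ]
    e2 <- v - sum(v * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
    cbind(e1, e2, .cross3(e1, e2))
  }
  Ff <- frameOf(fromPts); Ft <- frameOf(toPts)
  R <- Ft %*% t(Ff)
  origin_from <- fromPts[1, ]; origin_to <- toPts[1, ]
  function(xyz) sweep(sweep(xyz, 2, origin_from) %*% t(R), 2, origin_to, "+")
}

#' Build a Cartesian ensemble of a small glycan at prescribed torsions
#'
#' Internal-coordinate chain construction: the root residue ring is built at
#' the canonical 4C1 chair, every child residue is attached through its
#' glycosidic linkage with the requested phi/psi (and omega for 1-6
#' linkages) torsions, and each ring is completed as a rigid ideal chair.
#' Measured dihedrals on the result equal the requested values to numerical
#' precision. No force-field relaxation is attempted; frames in which two
#' atoms come closer than 0.5 A are kept but flagged with a warning.
#'
#' @param tree a [GlycanTree-class] fragment (at most 4 residues).
#' @param torsions numeric matrix (frames x torsion labels) of requested
#'   values in degrees; column names must match
#'   \code{torsionDefinitions(tree)$label}. Missing torsions default to
#'   phi = -75, psi = 120, omega = 60.
#' @param dialect residue-naming dialect for the atom table (\code{"PDB"} or
#'   \code{"GLYCAM"}).
#' @return a [GlycanEnsemble-class] whose residues appear in tree node-id
#'   order.
#' @export
buildLinkedEnsemble <- function(tree, torsions = NULL, dialect = "PDB") {
  validObject(tree)
  ids <- sort(tree@nodes$id)
  if (length(ids) > 4L) stop("fragment builder supports at most 4 residues")
  defs <- torsionDefinitions(tree)
  nf <- if (is.null(torsions)) 1L else nrow(torsions)
  if (is.null(torsions))
    torsions <- matrix(numeric(), nf, 0)
  getTor <- function(label, frame, default) {
    if (label %in% colnames(torsions)) torsions[frame, label] else default
  }

  nodes <- tree@nodes
  templates <- lapply(stats::setNames(ids, ids), function(i)
    .templateResidue(nodes$name[match(i, nodes$id)]))
  atoms <- do.call(rbind, lapply(ids, function(i) data.frame(
    name = rownames(templates[[as.character(i)]]),
    resname = dialectResname(nodes$name[match(i, nodes$id)],
                             nodes$anomer[match(i, nodes$id)], dialect),
    resid = i, element = substr(rownames(templates[[as.character(i)]]), 1, 1),
    stringsAsFactors = FALSE)))
  natoms <- nrow(atoms)
  rowOf <- function(res, atom) which(atoms$resid == res & atoms$name == atom)

  # breadth-first order from the root
  order_ids <- tree@root_id
  repeat {
    nxt <- tree@edges$child_id[tree@edges$parent_id %in% order_ids &
                               !tree@edges$child_id %in% order_ids]
    if (!length(nxt)) break
    order_ids <- c(order_ids, nxt)
  }

  co <- array(NA_real_, c(natoms, 3L, nf))
  clash <- FALSE
  ringT <- .ringFromCP(0.57, 0, 0)
  for (f in seq_len(nf)) {
    xyz <- matrix(NA_real_, natoms, 3)
    placeResidueRing <- function(res, ringCoords) {
      tpl <- templates[[as.character(res)]]
      fit <- .frameFit(tpl[c("C1", "O5", "C2"), ], ringCoords[c("C1", "O5", "C2"), ])
      placed <- fit(tpl)
      for (a in rownames(tpl)) xyz[rowOf(res, a), ] <<- placed[a, ]
    }
    placeResidueRing(tree@root_id, ringT)
    for (id in order_ids[-1]) {
      e <- tree@edges[tree@edges$child_id == id, ]
      lk <- defs[defs$child_id == id, ]
      lab <- function(t) lk$label[lk$torsion == t]
      n <- e$parent_pos
      p <- e$parent_id
      On <- paste0("O", n); Cn <- paste0("C", n)
      Cnm1 <- paste0("C", n - 1L)
      if (n == 6L) {
        # re-place O6 with the requested omega (O6-C6-C5-O5)
        om <- getTor(lab("omega"), f, 60)
        xyz[rowOf(p, "O6"), ] <- placeAtom(
          xyz[rowOf(p, "O5"), ], xyz[rowOf(p, "C5"), ], xyz[rowOf(p, "C6"), ],
          1.43, 109.5, om)
      }
      psi <- getTor(lab("psi"), f, 120)
      phi <- getTor(lab("phi"), f, -75)
      c1 <- placeAtom(xyz[rowOf(p, Cnm1), ], xyz[rowOf(p, Cn), ],
                      xyz[rowOf(p, On), ], 1.41, 117, psi)
      o5 <- placeAtom(xyz[rowOf(p, Cn), ], xyz[rowOf(p, On), ], c1,
                      sqrt(sum((ringT["C1", ] - ringT["O5", ])^2)), 107, phi)
      c2 <- placeAtom(xyz[rowOf(p, On), ], o5, c1,
                      sqrt(sum((ringT["C1", ] - ringT["C2", ])^2)),
                      acos(sum((ringT["O5", ] - ringT["C1", ]) *
                               (ringT["C2", ] - ringT["C1", ])) /
                           (sqrt(sum((ringT["O5", ] - ringT["C1", ])^2)) *
                            sqrt(sum((ringT["C2", ] - ringT["C1", ])^2)))) * 180 / pi,
                      120)
      placeResidueRing(id, rbind(C1 = c1, O5 = o5, C2 = c2))
    }
    if (min(stats::dist(xyz)) < 0.5) clash <- TRUE
    co[, , f] <- xyz
  }
  if (clash)
    warning("clashing construction: atoms closer than 0.5 A in at least one frame")
  new("GlycanEnsemble", atoms = atoms, coords = co)
}

#' Build a labelled arm-state test scaffold
#'
#' Constructs a minimal Man3 core + arm geometry with the (1-6)-arm terminus
#' ring centroid placed at a requested distance from the chitobiose
#' centroid, on the requested side of the root-GlcNAc ring plane: in front
#' (+normal) for \code{front_fold}, behind for \code{back_fold}, in-plane
#' and far for \code{open}. The construction is a labelled classifier test
#' geometry (rings are rigid ideal chairs; residues are not covalently
#' joined).
#'
#' @param state \code{"open"}, \code{"front_fold"} or \code{"back_fold"}.
#' @param distance arm-terminus-to-chitobiose centroid distance in Angstrom
#'   (> 2).
#' @param nFrames number of (identical) frames to emit.
#' @return list with \code{ensemble} (a [GlycanEnsemble-class]),
#'   \code{tree} (the Man3 [GlycanTree-class]) and \code{truth} (the
#'   requested state).
#' @export
buildArmGeometry <- function(state = c("open", "front_fold", "back_fold"),
                             distance = 14, nFrames = 1L) {
  state <- match.arg(state)
  if (distance <= 2) stop("distance must exceed 2 Angstrom")
  tree <- parseGlycan("man3")
  nodes <- tree@nodes
  templates <- lapply(stats::setNames(sort(nodes$id), sort(nodes$id)),
                      function(i) .templateResidue(nodes$name[match(i, nodes$id)]))
  path <- .armPath(tree)
  # residue centroids: root GlcNAc at origin, chito2 along +x
  chitoCentroid <- c(2.5, 0, 0)
  offset <- switch(state,
    open = c(distance, 0, 0),
    front_fold = c(1, 0, sqrt(distance^2 - 1)),
    back_fold = c(1, 0, -sqrt(distance^2 - 1)))
  shifts <- stats::setNames(
    list(c(0, 0, 0), c(5, 0, 0), c(9, 0, 0), c(12, 4.5, 0),
         chitoCentroid + offset),
    as.character(c(path$root, path$chito2, path$bman,
                   setdiff(nodes$id, unlist(path[c("root", "chito2", "bman",
                                                   "term")])),
                   path$term)))
  atoms <- do.call(rbind, lapply(sort(nodes$id), function(i) data.frame(
    name = rownames(templates[[as.character(i)]]),
    resname = dialectResname(nodes$name[match(i, nodes$id)],
                             nodes$anomer[match(i, nodes$id)], "PDB"),
    resid = i, element = substr(rownames(templates[[as.character(i)]]), 1, 1),
    stringsAsFactors = FALSE)))
  one <- do.call(rbind, lapply(sort(nodes$id), function(i)
    sweep(templates[[as.character(i)]], 2, shifts[[as.character(i)]], "+")))
  co <- array(rep(as.numeric(one), nFrames), c(nrow(one), 3L, nFrames))
  list(ensemble = new("GlycanEnsemble", atoms = atoms, coords = co),
       tree = tree, truth = state)
}
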