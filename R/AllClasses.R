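#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' GlycanTree: a rooted labelled tree of monosaccharides
#'
#' Represents an N-glycan (or fragment) as a rooted tree. Nodes are
#' monosaccharides; edges are glycosidic linkages annotated with the child
#' anomeric carbon and the parent attachment position. The root is the
#' reducing-end residue (the Asn-linked GlcNAc in an intact N-glycan).
#'
#' @slot nodes data.frame with columns \code{id} (integer key), \code{name}
#'   (one of GlcNAc, Man, Gal, Fuc, Xyl, Glc, Sia), \code{anomer}
#'   (\code{"a"}/\code{"b"}), \code{series} (\code{"D"}/\code{"L"}; Fuc is
#'   L-series), \code{ring} (\code{"p"} for pyranose) and \code{supported}
#'   (logical; FALSE for parse-only residues such as sialic acid).
#' @slot edges data.frame with columns \code{parent_id}, \code{child_id},
#'   \code{child_pos} (anomeric carbon of the child, 1 or 2) and
#'   \code{parent_pos} (attachment position on the parent: 2, 3, 4 or 6).
#' @slot root_id integer id of the root node.
#'
#' @seealso [parseGlycan()], [serializeGlycan()], [torsionDefinitions()]
#' @export
setClass("GlycanTree",
  representation(nodes = "data.frame", edges = "data.frame",
                 root_id = "integer"))

.mono_vocab <- c("GlcNAc", "Man", "Gal", "Fuc", "Xyl", "Glc", "Sia")

setValidity("GlycanTree", function(object) {
  nd <- object@nodes; ed <- object@edges
  msgs <- character()
  need_n <- c("id", "name", "anomer", "series", "ring", "supported")
  if (!all(need_n %in% names(nd))) return("nodes is missing required columns")
  if (anyDuplicated(nd$id)) msgs <- c(msgs, "node ids must be unique")
  if (!all(nd$name %in% .mono_vocab))
    msgs <- c(msgs, paste("unknown monosaccharide name:",
                          paste(setdiff(nd$name, .mono_vocab), collapse = ", ")))
  if (!all(nd$anomer %in% c("a", "b"))) msgs <- c(msgs, "anomer must be 'a' or 'b'")
  if (!(object@root_id %in% nd$id)) msgs <- c(msgs, "root_id not among node ids")
  if (nrow(ed)) {
    if (!all(c(ed$parent_id, ed$child_id) %in% nd$id))
      msgs <- c(msgs, "edge endpoints must be node ids")
    if (object@root_id %in% ed$child_id) msgs <- c(msgs, "root must have no parent")
    if (anyDuplicated(ed$child_id))
      msgs <- c(msgs, "every non-root node must have exactly one parent")
    if (anyDuplicated(ed[, c("parent_id", "parent_pos")]))
      msgs <- c(msgs, "duplicate substitution at one parent position")
    if (!all(ed$parent_pos %in% c(2L, 3L, 4L, 6L)))
      msgs <- c(msgs, "parent_pos must be 2, 3, 4 or 6")
  }
  non_root <- setdiff(nd$id, object@root_id)
  if (!setequal(ed$child_id, non_root))
    msgs <- c(msgs, "tree must be connected (every non-root needs a parent edge)")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' GlycanEnsemble: a coordinate ensemble (topology + frames)
#'
#' Carrier for an atomistic coordinate ensemble: a fixed atom table and one
#' Cartesian coordinate set per frame, in Angstrom.
#'
#' @slot atoms data.frame with columns \code{name}, \code{resname},
#'   \code{resid}, \code{element}.
#' @slot coords numeric array of dimension \code{c(n_atoms, 3, n_frames)}.
#'
#' @seealso [readEnsemble()], [writeEnsemblePDB()], [mapAtoms()]
#' @export
setClass("GlycanEnsemble",
  representation(atoms = "data.frame", coords = "array"))

setValidity("GlycanEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L) return("coords must be an n_atoms x 3 x n_frames array")
  if (d[2] != 3L) return("second dimension of coords must be 3 (x, y, z)")
  if (d[1] != nrow(object@atoms)) return("coords/atom-table atom counts differ")
  if (d[3] < 1L) return("ensemble must contain at least one frame")
  if (!all(c("name", "resname", "resid") %in% names(object@atoms)))
    return("atoms needs name, resname, resid columns")
  TRUE
})

#' AtomMap: resolution of tree atoms onto ensemble atom indices
#'
#' Maps each (tree node, canonical atom name) pair needed for analysis onto an
#' atom index of a [GlycanEnsemble], under a residue/atom naming dialect.
#'
#' @slot dialect character; one of \code{"PDB"}, \code{"GLYCAM"},
#'   \code{"custom"}.
#' @slot residues data.frame mapping tree \code{node_id} to ensemble
#'   \code{resid}.
#' @slot index named integer vector; names are \code{"<node_id>:<atom>"}.
#' @export
setClass("AtomMap",
  representation(dialect = "character", residues = "data.frame",
                 index = "integer"))

#' TorsionSet: per-linkage torsion angle time series
#'
#' One column per torsion (phi/psi of every linkage, omega of 1-6 linkages),
#' one row per frame, all values in degrees wrapped to (-180, 180].
#'
#' @slot values numeric matrix (frames x torsions) with column names equal to
#'   the torsion labels in \code{definitions}.
#' @slot definitions data.frame of torsion definitions as returned by
#'   [torsionDefinitions()].
#' @seealso [torsionSeries()], [circularSummary()]
#' @export
setClass("TorsionSet",
  representation(values = "matrix", definitions = "data.frame"))

setValidity("TorsionSet", function(object) {
  v <- object@values
  if (nrow(object@definitions) != ncol(v))
    return("one definition row per value column required")
  if (length(v) && (max(v) > 180 || min(v) <= -180))
    return("torsion values must lie in (-180, 180]")
  TRUE
})

#' ConformerLandscape: clusters plus density landscape of a torsion subspace
#'
#' Result of density-based clustering of one or two periodic torsion series,
#' with per-cluster circular statistics, count-based populations, the noise
#' fraction, per-frame assignments, and (optionally) a wrapped-kernel density
#' grid over the torus.
#'
#' @slot dimensions character vector of torsion labels (length 1 or 2).
#' @slot clusters data.frame: \code{cluster} (1 = most populated),
#'   per-dimension circular \code{mean_*} and \code{sd_*} (degrees),
#'   \code{population} (fraction of all frames) and \code{n} (member count).
#' @slot noise_fraction fraction of frames assigned to no cluster.
#' @slot assignments integer per-frame cluster label (0 = noise).
#' @slot kde list with elements \code{grid}, \code{x}, \code{y},
#'   \code{bandwidth}, \code{cell_area}, or NULL if not computed.
#' @slot params list of clustering parameters used.
#' @seealso [clusterTorsions()], [kdeLandscape()], [assessConvergence()]
#' @export
setClass("ConformerLandscape",
  representation(dimensions = "character", clusters = "data.frame",
                 noise_fraction = "numeric", assignments = "integer",
                 kde = "listOrNULL", params = "list"))

setValidity("ConformerLandscape", function(object) {
  cl <- object@clusters
  tot <- sum(cl$population) + object@noise_fraction
  if (abs(tot - 1) > 1e-9) return("populations plus noise must sum to 1")
  if (nrow(cl) > 1 && any(diff(cl$population) > 1e-12))
    return("clusters must be ordered by descending population")
  TRUE
})

#' PuckerSeries: per-frame pyranose ring pucker classification
#'
#' @slot states factor with levels \code{4C1}, \code{1C4}, \code{other}.
#' @slot t1,t2 numeric; the ring torsions C1-C2-C3-C4 and C2-C3-C4-C5
#'   (degrees), the projection used in xylose ring-flip maps.
#' @slot Q,theta,phi numeric; Cremer-Pople total amplitude (Angstrom), polar
#'   angle theta and azimuth phi (degrees).
#' @seealso [classifyPucker()], [puckerPopulations()]
#' @export
setClass("PuckerSeries",
  representation(states = "factor", t1 = "numeric", t2 = "numeric",
                 Q = "numeric", theta = "numeric", phi = "numeric"))

setValidity("PuckerSeries", function(object) {
  n <- length(object@states)
  if (any(vapply(list(object@t1, object@t2, object@Q, object@theta),
                 length, 1L) != n))
    return("all per-frame vectors must have equal length")
  th <- object@theta[is.finite(object@theta)]
  if (length(th) && (min(th) < -1e-9 || max(th) > 180 + 1e-9))
    return("theta must lie in [0, 180]")
  TRUE
})

#' ArmStateSeries: per-frame (1-6)-arm conformational state
#'
#' @slot states factor with levels \code{open}, \code{front_fold},
#'   \code{back_fold}, \code{rotated_core}.
#' @slot distance numeric; arm-terminus ring centroid to chitobiose centroid
#'   distance (Angstrom).
#' @slot signed_offset numeric; signed distance of the arm centroid from the
#'   root-GlcNAc ring mean plane (positive = front).
#' @slot psi_core numeric; core Man-beta(1-4)-GlcNAc psi (degrees).
#' @slot omega_rotamer factor gg/gt/tg (or NA) of the alpha(1-6) linkage.
#' @slot params list of classification parameters used.
#' @seealso [classifyArmState()]
#' @export
setClass("ArmStateSeries",
  representation(states = "factor", distance = "numeric",
                 signed_offset = "numeric", psi_core = "numeric",
                 omega_rotamer = "factor", params = "list"))

#' GlycoblockSet: decomposition of a glycan into glycoblocks
#'
#' A partition of the residues of a [GlycanTree] into self-contained 3D
#' units ("glycoblocks"): the chitobiose core, the trimannose core, arm
#' GlcNAc units, terminal galactose units and Lewis-type termini, each
#' carrying its modifiers (core fucoses, the beta(1-2)-xylose).
#'
#' @slot blocks list of blocks; each block is a list with elements
#'   \code{type}, \code{members} (node ids), \code{modifiers} (character),
#'   \code{arm} (\code{"core"}, \code{"1-3"}, \code{"1-6"}) and
#'   \code{descriptor}.
#' @slot tree the decomposed [GlycanTree].
#' @seealso [decomposeGlycoblocks()], [predictPropensity()]
#' @export
setClass("GlycoblockSet",
  representation(blocks = "list", tree = "GlycanTree"))

setValidity("GlycoblockSet", function(object) {
  mem <- unlist(lapply(object@blocks, `[[`, "members"))
  if (anyDuplicated(mem)) return("block member sets must be disjoint")
  if (!setequal(mem, object@tree@nodes$id))
    return("blocks must cover every residue of the tree")
  TRUE
})
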