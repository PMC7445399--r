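# Coordinate-ensemble reading/writing and residue/atom-name mapping.

.readOneTraj <- function(topology, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    list(atoms = pdb$atom, xyz = pdb$xyz)
  } else if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    list(atoms = NULL, xyz = xyz)
  } else if (ext %in% c("xtc", "nc", "ncdf", "netcdf")) {
    stop("trajectory format '", ext, "' is not supported by this build; ",
         "convert to multi-model PDB or DCD")
  } else stop("unrecognised trajectory format: ", path)
}

#' Read a coordinate ensemble
#'
#' Reads a topology plus one or more trajectory files into a
#' [GlycanEnsemble-class]. Supported formats: multi-model PDB (topology and
#' frames in one file, or as frame files) and DCD (frames; atom order taken
#' from the PDB topology). Frames from multiple files are concatenated in the
#' given order. Coordinates are in Angstrom throughout.
#'
#' @param topology path to a PDB file defining the atom table (its own models
#'   contribute frames when \code{frames} is NULL).
#' @param frames optional character vector of trajectory paths (PDB or DCD).
#' @param stride keep every \code{stride}-th frame (default 1).
#' @param discard number of leading frames to drop before applying the stride
#'   (equilibration discard; default 0).
#' @return a [GlycanEnsemble-class].
#' @export
readEnsemble <- function(topology, frames = NULL, stride = 1L, discard = 0L) {
  if (!file.exists(topology)) stop("topology file not found: ", topology)
  top <- .readOneTraj(topology, topology)
  if (is.null(top$atoms)) stop("topology must be a PDB file: ", topology)
  atoms <- data.frame(
    name = trimws(top$atoms$elety),
    resname = trimws(top$atoms$resid),
    resid = top$atoms$resno,
    element = trimws(ifelse(is.na(top$atoms$elesy), "", top$atoms$elesy)),
    stringsAsFactors = FALSE)
  natoms <- nrow(atoms)
  xyz_list <- if (is.null(frames)) list(top$xyz) else lapply(frames, function(f) {
    if (!file.exists(f)) stop("trajectory file not found: ", f)
    tr <- .readOneTraj(topology, f)
    tr$xyz
  })
  for (m in xyz_list)
    if (ncol(m) != 3L * natoms)
      stop("atom-count mismatch between topology (", natoms, " atoms) and a ",
           "trajectory frame block (", ncol(m) / 3, " atoms)")
  xyz <- do.call(rbind, xyz_list)
  keep <- seq_len(nrow(xyz))
  if (discard > 0L) keep <- keep[-seq_len(min(discard, length(keep)))]
  if (stride > 1L) keep <- keep[seq(1L, length(keep), by = stride)]
  if (!length(keep)) stop("ensemble contains zero frames after discard/stride")
  xyz <- xyz[keep, , drop = FALSE]
  nf <- nrow(xyz)
  co <- array(NA_real_, c(natoms, 3L, nf))
  for (f in seq_len(nf)) co[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  new("GlycanEnsemble", atoms = atoms, coords = co)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble a [GlycanEnsemble-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEnsemblePDB <- function(ensemble, path) {
  stopifnot(is(ensemble, "GlycanEnsemble"))
  a <- ensemble@atoms
  nf <- dim(ensemble@coords)[3]
  xyz <- t(apply(ensemble@coords, 3, function(m) as.vector(t(m))))
  if (nf == 1L) xyz <- matrix(xyz, 1)
  bio3d::write.pdb(file = path, xyz = xyz, type = "ATOM",
                   resno = a$resid, resid = a$resname, elety = a$name,
                   chain = "A")
  invisible(path)
}

#' @describeIn GlycanEnsemble-class number of frames
#' @param ensemble a GlycanEnsemble
#' @export
nFrames <- function(ensemble) dim(ensemble@coords)[3]

#' @describeIn GlycanEnsemble-class atom table accessor
#' @export
atomTable <- function(ensemble) ensemble@atoms

#' @describeIn GlycanEnsemble-class coordinate array accessor
#'   (atoms x 3 x frames, Angstrom)
#' @export
ensembleCoords <- function(ensemble) ensemble@coords

setMethod("show", "GlycanEnsemble", function(object) {
  cat(sprintf("GlycanEnsemble: %d atoms, %d residues, %d frames\n",
              nrow(object@atoms), length(unique(object@atoms$resid)),
              dim(object@coords)[3]))
})

.dialects <- function() {
  if (is.null(.pkg_env$dialects)) {
    path <- system.file("extdata", "atom_dialects.json",
                        package = "glycanarch", mustWork = TRUE)
    .pkg_env$dialects <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .pkg_env$dialects
}

#' Expected residue name for a monosaccharide under a naming dialect
#'
#' @param name monosaccharide name (e.g. \code{"GlcNAc"}).
#' @param anomer \code{"a"} or \code{"b"}.
#' @param dialect \code{"PDB"} or \code{"GLYCAM"}.
#' @return character residue code (the canonical one for PDB; the
#'   terminal-position code, e.g. \code{"0YB"}, for GLYCAM).
#' @export
dialectResname <- function(name, anomer, dialect = "PDB") {
  d <- .dialects()
  if (dialect == "PDB") return(d$PDB[[name]][[anomer]][1])
  if (dialect == "GLYCAM")
    return(paste0("0", d$GLYCAM[[name]], toupper(anomer)))
  stop("unknown dialect: ", dialect)
}

.resnameMatches <- function(resname, name, anomer, dialect) {
  d <- .dialects()
  if (dialect == "custom") return(TRUE)
  if (dialect == "PDB") return(resname %in% d$PDB[[name]][[anomer]])
  if (dialect == "GLYCAM") {
    letter <- d$GLYCAM[[name]]
    grepl(paste0("^[0-9A-Za-z]{1,2}", letter, toupper(anomer), "$"), resname)
  } else stop("unknown dialect: ", dialect)
}

#' Map tree residues and atoms onto ensemble atom indices
#'
#' Residues of the ensemble (in order of first appearance) are matched to the
#' tree nodes (in node-id order, which is the order the package's own writers
#' emit) and residue names are validated against the chosen dialect. Every
#' atom needed by the supplied torsion definitions must resolve, otherwise an
#' error names the missing residue and atom.
#'
#' @param tree a [GlycanTree-class].
#' @param ensemble a [GlycanEnsemble-class].
#' @param dialect one of \code{"PDB"}, \code{"GLYCAM"}, \code{"custom"}
#'   (custom skips residue-name validation).
#' @param definitions torsion definitions whose atoms must resolve; default
#'   \code{torsionDefinitions(tree)}. Use \code{NULL} to skip the check.
#' @return an [AtomMap-class].
#' @export
mapAtoms <- function(tree, ensemble, dialect = c("PDB", "GLYCAM", "custom"),
                     definitions = torsionDefinitions(tree)) {
  dialect <- match.arg(dialect)
  validObject(tree)
  a <- ensemble@atoms
  resids <- unique(a$resid)
  ids <- sort(tree@nodes$id)
  if (length(resids) != length(ids))
    stop("ensemble has ", length(resids), " residues but the glycan tree has ",
         length(ids))
  residues <- data.frame(node_id = ids, resid = resids)
  for (i in seq_along(ids)) {
    nd <- tree@nodes[match(ids[i], tree@nodes$id), ]
    rn <- a$resname[match(resids[i], a$resid)]
    if (!.resnameMatches(rn, nd$name, nd$anomer, dialect))
      stop("residue ", resids[i], " ('", rn, "') does not match ", nd$name,
           "-", nd$anomer, " under the ", dialect, " dialect")
  }
  key <- paste0(residues$node_id[match(a$resid, residues$resid)], ":", a$name)
  idx <- seq_len(nrow(a))
  if (anyDuplicated(key))
    stop("duplicate atom names within a residue; mapping would not be injective")
  names(idx) <- key
  map <- new("AtomMap", dialect = dialect, residues = residues, index = idx)
  if (!is.null(definitions) && nrow(definitions)) {
    missing <- character()
    for (i in seq_len(nrow(definitions))) {
      d <- definitions[i, ]
      for (k in 1:4) {
        key_k <- paste0(d[[paste0("res", k)]], ":", d[[paste0("atom", k)]])
        if (!key_k %in% names(idx)) {
          nd <- tree@nodes[match(d[[paste0("res", k)]], tree@nodes$id), ]
          missing <- c(missing, paste0("atom ", d[[paste0("atom", k)]],
                                       " of residue ", nd$id, " (", nd$name, ")"))
        }
      }
    }
    if (length(missing))
      stop("unresolved atoms required by torsion definitions: ",
           paste(unique(missing), collapse = "; "))
  }
  map
}

#' Resolve one (tree node, atom name) pair to an ensemble atom index
#' @param map an [AtomMap-class].
#' @param node tree node id.
#' @param atom canonical atom name.
#' @return integer atom index.
#' @export
resolveAtom <- function(map, node, atom) {
  key <- paste0(node, ":", atom)
  i <- map@index[key]
  if (is.na(i)) stop("unresolved atom ", atom, " in residue ", node)
  unname(i)
}

setMethod("show", "AtomMap", function(object) {
  cat(sprintf("AtomMap (%s dialect): %d residues, %d atoms indexed\n",
              object@dialect, nrow(object@residues), length(object@index)))
})

#' Write a per-linkage cluster population table
#'
#' Emulates supplementary-table layout: one row per (linkage, torsion,
#' cluster) with the per-dimension circular mean, circular SD and population
#' in percent; density-noise frames get their own row whenever present.
#' Populations for each torsion sum to 100.
#'
#' @param landscapes list of [ConformerLandscape-class] objects.
#' @param path output CSV path.
#' @return the table, invisibly (also written to \code{path}).
#' @export
writePopulationTable <- function(landscapes, path) {
  rows <- list()
  for (ls in landscapes) {
    stopifnot(is(ls, "ConformerLandscape"))
    dims <- ls@dimensions
    cl <- ls@clusters
    for (d in seq_along(dims)) {
      lab <- dims[d]
      torsion <- sub("^.*:", "", lab)
      linkage <- sub(":[^:]*$", "", lab)
      for (i in seq_len(nrow(cl)))
        rows[[length(rows) + 1L]] <- data.frame(
          linkage = linkage, torsion = torsion, cluster = as.character(i),
          mean_deg = .fmtNum(cl[[paste0("mean_", d)]][i], 2),
          sd_deg = .fmtNum(cl[[paste0("sd_", d)]][i], 2),
          population_pct = .fmtNum(100 * cl$population[i], 2),
          stringsAsFactors = FALSE)
      if (ls@noise_fraction > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          linkage = linkage, torsion = torsion, cluster = "noise",
          mean_deg = "", sd_deg = "",
          population_pct = .fmtNum(100 * ls@noise_fraction, 2),
          stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(linkage = character(), torsion = character(),
               cluster = character(), mean_deg = character(),
               sd_deg = character(), population_pct = character())
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}
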