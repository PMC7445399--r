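# Sequence model: condensed-text parsing, canonical serialization, and
# linkage-level torsion definitions.

.pkg_env <- new.env(parent = emptyenv())

.name_aliases <- c(Neu5Ac = "Sia", NeuAc = "Sia", NeuNAc = "Sia")

.parseError <- function(msg, token, offset) {
  stop(sprintf("glycan parse error at character %d ('%s'): %s",
               offset, token, msg), call. = FALSE)
}

.newNode <- function(env, name, anomer) {
  raw <- name
  if (name %in% names(.name_aliases)) name <- .name_aliases[[name]]
  if (!name %in% .mono_vocab)
    return(NA_integer_)  # caller raises with offset info
  id <- env$next_id
  env$next_id <- id + 1L
  env$nodes[[id]] <- data.frame(
    id = id, name = name, anomer = anomer,
    series = if (name == "Fuc") "L" else "D",
    ring = "p", supported = name != "Sia",
    stringsAsFactors = FALSE)
  id
}

.addEdge <- function(env, parent, child, child_pos, parent_pos, offset) {
  for (e in env$edges)
    if (e$parent_id == parent && e$parent_pos == parent_pos)
      .parseError("duplicate substitution at this position",
                  sprintf("position %d", parent_pos), offset)
  env$edges[[length(env$edges) + 1L]] <- data.frame(
    parent_id = parent, child_id = child,
    child_pos = child_pos, parent_pos = parent_pos)
  invisible()
}

# Parse a chain whose rightmost token is the (local) root residue; returns the
# node id of that residue. `off` is the 1-based offset of `s` in the full text.
.parseChain <- function(env, s, off, anomer = "b") {
  m <- regexpr("[A-Za-z][A-Za-z0-9]*$", s)
  if (m == -1L)
    .parseError("expected a residue name", substr(s, max(1, nchar(s) - 8), nchar(s)),
                off + nchar(s) - 1L)
  name <- substr(s, m, nchar(s))
  id <- .newNode(env, name, anomer)
  if (is.na(id)) .parseError("unknown residue token", name, off + m - 1L)
  rest <- substr(s, 1L, m - 1L)
  # peel bracketed branches and then the main chain, right to left
  while (nzchar(rest)) {
    if (substring(rest, nchar(rest)) == "]") {
      depth <- 0L
      open <- -1L
      for (i in rev(seq_len(nchar(rest)))) {
        ch <- substring(rest, i, i)
        if (ch == "]") depth <- depth + 1L
        if (ch == "[") {
          depth <- depth - 1L
          if (depth == 0L) { open <- i; break }
        }
      }
      if (open == -1L)
        .parseError("unbalanced brackets", "]", off + nchar(rest) - 1L)
      inner <- substr(rest, open + 1L, nchar(rest) - 1L)
      .parseLinkedChain(env, inner, off + open, id)
      rest <- substr(rest, 1L, open - 1L)
    } else {
      .parseLinkedChain(env, rest, off, id)
      rest <- ""
    }
  }
  id
}

# Parse "…Name(a1-3)" and attach its root to `parent`.
.parseLinkedChain <- function(env, s, off, parent) {
  lm <- regexpr("\\(([ab])([12])-([2346])\\)$", s, perl = TRUE)
  if (lm == -1L)
    .parseError("expected a linkage specification like (b1-4)",
                substr(s, max(1L, nchar(s) - 7L), nchar(s)),
                off + nchar(s) - 1L)
  spec <- substr(s, lm + 1L, nchar(s) - 1L)
  anomer <- substr(spec, 1L, 1L)
  child_pos <- as.integer(substr(spec, 2L, 2L))
  parent_pos <- as.integer(substr(spec, 4L, 4L))
  if (grepl("\\[", s) && !grepl("\\]", substr(s, 1L, lm)))
    .parseError("unbalanced brackets", "[", off)
  child <- .parseChain(env, substr(s, 1L, lm - 1L), off, anomer)
  .addEdge(env, parent, child, child_pos, parent_pos, off + lm - 1L)
  invisible(child)
}

#' Parse a glycan sequence or shorthand name into a GlycanTree
#'
#' Accepts either a shorthand from the glycoform registry (for example
#' \code{"ngfx"}, \code{"gf"}, \code{"lea"}, \code{"xfa2g2"}; see
#' [glycanRegistry()]) or condensed IUPAC-like text with bracketed branches,
#' e.g. \code{"Man(a1-3)[Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc"}. The
#' rightmost residue is the reducing end (tree root); a bracketed group
#' attaches to the residue on its right.
#'
#' In shorthand names, \emph{f} adds the plant-type core Fuc-alpha(1-3) to
#' the reducing-end GlcNAc, \emph{x} adds Xyl-beta(1-2) to the central
#' mannose, \emph{g} caps both arms with Gal-beta(1-3), and \emph{ng} leaves
#' the arms at GlcNAc-beta(1-2).
#'
#' @param text sequence string or registry shorthand (case-insensitive for
#'   shorthands).
#' @return a validated [GlycanTree-class] object.
#' @examples
#' parseGlycan("GlcNAc")
#' parseGlycan("ngfx")
#' @export
parseGlycan <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  reg <- glycanRegistry()
  key <- tolower(trimws(text))
  hit <- vapply(reg, function(e)
    key == tolower(e$name) || key %in% tolower(unlist(e$aliases)), logical(1))
  if (any(hit)) text <- reg[[which(hit)[1]]]$sequence
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s)) .parseError("empty sequence", "", 1L)
  env <- new.env(parent = emptyenv())
  env$next_id <- 1L
  env$nodes <- list()
  env$edges <- list()
  nopen <- lengths(regmatches(s, gregexpr("\\[", s)))
  nclose <- lengths(regmatches(s, gregexpr("\\]", s)))
  if (nopen != nclose)
    .parseError("unbalanced brackets", if (nopen > nclose) "[" else "]", nchar(s))
  root <- .parseChain(env, s, 1L)
  tree <- new("GlycanTree",
              nodes = do.call(rbind, env$nodes),
              edges = if (length(env$edges)) do.call(rbind, env$edges) else
                data.frame(parent_id = integer(), child_id = integer(),
                           child_pos = integer(), parent_pos = integer()),
              root_id = root)
  validObject(tree)
  tree
}

.childrenOf <- function(tree, id) {
  ed <- tree@edges
  ed[ed$parent_id == id, , drop = FALSE]
}

.nodeName <- function(tree, id) tree@nodes$name[match(id, tree@nodes$id)]
.nodeAnomer <- function(tree, id) tree@nodes$anomer[match(id, tree@nodes$id)]

.subtreeDepth <- function(tree, id) {
  ch <- .childrenOf(tree, id)
  if (!nrow(ch)) return(1L)
  1L + max(vapply(ch$child_id, function(c) .subtreeDepth(tree, c), 1L))
}

#' Serialize a GlycanTree to canonical condensed text
#'
#' The serialization is canonical: the main chain continues through the child
#' subtree of greatest depth (ties broken by the lowest attachment position)
#' and the remaining branches are bracketed in order of descending attachment
#' position, so isomorphic trees produce byte-identical strings and
#' \code{parseGlycan(serializeGlycan(x))} reproduces \code{x}.
#'
#' @param tree a [GlycanTree-class].
#' @return single character string.
#' @export
serializeGlycan <- function(tree) {
  validObject(tree)
  ser <- function(id) {
    ch <- .childrenOf(tree, id)
    if (!nrow(ch)) return(.nodeName(tree, id))
    depth <- vapply(ch$child_id, function(c) .subtreeDepth(tree, c), 1L)
    ord <- order(-depth, ch$parent_pos)
    main <- ch[ord[1], ]
    rest <- ch[ord[-1], , drop = FALSE]
    rest <- rest[order(-rest$parent_pos), , drop = FALSE]
    lk <- function(e) sprintf("(%s%d-%d)", .nodeAnomer(tree, e$child_id),
                              e$child_pos, e$parent_pos)
    paste0(ser(main$child_id), lk(main),
           paste(vapply(seq_len(nrow(rest)), function(i)
             paste0("[", ser(rest$child_id[i]), lk(rest[i, ]), "]"),
             character(1)), collapse = ""),
           .nodeName(tree, id))
  }
  ser(tree@root_id)
}

#' The glycoform shorthand registry
#'
#' Returns the data-driven registry of named glycoforms: the eight plant
#' biantennary forms (\code{ng}, \code{g}, \code{ngf}, \code{gf}, \code{ngx},
#' \code{gx}, \code{ngfx}, \code{gfx}), the Lewis-terminated plant and
#' schistosome-type forms (\code{lea}, \code{lex}), the hybrid
#' mammalian/plant constructs (\code{xa2g2}, \code{xfa2g2}, \code{xfa2},
#' \code{ffa2g2}) and the \code{man3} core. Each entry carries the condensed
#' sequence, aliases and residue-level provenance notes.
#'
#' @return named list of registry entries.
#' @export
glycanRegistry <- function() {
  if (is.null(.pkg_env$registry)) {
    path <- system.file("extdata", "glycan_registry.json",
                        package = "glycanarch", mustWork = TRUE)
    .pkg_env$registry <- jsonlite::read_json(path, simplifyVector = FALSE)$glycoforms
    names(.pkg_env$registry) <-
      vapply(.pkg_env$registry, `[[`, character(1), "name")
  }
  .pkg_env$registry
}

#' Torsion definitions for every glycosidic linkage of a tree
#'
#' Every linkage X(1-n)Y yields phi = O5(X)-C1(X)-On(Y)-Cn(Y) and
#' psi = C1(X)-On(Y)-Cn(Y)-C(n-1)(Y); a 1-6 linkage additionally yields
#' omega = O6(Y)-C6(Y)-C5(Y)-O5(Y), whose staggered rotamers gg/gt/tg sit at
#' -60, +60 and 180 degrees. For 2-linked substituents (the beta(1-2)-xylose
#' and the arm GlcNAcs) the fourth psi atom is C1 of the parent.
#'
#' @param tree a [GlycanTree-class].
#' @return data.frame with one row per torsion: \code{label}, \code{linkage},
#'   \code{torsion}, \code{child_id}, \code{parent_id}, and the four
#'   (residue id, atom name) pairs as \code{res1..res4}, \code{atom1..atom4}.
#' @examples
#' nrow(torsionDefinitions(parseGlycan("man3")))  # 9
#' @export
torsionDefinitions <- function(tree) {
  validObject(tree)
  unsupported <- tree@nodes$id[!tree@nodes$supported]
  ed <- tree@edges
  rows <- list()
  for (i in seq_len(nrow(ed))) {
    e <- ed[i, ]
    if (e$child_id %in% unsupported || e$parent_id %in% unsupported)
      stop("linkage involves a residue unsupported for analysis (sialic acid ",
           "is accepted as a parse token only)")
    n <- e$parent_pos
    if (!n %in% c(2L, 3L, 4L, 6L)) stop("unknown attachment position: ", n)
    cn <- .nodeName(tree, e$child_id)
    pn <- .nodeName(tree, e$parent_id)
    linkage <- sprintf("%s%d(%s%d-%d)%s%d", cn, e$child_id,
                       .nodeAnomer(tree, e$child_id), e$child_pos, n,
                       pn, e$parent_id)
    mk <- function(torsion, r, a) {
      data.frame(label = paste0(linkage, ":", torsion), linkage = linkage,
                 torsion = torsion,
                 child_id = e$child_id, parent_id = e$parent_id,
                 res1 = r[1], atom1 = a[1], res2 = r[2], atom2 = a[2],
                 res3 = r[3], atom3 = a[3], res4 = r[4], atom4 = a[4],
                 stringsAsFactors = FALSE)
    }
    On <- paste0("O", n); Cn <- paste0("C", n); Cnm1 <- paste0("C", n - 1L)
    ci <- e$child_id; pi_ <- e$parent_id
    rows[[length(rows) + 1L]] <-
      mk("phi", c(ci, ci, pi_, pi_), c("O5", "C1", On, Cn))
    rows[[length(rows) + 1L]] <-
      mk("psi", c(ci, pi_, pi_, pi_), c("C1", On, Cn, Cnm1))
    if (n == 6L)
      rows[[length(rows) + 1L]] <-
        mk("omega", c(pi_, pi_, pi_, pi_), c("O6", "C6", "C5", "O5"))
  }
  if (!length(rows))
    return(data.frame(label = character(), linkage = character(),
                      torsion = character(), child_id = integer(),
                      parent_id = integer(),
                      res1 = integer(), atom1 = character(),
                      res2 = integer(), atom2 = character(),
                      res3 = integer(), atom3 = character(),
                      res4 = integer(), atom4 = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Test whether two GlycanTrees are isomorphic
#'
#' Trees are compared by canonical serialization, so node numbering and the
#' entry order of branches are irrelevant.
#' @param a,b [GlycanTree-class] objects.
#' @return logical.
#' @export
isIsomorphic <- function(a, b) serializeGlycan(a) == serializeGlycan(b)

setMethod("show", "GlycanTree", function(object) {
  cat(sprintf("GlycanTree: %d residues, %d linkages\n",
              nrow(object@nodes), nrow(object@edges)))
  cat(" ", serializeGlycan(object), "\n")
})

#' @describeIn GlycanTree-class node table accessor
#' @param tree a GlycanTree
#' @export
glycanNodes <- function(tree) tree@nodes

#' @describeIn GlycanTree-class linkage table accessor
#' @export
glycanLinkages <- function(tree) tree@edges

#' @describeIn GlycanTree-class root node id accessor
#' @export
glycanRoot <- function(tree) tree@root_id
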