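# Glycoblock decomposition and the sequence-to-propensity rule engine.

#' PropensityReport: qualitative conformational prediction for a glycan
#'
#' @slot prediction character; (1-6)-arm propensity: one of
#'   \code{open_dominant}, \code{closed_dominant}, \code{mixed},
#'   \code{restrained_interacting}.
#' @slot psi_shift numeric; predicted shift of the chitobiose
#'   GlcNAc-b(1-4)-GlcNAc psi in degrees (0, or about -20 with a core
#'   a(1-3)-fucose).
#' @slot notes character; flexibility notes contributed by fired rules.
#' @slot trace data.frame of fired rules in priority order (id, priority,
#'   effect, anchor).
#' @slot metadata named list of annotated reference populations carried by
#'   the fired rules (metadata only, never computed).
#' @seealso [predictPropensity()]
#' @export
setClass("PropensityReport",
  representation(prediction = "character", psi_shift = "numeric",
                 notes = "character", trace = "data.frame",
                 metadata = "list"))

setMethod("show", "PropensityReport", function(object) {
  cat("PropensityReport\n")
  cat("  (1-6) arm:", object@prediction, "\n")
  cat("  chitobiose psi shift:", object@psi_shift, "deg\n")
  cat("  rules fired:", paste(object@trace$id, collapse = ", "), "\n")
})

.glycoblockRules <- function() {
  if (is.null(.pkg_env$rules)) {
    path <- system.file("extdata", "glycoblock_rules.json",
                        package = "glycanarch", mustWork = TRUE)
    .pkg_env$rules <- jsonlite::read_json(path, simplifyVector = FALSE)
  }
  .pkg_env$rules
}

#' The glycoblock vocabulary and propensity rule base
#' @return list with elements \code{block_vocabulary} and \code{rules} as
#'   loaded from the versioned JSON rule file.
#' @export
glycoblockRules <- function() .glycoblockRules()

#' Decompose a glycan tree into glycoblocks
#'
#' Partitions the residues into self-contained 3D units by precedence:
#' (1) the chitobiose core (reducing-end GlcNAc + its b(1-4)-GlcNAc),
#' absorbing core fucoses as modifiers; (2) the trimannose core (b-Man and
#' both arm mannoses), absorbing a b(1-2)-Xyl; (3) Lewis-type branched
#' termini (Gal-b(1-3)[Fuc-a(1-4)]GlcNAc = LeA, Gal-b(1-4)[Fuc-a(1-3)]GlcNAc
#' = LeX), which absorb their GlcNAc; (4) remaining b(1-2) arm GlcNAcs;
#' (5) unbranched terminal galactoses. Every residue must be assigned to
#' exactly one block.
#'
#' @param tree a [GlycanTree-class] rooted at a reducing-end GlcNAc and
#'   containing the Man3 core.
#' @return a [GlycoblockSet-class].
#' @examples
#' decomposeGlycoblocks(parseGlycan("gfx"))
#' @export
decomposeGlycoblocks <- function(tree) {
  validObject(tree)
  edges <- tree@edges
  childAt <- function(id, pos) {
    e <- edges[edges$parent_id == id & edges$parent_pos == pos, ]
    if (nrow(e)) e$child_id[1] else NA_integer_
  }
  root <- tree@root_id
  if (.nodeName(tree, root) != "GlcNAc")
    stop("glycoblock decomposition requires a reducing-end GlcNAc root")
  chito2 <- childAt(root, 4L)
  if (is.na(chito2) || .nodeName(tree, chito2) != "GlcNAc")
    stop("no chitobiose: root GlcNAc lacks a b(1-4)-GlcNAc")
  bman <- childAt(chito2, 4L)
  man3 <- childAt(bman, 3L); man6 <- childAt(bman, 6L)
  if (is.na(bman) || .nodeName(tree, bman) != "Man" ||
      is.na(man3) || is.na(man6) ||
      .nodeName(tree, man3) != "Man" || .nodeName(tree, man6) != "Man")
    stop("no trimannose core (b-Man with a(1-3)- and a(1-6)-Man) found")

  vocab <- .glycoblockRules()$block_vocabulary
  assigned <- integer(0)
  blocks <- list()
  addBlock <- function(type, members, modifiers, arm) {
    blocks[[length(blocks) + 1L]] <<- list(
      type = type, members = sort(members),
      modifiers = sort(modifiers), arm = arm,
      descriptor = vocab[[type]]$descriptor %||% "")
    assigned <<- c(assigned, members)
  }

  # (1) chitobiose + core fucose modifiers
  mem <- c(root, chito2); mods <- character()
  for (pos in c(3L, 6L)) {
    f <- childAt(root, pos)
    if (!is.na(f) && .nodeName(tree, f) == "Fuc") {
      mem <- c(mem, f)
      mods <- c(mods, paste0("Fuc_a1_", pos))
    }
  }
  addBlock("chitobiose_core", mem, mods, "core")

  # (2) trimannose + xylose modifier
  mem <- c(bman, man3, man6); mods <- character()
  xyl <- childAt(bman, 2L)
  if (!is.na(xyl) && .nodeName(tree, xyl) == "Xyl") {
    mem <- c(mem, xyl)
    mods <- c(mods, "Xyl_b1_2")
  }
  addBlock("trimannose_core", mem, mods, "core")

  # (3)-(5) arm blocks
  for (arm in c("1-3", "1-6")) {
    armman <- if (arm == "1-3") man3 else man6
    g <- childAt(armman, 2L)
    if (is.na(g)) next
    if (.nodeName(tree, g) != "GlcNAc")
      stop("unassignable residue ", g, " (", .nodeName(tree, g),
           ") on the (", arm, ") arm")
    gal3 <- childAt(g, 3L); gal4 <- childAt(g, 4L)
    fuc3 <- if (!is.na(gal4) && .nodeName(tree, gal4) == "Fuc") gal4 else NA
    isGal <- function(id) !is.na(id) && .nodeName(tree, id) == "Gal"
    isFuc <- function(id) !is.na(id) && .nodeName(tree, id) == "Fuc"
    if (isGal(gal3) && isFuc(gal4)) {
      addBlock("LeA_terminus", c(g, gal3, gal4), character(), arm)
    } else if (isGal(gal4) && isFuc(gal3)) {
      addBlock("LeX_terminus", c(g, gal3, gal4), character(), arm)
    } else {
      addBlock("arm_GlcNAc", g, character(), arm)
      if (isGal(gal3)) addBlock("terminal_Gal_1_3", gal3, character(), arm)
      if (isGal(gal4)) addBlock("terminal_Gal_1_4", gal4, character(), arm)
      leftover <- setdiff(c(gal3, gal4), c(NA, assigned))
      if (length(leftover))
        stop("unassignable residue(s): ",
             paste(leftover, "(", .nodeName(tree, leftover), ")", collapse = ", "))
    }
  }

  un <- setdiff(tree@nodes$id, assigned)
  if (length(un))
    stop("unassignable residue(s): ",
         paste0(un, " (", vapply(un, function(i) .nodeName(tree, i),
                                 character(1)), ")", collapse = ", "))
  new("GlycoblockSet", blocks = blocks, tree = tree)
}

#' @describeIn GlycoblockSet-class list of blocks accessor
#' @param x a GlycoblockSet
#' @export
glycoblocks <- function(x) x@blocks

#' @describeIn GlycoblockSet-class block type vector (with modifiers, e.g.
#'   \code{"chitobiose_core+Fuc_a1_3"})
#' @export
blockSignatures <- function(x) {
  vapply(x@blocks, function(b)
    paste(c(b$type, b$modifiers), collapse = "+"), character(1))
}

setMethod("show", "GlycoblockSet", function(object) {
  cat(sprintf("GlycoblockSet: %d blocks over %d residues\n",
              length(object@blocks), nrow(object@tree@nodes)))
  for (b in object@blocks)
    cat(sprintf("  [%s] %s  residues: %s%s\n", b$arm, b$type,
                paste(b$members, collapse = ","),
                if (length(b$modifiers))
                  paste0("  modifiers: ", paste(b$modifiers, collapse = ","))
                else ""))
})

.blockFeatures <- function(bs) {
  blocks <- bs@blocks
  type_of <- vapply(blocks, `[[`, character(1), "type")
  arm_of <- vapply(blocks, `[[`, character(1), "arm")
  mods <- unlist(lapply(blocks, `[[`, "modifiers"))
  terminalOn <- function(arm) {
    cand <- type_of[arm_of == arm &
                    type_of %in% c("terminal_Gal_1_3", "terminal_Gal_1_4",
                                   "LeA_terminus", "LeX_terminus")]
    if (length(cand)) cand[1] else {
      g <- type_of[arm_of == arm & type_of == "arm_GlcNAc"]
      if (length(g)) "arm_GlcNAc" else "none"
    }
  }
  a16 <- terminalOn("1-6"); a13 <- terminalOn("1-3")
  list(
    has_fuc13 = "Fuc_a1_3" %in% mods,
    has_fuc16 = "Fuc_a1_6" %in% mods,
    has_xyl = "Xyl_b1_2" %in% mods,
    open_bias_modifier = ("Fuc_a1_3" %in% mods) || ("Xyl_b1_2" %in% mods),
    arm16_terminal = a16,
    arm13_terminal = a13,
    gal13_terminal_present = "terminal_Gal_1_3" %in% type_of,
    both_lea = a16 == "LeA_terminus" && a13 == "LeA_terminus",
    both_lex = a16 == "LeX_terminus" && a13 == "LeX_terminus")
}

.conditionHolds <- function(cond, feats) {
  if (!length(cond)) return(TRUE)
  all(vapply(names(cond), function(nm)
    identical(feats[[nm]], cond[[nm]]), logical(1)))
}

#' Predict qualitative (1-6)-arm propensity from a glycoblock decomposition
#'
#' Applies the data-driven rule base (see [glycoblockRules()]) to the block
#' features of a decomposition: core fucosylation pattern, central xylose,
#' and the terminal block type of each arm. Fired rules are resolved by
#' explicit integer priority; rules carrying an explicit prediction override
#' the open-bias aggregation, and the full trace (with each rule's evidence
#' anchor and annotated reference populations) is returned.
#'
#' @param blocks a [GlycoblockSet-class] (or a [GlycanTree-class], which is
#'   decomposed first).
#' @return a [PropensityReport-class].
#' @examples
#' predictPropensity(parseGlycan("gfx"))@prediction  # open_dominant
#' @export
predictPropensity <- function(blocks) {
  if (is(blocks, "GlycanTree")) blocks <- decomposeGlycoblocks(blocks)
  stopifnot(is(blocks, "GlycoblockSet"))
  feats <- .blockFeatures(blocks)
  rules <- .glycoblockRules()$rules
  ids <- vapply(rules, `[[`, character(1), "id")
  fired <- Filter(function(r)
    r$id != "Rdefault" && .conditionHolds(r$condition, feats), rules)
  if (!length(fired)) fired <- rules[ids == "Rdefault"]
  pri <- vapply(fired, function(r) as.numeric(r$priority), numeric(1))
  fired <- fired[order(-pri)]

  preds <- Filter(function(r) !is.null(r$effects$prediction), fired)
  notes <- unlist(lapply(fired, function(r) r$effects$note))
  conflict <- length(unique(vapply(preds, function(r)
    r$effects$prediction, character(1)))) > 1
  prediction <- if (length(preds)) {
    preds[[1]]$effects$prediction
  } else if (any(vapply(fired, function(r)
    identical(r$effects$bias, "open"), logical(1)))) {
    "open_dominant"
  } else "mixed"
  psi_shift <- sum(vapply(fired, function(r)
    as.numeric(r$effects$psi_shift %||% 0), numeric(1)))

  trace <- do.call(rbind, lapply(fired, function(r) data.frame(
    id = r$id, priority = as.numeric(r$priority),
    effect = paste(names(r$effects), vapply(r$effects, function(e)
      paste(format(e), collapse = " "), character(1)),
      sep = "=", collapse = "; "),
    anchor = r$anchor, stringsAsFactors = FALSE)))
  if (conflict)
    notes <- c(notes, paste("conflicting predictions resolved by priority:",
                            paste(vapply(preds, `[[`, character(1), "id"),
                                  collapse = " > ")))
  meta <- list()
  for (r in fired)
    for (nm in names(r$reference_populations))
      meta[[nm]] <- r$reference_populations[[nm]]
  new("PropensityReport", prediction = prediction, psi_shift = psi_shift,
      notes = as.character(notes %||% character()), trace = trace,
      metadata = meta)
}

#' Compare two glycoblock decompositions
#'
#' Lists blocks present in only one of the two decompositions and blocks of
#' the same type/arm whose modifier sets differ.
#'
#' @param a,b [GlycanTree-class] or [GlycoblockSet-class] objects.
#' @return data.frame with columns \code{change} (added / removed /
#'   modified), \code{arm}, \code{type} and \code{detail}; zero rows when
#'   the decompositions are identical.
#' @export
compareDecompositions <- function(a, b) {
  if (is(a, "GlycanTree")) a <- decomposeGlycoblocks(a)
  if (is(b, "GlycanTree")) b <- decomposeGlycoblocks(b)
  keyed <- function(x) {
    k <- vapply(x@blocks, function(bl) paste(bl$arm, bl$type), character(1))
    split(x@blocks, k)
  }
  ka <- keyed(a); kb <- keyed(b)
  rows <- list()
  add <- function(change, arm, type, detail)
    rows[[length(rows) + 1L]] <<- data.frame(
      change = change, arm = arm, type = type, detail = detail,
      stringsAsFactors = FALSE)
  for (k in union(names(ka), names(kb))) {
    na_ <- length(ka[[k]] %||% list()); nb_ <- length(kb[[k]] %||% list())
    arm <- strsplit(k, " ")[[1]][1]; type <- strsplit(k, " ")[[1]][2]
    if (nb_ > na_) add("added", arm, type, paste0("x", nb_ - na_))
    if (na_ > nb_) add("removed", arm, type, paste0("x", na_ - nb_))
    if (na_ && nb_) {
      ma <- sort(unique(unlist(lapply(ka[[k]], `[[`, "modifiers"))))
      mb <- sort(unique(unlist(lapply(kb[[k]], `[[`, "modifiers"))))
      if (!identical(ma, mb)) {
        gained <- setdiff(mb, ma); lost <- setdiff(ma, mb)
        add("modified", arm, type, paste0(
          if (length(gained)) paste0("+", gained, collapse = " ") else "",
          if (length(gained) && length(lost)) " " else "",
          if (length(lost)) paste0("-", lost, collapse = " ") else ""))
      }
    }
  }
  if (!length(rows))
    return(data.frame(change = character(), arm = character(),
                      type = character(), detail = character()))
  out <- do.call(rbind, rows)
  out[order(out$change, out$arm, out$type), , drop = FALSE]
}
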