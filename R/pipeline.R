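# End-to-end orchestration: simulate / analyze / blocks runs with manifests.
# These functions back the command-line interface in
# inst/scripts/glycanarch-cli.R.

.defaultParams <- list(
  dialect = "PDB", stride = 1L, discard = 0L,
  eps = 25, minFraction = 0.01, bandwidth = 10, gridSize = 90,
  threshold = 15, dOpen = 8, psiTol = 90)

.mergeConfig <- function(config, defaults = .defaultParams) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

.writeManifest <- function(path, kind, config, inputs = character()) {
  manifest <- list(
    tool = "glycanarch", kind = kind,
    version = as.character(utils::packageVersion("glycanarch")),
    parameters = config[order(names(config))],
    input_md5 = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list())
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Analyse the torsion landscape of every linkage of an ensemble
#'
#' Computes the torsion series, clusters each linkage's phi/psi pair (plus
#' the omega of 1-6 linkages, one-dimensionally) under the toroidal metric,
#' and classifies the (1-6)-arm state when the glycan has one.
#'
#' @param ensemble a [GlycanEnsemble-class].
#' @param tree the matching [GlycanTree-class].
#' @param map an [AtomMap-class]; computed if NULL.
#' @param params named list overriding the defaults (eps, minFraction,
#'   bandwidth, gridSize, dOpen, psiTol, dialect).
#' @return list with \code{torsions} ([TorsionSet-class]), \code{landscapes}
#'   (named list of [ConformerLandscape-class]) and \code{armState} (an
#'   [ArmStateSeries-class] or NULL).
#' @export
analyzeEnsemble <- function(ensemble, tree, map = NULL, params = list()) {
  p <- .mergeConfig(params)
  defs <- torsionDefinitions(tree)
  if (is.null(map)) map <- mapAtoms(tree, ensemble, p$dialect, defs)
  ts <- torsionSeries(ensemble, map, defs)
  vals <- torsionValues(ts)
  landscapes <- list()
  for (lk in unique(defs$linkage)) {
    sub <- defs[defs$linkage == lk, ]
    pp <- sub$label[sub$torsion %in% c("phi", "psi")]
    ls <- clusterTorsions(vals[, pp, drop = FALSE], eps = p$eps,
                          minFraction = p$minFraction, dimensions = pp)
    landscapes[[lk]] <- withKde(ls, vals[, pp, drop = FALSE],
                                bandwidth = p$bandwidth,
                                gridSize = p$gridSize)
    om <- sub$label[sub$torsion == "omega"]
    if (length(om)) {
      lso <- clusterTorsions(vals[, om], eps = p$eps,
                             minFraction = p$minFraction, dimensions = om)
      landscapes[[paste0(lk, ":omega")]] <- lso
    }
  }
  arm <- tryCatch(
    classifyArmState(ensemble, map, tree, dOpen = p$dOpen, psiTol = p$psiTol),
    error = function(e) NULL)
  list(torsions = ts, landscapes = landscapes, armState = arm)
}

#' Run the full analysis pipeline on trajectory files
#'
#' Reads the ensemble, analyses the pooled data and (when several trajectory
#' files are given) each trajectory separately, applies the convergence
#' rule per trajectory, and writes population tables, KDE grids, per-frame
#' state series and a reproducibility manifest into \code{outDir}. Outputs
#' are byte-deterministic for a fixed configuration.
#'
#' @param config list (or path to a JSON file) with at least \code{topology}
#'   and \code{glycan}; optional \code{frames} (character vector),
#'   \code{dialect}, \code{stride}, \code{discard}, \code{eps},
#'   \code{minFraction}, \code{bandwidth}, \code{gridSize},
#'   \code{threshold}, \code{dOpen}, \code{psiTol}.
#' @param outDir output directory (created if needed).
#' @return invisible list of the in-memory results (pooled analysis,
#'   per-trajectory convergence report, file paths).
#' @export
runAnalyze <- function(config, outDir) {
  cfg <- .mergeConfig(config)
  if (is.null(cfg$topology)) stop("config must name a topology file")
  if (is.null(cfg$glycan)) stop("config must name the glycan (shorthand or sequence)")
  if (!file.exists(cfg$topology))
    stop("topology file not found: ", cfg$topology)
  for (f in cfg$frames %||% character())
    if (!file.exists(f)) stop("trajectory file not found: ", f)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  tree <- parseGlycan(cfg$glycan)
  ens <- readEnsemble(cfg$topology, cfg$frames, stride = cfg$stride,
                      discard = cfg$discard)
  pooled <- analyzeEnsemble(ens, tree, params = cfg)

  # per-trajectory convergence (falls back to the pooled ensemble)
  traj <- list()
  if (length(cfg$frames %||% character()) > 1L) {
    tn <- make.unique(basename(cfg$frames))
    for (i in seq_along(cfg$frames)) {
      e1 <- readEnsemble(cfg$topology, cfg$frames[i], stride = cfg$stride,
                         discard = cfg$discard)
      traj[[tn[i]]] <- analyzeEnsemble(e1, tree, params = cfg)$landscapes
    }
  } else traj[["pooled"]] <- pooled$landscapes
  conv <- assessConvergence(traj, threshold = cfg$threshold)

  paths <- list(
    populations = file.path(outDir, "populations.csv"),
    torsions = file.path(outDir, "torsions.csv"),
    convergence = file.path(outDir, "convergence.csv"),
    manifest = file.path(outDir, "manifest.json"))
  writePopulationTable(pooled$landscapes, paths$populations)

  long <- torsionLong(pooled$torsions)
  long$value <- .fmtNum(long$value, 4)
  utils::write.csv(long, paths$torsions, row.names = FALSE, quote = FALSE)

  ct <- conv@table
  if (nrow(ct)) ct$circular_sd <- .fmtNum(ct$circular_sd, 3)
  utils::write.csv(cbind(ct, flag = conv@flags[ct$trajectory]),
                   paths$convergence, row.names = FALSE, quote = FALSE)

  for (nm in names(pooled$landscapes)) {
    kde <- pooled$landscapes[[nm]]@kde
    if (is.null(kde)) next
    safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
    gp <- file.path(outDir, paste0("kde_", safe, ".csv"))
    utils::write.table(matrix(.fmtNum(kde$grid, 8), nrow = NROW(kde$grid)),
                       gp, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    jsonlite::write_json(
      list(landscape = nm, dimensions = pooled$landscapes[[nm]]@dimensions,
           bandwidth = kde$bandwidth, grid_size = NROW(kde$grid),
           cell_area = kde$cell_area, axis_centers = kde$x),
      file.path(outDir, paste0("kde_", safe, ".json")),
      auto_unbox = TRUE, digits = NA)
    paths[[paste0("kde_", safe)]] <- gp
  }

  if (!is.null(pooled$armState)) {
    as_ <- pooled$armState
    df <- data.frame(frame = seq_along(as_@states), state = as_@states,
                     distance = .fmtNum(as_@distance, 3),
                     signed_offset = .fmtNum(as_@signed_offset, 3),
                     psi_core = .fmtNum(as_@psi_core, 3),
                     omega_rotamer = as.character(as_@omega_rotamer))
    ap <- file.path(outDir, "armstates.csv")
    utils::write.csv(df, ap, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(fractions = as.list(armStatePopulations(as_)),
           parameters = as_@params),
      file.path(outDir, "armstate_summary.json"),
      auto_unbox = TRUE, digits = NA)
    paths$armstates <- ap
  }

  .writeManifest(paths$manifest, "analyze", cfg,
                 c(cfg$topology, cfg$frames %||% character()))
  invisible(list(pooled = pooled, convergence = conv, paths = paths))
}

#' Generate and write a synthetic ensemble with its ground truth
#'
#' Samples glycosidic torsions from the configured von Mises mixture for
#' the first linkage of the glycan (remaining torsions held at their
#' defaults), builds the Cartesian ensemble, and writes a multi-model PDB,
#' the true per-frame component labels, and a manifest. Fully
#' seed-deterministic.
#'
#' @param config list or JSON path with \code{glycan} (at most 4 residues),
#'   \code{components} (list of \code{list(mean = c(phi, psi), kappa,
#'   weight)}), \code{n_frames}, \code{seed}; optional \code{dialect}.
#' @param outDir output directory.
#' @return invisible list with the ensemble, truth labels and file paths.
#' @export
runSimulate <- function(config, outDir) {
  cfg <- .mergeConfig(config)
  for (req in c("glycan", "components", "n_frames", "seed"))
    if (is.null(cfg[[req]])) stop("simulate config is missing field: ", req)
  # components may arrive as a data.frame when re-read from a JSON manifest
  if (is.data.frame(cfg$components))
    cfg$components <- lapply(seq_len(nrow(cfg$components)), function(i)
      as.list(cfg$components[i, , drop = FALSE]))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tree <- parseGlycan(cfg$glycan)
  defs <- torsionDefinitions(tree)
  if (!nrow(defs)) stop("glycan has no linkages to simulate")
  lk <- defs$linkage[1]
  labs <- defs$label[defs$linkage == lk & defs$torsion %in% c("phi", "psi")]
  comps <- lapply(cfg$components, function(cc)
    list(mean = as.numeric(unlist(cc$mean)), kappa = as.numeric(cc$kappa),
         weight = as.numeric(cc$weight)))
  mx <- sampleTorsionMixture(list(
    dimensions = labs, components = comps,
    n_frames = cfg$n_frames, seed = cfg$seed))
  ens <- buildLinkedEnsemble(tree, mx$values, dialect = cfg$dialect)
  paths <- list(pdb = file.path(outDir, "ensemble.pdb"),
                truth = file.path(outDir, "truth.csv"),
                manifest = file.path(outDir, "manifest.json"))
  writeEnsemblePDB(ens, paths$pdb)
  utils::write.csv(data.frame(frame = seq_along(mx$labels),
                              component = mx$labels),
                   paths$truth, row.names = FALSE, quote = FALSE)
  .writeManifest(paths$manifest, "simulate", cfg)
  invisible(list(ensemble = ens, truth = mx, tree = tree, paths = paths))
}

#' Decompose a glycan and report its predicted propensity
#'
#' @param config list or JSON path with \code{glycan} (shorthand or
#'   condensed sequence).
#' @param outDir output directory for \code{blocks.json} and
#'   \code{report.txt}.
#' @return invisible list with the [GlycoblockSet-class] and
#'   [PropensityReport-class].
#' @export
runBlocks <- function(config, outDir) {
  cfg <- .mergeConfig(config, defaults = list())
  if (is.null(cfg$glycan)) stop("config must name the glycan")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tree <- parseGlycan(cfg$glycan)
  bs <- decomposeGlycoblocks(tree)
  rep_ <- predictPropensity(bs)
  jsonlite::write_json(
    list(glycan = cfg$glycan, sequence = serializeGlycan(tree),
         blocks = lapply(bs@blocks, function(b)
           b[c("type", "members", "modifiers", "arm", "descriptor")]),
         prediction = rep_@prediction, psi_shift = rep_@psi_shift,
         notes = rep_@notes,
         trace = rep_@trace, reference_populations = rep_@metadata),
    file.path(outDir, "blocks.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  txt <- c(
    sprintf("glycan: %s", cfg$glycan),
    sprintf("sequence: %s", serializeGlycan(tree)),
    "",
    "glycoblocks:",
    vapply(bs@blocks, function(b)
      sprintf("  [%s] %s%s (residues %s)", b$arm, b$type,
              if (length(b$modifiers))
                paste0(" + ", paste(b$modifiers, collapse = ", ")) else "",
              paste(b$members, collapse = ",")), character(1)),
    "",
    sprintf("(1-6) arm propensity: %s", rep_@prediction),
    sprintf("chitobiose psi shift: %g deg", rep_@psi_shift),
    "rules fired:",
    sprintf("  %s (priority %g): %s", rep_@trace$id, rep_@trace$priority,
            rep_@trace$anchor))
  writeLines(txt, file.path(outDir, "report.txt"))
  invisible(list(blocks = bs, report = rep_))
}
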