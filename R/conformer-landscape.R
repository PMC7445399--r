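# Density-based conformer clustering on the torus, wrapped-kernel density
# landscapes, the convergence rule, and named-state populations.

.toroidalDist <- function(a, b) {
  # a: m x d, b: k x d matrices of angles; returns m x k distance matrix
  d <- ncol(a)
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(d)) {
    dif <- abs(outer(a[, j], b[, j], "-")) %% 360
    dif <- pmin(dif, 360 - dif)
    out <- out + dif^2
  }
  sqrt(out)
}

#' ConvergenceReport: per-trajectory sampling-sufficiency assessment
#'
#' @slot table data.frame with one row per (trajectory, landscape, cluster,
#'   dimension): the circular SD and whether it exceeds the threshold.
#' @slot flags named character; \code{"converged"} or \code{"extend"} per
#'   trajectory.
#' @slot threshold numeric threshold in degrees.
#' @seealso [assessConvergence()]
#' @export
setClass("ConvergenceReport",
  representation(table = "data.frame", flags = "character",
                 threshold = "numeric"))

setMethod("show", "ConvergenceReport", function(object) {
  cat("ConvergenceReport (threshold ", object@threshold, " deg):\n", sep = "")
  for (tr in names(object@flags))
    cat("  ", tr, ": ", object@flags[[tr]], "\n", sep = "")
})

#' Density-based clustering of periodic torsion data
#'
#' Clusters one- or two-dimensional torsion samples with a DBSCAN-family
#' density rule under the toroidal metric (per-dimension shortest angular
#' difference, combined in the Euclidean sense). For speed the sample is
#' quantised onto a fine periodic histogram (default 2 degree cells, far
#' below the neighbourhood radius) and the density rule operates on weighted
#' cells; populations and per-cluster circular statistics are computed from
#' the original, unquantised values. Clusters whose population falls below
#' \code{minFraction} are merged into noise, and cluster labels are assigned
#' in order of descending population (label 1 = most populated).
#'
#' @param values numeric vector (one torsion) or an n x 2 matrix (e.g. the
#'   phi/psi pair of one linkage), angles in degrees.
#' @param eps neighbourhood radius in degrees (default 25).
#' @param minFraction minimum population a cluster must reach (default 0.01).
#' @param minPts core-point weight threshold; default
#'   \code{max(5, round(0.002 * n))}.
#' @param binWidth histogram cell width in degrees (default 2).
#' @param dimensions optional character labels for the dimensions.
#' @return a [ConformerLandscape-class] (without a KDE grid; see
#'   [kdeLandscape()]).
#' @examples
#' set.seed(1)
#' x <- c(rvonmises(700, 60, 50), rvonmises(300, -120, 50))
#' landscapeClusters(clusterTorsions(x))$population
#' @export
clusterTorsions <- function(values, eps = 25, minFraction = 0.01,
                            minPts = NULL, binWidth = 2,
                            dimensions = NULL) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1,
                                             dimnames = list(NULL, dimensions))
  n <- nrow(values)
  if (!n) stop("cannot cluster an empty torsion series")
  d <- ncol(values)
  stopifnot(d %in% c(1L, 2L), eps > 0)
  if (is.null(dimensions))
    dimensions <- colnames(values) %||% paste0("dim", seq_len(d))
  if (is.null(minPts)) minPts <- max(5, round(0.002 * n))
  vals <- apply(values, 2, wrapAngle)
  if (n == 1L) vals <- matrix(vals, 1)

  nb <- max(4L, round(360 / binWidth))
  bw <- 360 / nb
  cellIdx <- function(x) pmin(nb - 1L, pmax(0L, as.integer(ceiling((x + 180) / bw) - 1L)))
  ij <- apply(vals, 2, cellIdx)
  if (n == 1L) ij <- matrix(ij, 1)
  key <- ij[, 1] + if (d == 2L) nb * ij[, 2] else 0L
  tab <- table(key)
  cells <- as.integer(names(tab))
  w <- as.numeric(tab)
  m <- length(cells)
  centers <- cbind(-180 + (cells %% nb + 0.5) * bw,
                   if (d == 2L) -180 + (cells %/% nb + 0.5) * bw)
  centers <- matrix(centers, m, d)

  # weighted DBSCAN over occupied cells
  D <- .toroidalDist(centers, centers)
  within <- D <= eps
  wsum <- as.numeric(within %*% w)
  core <- wsum >= minPts
  cellLab <- integer(m)
  if (any(core)) {
    ci <- which(core)
    lab <- integer(length(ci))
    comp <- 0L
    adj <- within[ci, ci, drop = FALSE]
    for (s in seq_along(ci)) {
      if (lab[s]) next
      comp <- comp + 1L
      queue <- s
      lab[s] <- comp
      while (length(queue)) {
        u <- queue[[1]]; queue <- queue[-1]
        nb_u <- which(adj[u, ] & lab == 0L)
        lab[nb_u] <- comp
        queue <- c(queue, nb_u)
      }
    }
    cellLab[ci] <- lab
    # border cells join the cluster of their nearest core cell within eps
    for (s in which(!core)) {
      dcore <- D[s, ci]
      if (any(dcore <= eps)) cellLab[s] <- lab[which.min(dcore)]
    }
  }

  assign <- cellLab[match(key, cells)]
  # population-based pruning and relabelling
  labs <- sort(unique(assign[assign > 0]))
  pops <- vapply(labs, function(l) mean(assign == l), numeric(1))
  keep <- labs[pops >= minFraction]
  assign[!assign %in% keep] <- 0L
  keep <- keep[order(-pops[match(keep, labs)])]
  relab <- integer(max(c(0L, keep)))
  relab[keep] <- seq_along(keep)
  assign[assign > 0] <- relab[assign[assign > 0]]

  k <- length(keep)
  cl <- data.frame(cluster = seq_len(k))
  for (j in seq_len(d)) {
    ms <- numeric(k); ss <- numeric(k)
    for (l in seq_len(k)) {
      s <- circularSummary(vals[assign == l, j])
      ms[l] <- s$mean; ss[l] <- s$sd
    }
    cl[[paste0("mean_", j)]] <- ms
    cl[[paste0("sd_", j)]] <- ss
  }
  cl$n <- vapply(seq_len(k), function(l) sum(assign == l), numeric(1))
  cl$population <- cl$n / n
  noise <- 1 - sum(cl$population)
  new("ConformerLandscape", dimensions = dimensions, clusters = cl,
      noise_fraction = noise, assignments = as.integer(assign),
      kde = NULL,
      params = list(eps = eps, minFraction = minFraction, minPts = minPts,
                    binWidth = bw, n = n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn ConformerLandscape-class cluster summary table
#' @param x a ConformerLandscape
#' @export
landscapeClusters <- function(x) x@clusters

#' @describeIn ConformerLandscape-class fraction of frames left as noise
#' @export
noiseFraction <- function(x) x@noise_fraction

#' @describeIn ConformerLandscape-class per-frame cluster assignments
#'   (0 = noise)
#' @export
clusterAssignments <- function(x) x@assignments

setMethod("show", "ConformerLandscape", function(object) {
  cat(sprintf("ConformerLandscape over (%s): %d cluster(s), noise %.3f\n",
              paste(object@dimensions, collapse = ", "),
              nrow(object@clusters), object@noise_fraction))
  print(object@clusters, digits = 4)
})

#' Wrapped-kernel density landscape on the torus
#'
#' Binned kernel density estimate with a wrapped (periodic) Gaussian kernel,
#' evaluated on a regular grid over (-180, 180] per dimension. The density
#' integrates to 1 over the torus: \code{sum(grid) * cell_area == 1}.
#'
#' @param values numeric vector or n x 2 matrix of angles (degrees).
#' @param bandwidth Gaussian kernel SD in degrees (default 10).
#' @param gridSize number of grid cells per dimension (default 90, i.e. 4
#'   degree cells).
#' @return list with elements \code{grid} (vector or matrix of densities in
#'   per-square-degree units), \code{x}, \code{y} (cell centers; \code{y}
#'   NULL in 1D), \code{bandwidth}, \code{cell_area}.
#' @export
kdeLandscape <- function(values, bandwidth = 10, gridSize = 90) {
  stopifnot(bandwidth > 0, gridSize >= 4)
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (!nrow(values)) stop("cannot estimate a density from an empty series")
  d <- ncol(values)
  nb <- as.integer(gridSize)
  bw <- 360 / nb
  centers <- -180 + (seq_len(nb) - 0.5) * bw
  idx <- function(x) pmin(nb - 1L, pmax(0L, as.integer(ceiling((wrapAngle(x) + 180) / bw) - 1L)))
  # wrapped Gaussian kernel matrix between cell centers
  difs <- outer(centers, centers, "-")
  K <- 0
  for (k in -2:2) K <- K + stats::dnorm(difs + 360 * k, 0, bandwidth)
  if (d == 1L) {
    counts <- tabulate(idx(values[, 1]) + 1L, nbins = nb)
    dens <- as.numeric(K %*% counts)
    cell_area <- bw
  } else {
    counts <- matrix(0, nb, nb)
    ii <- idx(values[, 1]) + 1L
    jj <- idx(values[, 2]) + 1L
    for (p in seq_len(nrow(values))) counts[ii[p], jj[p]] <- counts[ii[p], jj[p]] + 1
    dens <- K %*% counts %*% K
    cell_area <- bw^2
  }
  dens <- dens / (sum(dens) * cell_area)
  list(grid = dens, x = centers, y = if (d == 2L) centers else NULL,
       bandwidth = bandwidth, cell_area = cell_area)
}

#' Attach a KDE landscape to a clustering result
#'
#' @param landscape a [ConformerLandscape-class].
#' @param values the torsion values the landscape was clustered from.
#' @param bandwidth,gridSize passed to [kdeLandscape()].
#' @return the landscape with its \code{kde} slot filled.
#' @export
withKde <- function(landscape, values, bandwidth = 10, gridSize = 90) {
  landscape@kde <- kdeLandscape(values, bandwidth, gridSize)
  landscape
}

#' Apply the per-trajectory convergence rule
#'
#' A trajectory's sampling is deemed sufficient when no cluster of any of its
#' torsion landscapes has a per-dimension circular SD strictly above the
#' threshold (15 degrees by default); otherwise the trajectory is flagged
#' \code{"extend"}. The comparison is a strict inequality: an SD of exactly
#' 15 converges.
#'
#' @param trajectories named list; each element is one trajectory's
#'   [ConformerLandscape-class] or a list of them.
#' @param threshold degrees (default 15).
#' @return a [ConvergenceReport-class].
#' @export
assessConvergence <- function(trajectories, threshold = 15) {
  stopifnot(length(trajectories) >= 1)
  if (is.null(names(trajectories)))
    names(trajectories) <- paste0("trajectory", seq_along(trajectories))
  rows <- list()
  flags <- character()
  for (tr in names(trajectories)) {
    lss <- trajectories[[tr]]
    if (is(lss, "ConformerLandscape")) lss <- list(lss)
    exceed_any <- FALSE
    for (ls in lss) {
      cl <- ls@clusters
      dlabs <- ls@dimensions
      for (j in seq_along(dlabs)) for (i in seq_len(nrow(cl))) {
        sdv <- cl[[paste0("sd_", j)]][i]
        ex <- sdv > threshold
        exceed_any <- exceed_any || ex
        rows[[length(rows) + 1L]] <- data.frame(
          trajectory = tr, landscape = paste(dlabs, collapse = "/"),
          cluster = cl$cluster[i], dimension = dlabs[j],
          circular_sd = sdv, exceeds = ex, stringsAsFactors = FALSE)
      }
    }
    flags[[tr]] <- if (exceed_any) "extend" else "converged"
  }
  new("ConvergenceReport",
      table = if (length(rows)) do.call(rbind, rows) else
        data.frame(trajectory = character(), landscape = character(),
                   cluster = integer(), dimension = character(),
                   circular_sd = numeric(), exceeds = logical()),
      flags = flags, threshold = threshold)
}

#' @describeIn ConvergenceReport-class per-trajectory converged/extend flags
#' @param report a ConvergenceReport
#' @export
convergenceFlags <- function(report) report@flags

#' Population of named conformational states
#'
#' Sums cluster populations by a user-supplied state predicate: a function
#' receiving the named vector of a cluster's per-dimension circular means and
#' returning a single state name. Every cluster must be assigned; the density
#' noise fraction is reported separately under \code{attr(, "noise")}.
#'
#' @param landscape a [ConformerLandscape-class].
#' @param classifier function(means) -> character(1).
#' @return named numeric vector of state fractions with a \code{noise}
#'   attribute.
#' @export
statePopulations <- function(landscape, classifier) {
  cl <- landscape@clusters
  d <- length(landscape@dimensions)
  states <- character(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    means <- vapply(seq_len(d), function(j) cl[[paste0("mean_", j)]][i],
                    numeric(1))
    names(means) <- landscape@dimensions
    s <- classifier(means)
    if (length(s) != 1L || is.na(s) || !nzchar(s))
      stop("state predicate left cluster ", i, " unassigned")
    states[i] <- s
  }
  out <- tapply(cl$population, states, sum)
  out <- stats::setNames(as.numeric(out), names(out))
  attr(out, "noise") <- landscape@noise_fraction
  out
}
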