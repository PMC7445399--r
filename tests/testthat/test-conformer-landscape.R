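test_that("a single tight mode yields one full-population cluster", {
  set.seed(21)
  x <- rvonmises(1e4, -45, 100)
  ls <- clusterTorsions(x)
  cl <- landscapeClusters(ls)
  expect_equal(nrow(cl), 1)
  expect_gt(cl$population[1], 0.99)
  expect_lt(noiseFraction(ls), 0.01)
  expect_lt(abs(cl$mean_1[1] + 45), 1)
})

test_that("two-component toroidal mixtures are recovered with correct weights", {
  spec <- list(dimensions = c("phi", "psi"),
               components = list(
                 list(mean = c(60, 180), kappa = 50, weight = 0.7),
                 list(mean = c(-60, -120), kappa = 50, weight = 0.3)),
               n_frames = 3e4, seed = 42)
  mx <- sampleTorsionMixture(spec)
  ls <- clusterTorsions(mx$values)
  cl <- landscapeClusters(ls)
  expect_equal(nrow(cl), 2)
  # oracle: toroidal nearest-mean assignment of the same draws
  oracle <- nearestMeanAssign(mx$values, rbind(c(60, 180), c(-60, -120)))
  expect_lt(abs(cl$population[1] - mean(oracle == 1)), 0.02)
  expect_lt(abs(cl$population[2] - mean(oracle == 2)), 0.02)
  # cluster means near the true modes
  expect_lt(abs(cl$mean_1[1] - 60), 2)
  expect_lt(abs(cl$mean_2[2] + 120), 2)
})

test_that("a mode straddling +/-180 is never split", {
  set.seed(33)
  x <- rvonmises(2e4, 179, 50)
  cl <- landscapeClusters(clusterTorsions(x))
  expect_equal(nrow(cl), 1)
  expect_lt(abs(((cl$mean_1[1] - 179 + 180) %% 360) - 180), 2)
})

test_that("clustering is invariant to a global rotation of all angles", {
  spec <- list(dimensions = "omega",
               components = list(
                 list(mean = -60, kappa = 50, weight = 0.6),
                 list(mean = 60, kappa = 50, weight = 0.4)),
               n_frames = 2e4, seed = 9)
  mx <- sampleTorsionMixture(spec)
  ls0 <- clusterTorsions(mx$values[, 1])
  rotated <- ((mx$values[, 1] + 137 + 180) %% 360) - 180
  ls1 <- clusterTorsions(rotated)
  cl0 <- landscapeClusters(ls0); cl1 <- landscapeClusters(ls1)
  expect_equal(nrow(cl0), nrow(cl1))
  expect_equal(cl0$population, cl1$population, tolerance = 0.01)
  shift <- ((cl1$mean_1 - cl0$mean_1 + 180) %% 360) - 180
  expect_equal(shift, rep(137, nrow(cl0)), tolerance = 2)
})

test_that("populations plus noise always account for every frame", {
  set.seed(5)
  x <- c(rvonmises(5000, 0, 30), runif(500, -180, 180))
  ls <- clusterTorsions(x)
  expect_equal(sum(landscapeClusters(ls)$population) + noiseFraction(ls), 1,
               tolerance = 1e-12)
  expect_equal(sum(landscapeClusters(ls)$n) + sum(clusterAssignments(ls) == 0),
               length(x))
})

test_that("the wrapped KDE integrates to one and peaks at the sample mode", {
  set.seed(77)
  x <- cbind(rvonmises(2e4, 100, 30), rvonmises(2e4, -150, 30))
  kd <- kdeLandscape(x)
  expect_equal(sum(kd$grid) * kd$cell_area, 1, tolerance = 1e-6)
  peak <- which(kd$grid == max(kd$grid), arr.ind = TRUE)
  cellw <- 360 / length(kd$x)
  expect_lt(abs(((kd$x[peak[1]] - circularMean(x[, 1]) + 180) %% 360) - 180),
            cellw)
  expect_lt(abs(((kd$y[peak[2]] - circularMean(x[, 2]) + 180) %% 360) - 180),
            cellw)
})

test_that("uniform angles give a flat KDE within Monte-Carlo noise", {
  set.seed(88)
  n <- 1e5
  x <- runif(n, -180, 180)
  kd <- kdeLandscape(x, bandwidth = 10, gridSize = 90)
  target <- 1 / 360
  # binned KDE cell values are kernel-weighted multinomial sums; bound the
  # deviation by 5 sigma of the dominant binomial term
  sigma <- target * sqrt(90 / n)
  expect_lt(max(abs(kd$grid - target)), 5 * sigma)
})

test_that("the 15-degree convergence rule is strict", {
  mk <- function(sd) {
    new("ConformerLandscape", dimensions = "phi",
        clusters = data.frame(cluster = 1L, mean_1 = 0, sd_1 = sd, n = 100L,
                              population = 1),
        noise_fraction = 0, assignments = rep(1L, 100L), kde = NULL,
        params = list())
  }
  r <- assessConvergence(list(t1 = mk(14), t2 = mk(15.0), t3 = mk(16)))
  expect_identical(unname(convergenceFlags(r)),
                   c("converged", "converged", "extend"))
  # multi-landscape trajectory: one bad cluster flips the whole trajectory
  r2 <- assessConvergence(list(t = list(mk(10), mk(15.5))))
  expect_identical(unname(convergenceFlags(r2)), "extend")
})

test_that("state predicates partition cluster populations", {
  spec <- list(dimensions = "omega",
               components = list(
                 list(mean = -60, kappa = 60, weight = 0.5),
                 list(mean = 60, kappa = 60, weight = 0.3),
                 list(mean = 180, kappa = 60, weight = 0.2)),
               n_frames = 2e4, seed = 12)
  mx <- sampleTorsionMixture(spec)
  ls <- clusterTorsions(mx$values[, 1])
  states <- statePopulations(ls, function(m)
    c("gg", "gt", "tg")[which.min(abs(((m - c(-60, 60, 180) + 180) %% 360) - 180))])
  truth <- table(c("gg", "gt", "tg")[mx$labels]) / length(mx$labels)
  for (s in names(truth))
    expect_lt(abs(states[[s]] - truth[[s]]), 0.02)
  expect_equal(sum(states) + attr(states, "noise"), 1, tolerance = 1e-9)

  # an unassigned cluster is an error
  expect_error(statePopulations(ls, function(m) NA_character_), "unassigned")
})
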