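test_that("default candidate grids match the documented values", {
  g <- defaultGrid("tsne", n = 1e5)
  expect_identical(g@perplexityValues,
                   c(seq(20, 380, by = 30), 410, seq(450, 750, by = 50),
                     800))
  expect_identical(g@perplexityValues[1:3], c(20, 50, 80))
  expect_true(410 %in% g@perplexityValues)
  expect_identical(g@perplexityValues[length(g@perplexityValues)], 800)

  u <- defaultGrid("umap", n = 1e5)
  expect_length(u@nNeighborsValues, 30L)
  expect_identical(u@nNeighborsValues, c(5:30, 35L, 40L, 45L, 50L))
  expect_length(u@minDistValues, 10L)
  expect_equal(u@minDistValues, c(0.0125, 0.05, seq(0.1, 0.8, by = 0.1)))

  # feasibility filter: only perplexity 20 survives n = 100
  expect_identical(defaultGrid("tsne", n = 100)@perplexityValues, 20)
  expect_error(defaultGrid("tsne", n = 40), "no feasible")
})

test_that("grid expansion has the right cardinality and ordering", {
  u <- defaultGrid("umap", n = 1e5)
  expect_length(scEmbedQC:::.gridSettings(u), 300L)  # joint: 30 x 10
  um <- defaultGrid("umap", n = 1e5, mode = "marginal")
  expect_length(scEmbedQC:::.gridSettings(um), 40L)  # marginal: 30 + 10
  tg <- defaultGrid("tsne", n = 1e5)
  s <- scEmbedQC:::.gridSettings(tg)
  expect_identical(vapply(s, function(x) x@perplexity, numeric(1)),
                   tg@perplexityValues)
})

test_that("grid search finds the minimizer with ties broken downward", {
  sim <- simulateClusters(nCells = 120, nGenes = 80, kClusters = 3,
                          separation = 8, seed = 31)
  grid <- hyperparamGrid("tsne", perplexityValues = c(8, 15, 25))
  opt <- gridSearch(sim$matrix, grid, numPCs = 5)
  res <- gridResults(opt)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$status == "ok"))
  mn <- min(res$n_dubious)
  best <- bestSetting(opt)
  expect_equal(res$n_dubious[res$perplexity == best@perplexity], mn)
  # ties: best is the smallest minimizer, all minimizers reported
  minPerp <- res$perplexity[res$n_dubious == mn]
  expect_equal(best@perplexity, min(minPerp))
  expect_length(opt@allMinimizers, length(minPerp))
  # exact percentage bookkeeping
  expect_equal(res$pct_dubious, 100 * res$n_dubious / 120)
})

test_that("a failed setting is recorded and excluded, not fatal", {
  sim <- simulateClusters(nCells = 60, nGenes = 40, kClusters = 2,
                          separation = 8, seed = 32)
  grid <- hyperparamGrid("tsne", perplexityValues = c(10, 50))  # 50 >= 59/3
  expect_warning(opt <- gridSearch(sim$matrix, grid, numPCs = 3),
                 "failed")
  res <- gridResults(opt)
  expect_identical(res$status, c("ok", "failed"))
  expect_true(is.na(res$n_dubious[2]))
  expect_equal(bestSetting(opt)@perplexity, 10)
})

test_that("marginal UMAP mode evaluates anchored sweeps", {
  sim <- simulateClusters(nCells = 100, nGenes = 60, kClusters = 3,
                          separation = 8, seed = 33)
  grid <- hyperparamGrid("umap", nNeighborsValues = c(8L, 15L),
                         minDistValues = c(0.1, 0.4), mode = "marginal",
                         anchorNNeighbors = 10L, anchorMinDist = 0.25)
  opt <- gridSearch(sim$matrix, grid, numPCs = 5)
  res <- gridResults(opt)
  expect_equal(nrow(res), 4L)  # 2 + 2, not 2 x 2
  expect_equal(res$min_dist[1:2], c(0.25, 0.25))
  expect_equal(res$n_neighbors[3:4], c(10L, 10L))
  expect_s4_class(bestSetting(opt), "HyperparamSetting")
})

test_that("joint UMAP mode covers the Cartesian product", {
  sim <- simulateClusters(nCells = 80, nGenes = 50, kClusters = 2,
                          separation = 8, seed = 34)
  grid <- hyperparamGrid("umap", nNeighborsValues = c(6L, 12L),
                         minDistValues = c(0.1, 0.5), mode = "joint")
  opt <- gridSearch(sim$matrix, grid, numPCs = 4)
  res <- gridResults(opt)
  expect_equal(nrow(res), 4L)
  expect_equal(res$n_neighbors, c(6L, 6L, 12L, 12L))
  expect_equal(res$min_dist, c(0.1, 0.5, 0.1, 0.5))
})

test_that("adding candidates can only improve the minimum dubious count", {
  sim <- simulateClusters(nCells = 100, nGenes = 60, kClusters = 3,
                          separation = 8, seed = 35)
  g1 <- hyperparamGrid("tsne", perplexityValues = c(5, 12))
  g2 <- hyperparamGrid("tsne", perplexityValues = c(5, 12, 20))
  m1 <- min(gridResults(gridSearch(sim$matrix, g1, numPCs = 5))$n_dubious)
  m2 <- min(gridResults(gridSearch(sim$matrix, g2, numPCs = 5))$n_dubious)
  expect_lte(m2, m1)
})

test_that("kneedle locates the elbow of a convex-decreasing curve", {
  expect_equal(kneedleElbow(1:5, c(100, 20, 10, 9, 8)), 2)
  # strictly linear: the chord equals the curve, no knee
  expect_warning(v <- kneedleElbow(1:5, c(50, 40, 30, 20, 10)), "no knee")
  expect_true(is.na(v))
  # constant counts: degenerate input
  expect_warning(v2 <- kneedleElbow(1:5, rep(3, 5)), "constant")
  expect_true(is.na(v2))
  expect_error(kneedleElbow(1:2, c(2, 1)), "at least 3")
  expect_error(kneedleElbow(c(1, 3, 2), c(3, 2, 1)), "increasing")
})

test_that("dubious counts are elevated at a too-small perplexity then flat", {
  # mid-range neighborhoods are scrambled when the perplexity is far too
  # small; past a modest threshold the count plateaus at zero
  sim <- simulateClusters(nCells = 300, nGenes = 500, kClusters = 3,
                          separation = 8, seed = 71)
  opt <- gridSearch(sim$matrix,
                    hyperparamGrid("tsne",
                                   perplexityValues = c(2, 3, 5, 20, 40, 60)),
                    numPCs = 12)
  nd <- gridResults(opt)$n_dubious
  expect_gt(nd[1], 0L)
  expect_true(all(nd[-1] == 0L))
  # the elbow of that curve sits at the start of the plateau
  expect_equal(opt@kneedleValue, 3)
})
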