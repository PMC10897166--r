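test_that("ordered neighbors follow distance then index", {
  xy <- cbind(c(0, 1, 3, 7), 0)
  expect_identical(orderedNeighbors(xy, 1, 2), c(2L, 3L))
  expect_identical(orderedNeighbors(xy, 1, 3), c(2L, 3L, 4L))
  # equidistant pair: ascending index breaks the tie
  tie <- rbind(c(0, 0), c(1, 0), c(-1, 0))
  expect_identical(orderedNeighbors(tie, 1, 2), c(2L, 3L))
  expect_error(orderedNeighbors(xy, 1, 4), "\\[1, n - 1\\]")
  expect_error(orderedNeighbors(xy, 9, 2), "out of range")
})

test_that("ordered neighbors match a full-sort brute force", {
  set.seed(21)
  xy <- matrix(rnorm(50 * 3), 50, 3)
  d1 <- vapply(seq_len(50),
               function(j) sqrt(sum((xy[1, ] - xy[j, ])^2)), numeric(1))
  expect_identical(orderedNeighbors(xy, 1, 25),
                   bruteSelectNeighbors(d1, 1, 25))
})

test_that("the ordered 2D distance vector of the embedding is non-decreasing", {
  set.seed(22)
  emb <- matrix(rnorm(40 * 2), 40, 2)
  for (i in c(1, 17, 40)) {
    b <- orderedNeighbors(emb, i, 20)
    dists <- sqrt(colSums((t(emb[b, ]) - emb[i, ])^2))
    expect_true(all(diff(dists) >= 0))
  }
})

test_that("reliability score hand oracles: identity, reversal, 11/14", {
  # identity: passthrough on a 2D pre-embedding gives 1 for every cell
  set.seed(23)
  pre <- matrix(rnorm(30 * 2), 30, 2)
  expect_equal(unname(reliabilityScores(pre, pre, 50)), rep(1, 30))

  # exact reversal of the neighbor order gives -1
  preLine <- cbind(c(0, 1, 2, 3, 20, 21), 0)
  embLine <- cbind(c(0, 3, 2, 1, 10, 11), 0)
  expect_equal(reliabilityScore(preLine, embLine, 1, 3), -1)

  # pre-ordered 2D distances (2, 1, 4) vs sorted (1, 2, 4): by the
  # covariance formula, r = 33/sqrt(42 * 42) = 11/14
  pre4 <- cbind(c(0, 1, 2, 3), 0)
  emb4 <- cbind(c(0, 2, 1, 4), 0)
  expect_equal(reliabilityScore(pre4, emb4, 1, 3), 11 / 14)
})

test_that("neighborhood size follows the half-up rounded, clamped rule", {
  expect_identical(neighborhoodSizeFor(100, 50), 50L)
  expect_identical(neighborhoodSizeFor(7, 50), 4L)    # round(3.5) half-up
  expect_identical(neighborhoodSizeFor(10, 100), 9L)  # clamp to n - 1
  expect_identical(neighborhoodSizeFor(100, 1), 2L)   # clamp to 2
  expect_error(neighborhoodSizeFor(100, 0), "similarityPercent")
})

test_that("scores match the brute-force oracle on random instances", {
  set.seed(24)
  for (rep in 1:4) {
    n <- sample(10:60, 1)
    d <- sample(2:6, 1)
    x <- sample(c(20, 50, 80, 100), 1)
    pre <- matrix(rnorm(n * d), n, d)
    emb <- matrix(rnorm(n * 2), n, 2)
    expect_equal(unname(reliabilityScores(pre, emb, x)),
                 bruteReliabilityScores(pre, emb, x), tolerance = 1e-10)
  }
})

test_that("scores are invariant under rigid motions of the 2D space", {
  set.seed(25)
  pre <- matrix(rnorm(40 * 5), 40, 5)
  emb <- matrix(rnorm(40 * 2), 40, 2)
  base <- reliabilityScores(pre, emb, 50)
  th <- 0.77
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  refl <- diag(c(1, -1))
  moved <- emb %*% rot %*% refl
  moved <- sweep(moved, 2, c(3.2, -11))
  expect_equal(unname(reliabilityScores(pre, moved, 50)), unname(base),
               tolerance = 1e-10)
  # and under reordering of the genes behind the pre-embedding space
  sim <- simulateClusters(nCells = 40, nGenes = 30, kClusters = 2,
                          separation = 6, seed = 26)
  p1 <- computePCA(sim$matrix, K = 3)
  p2 <- computePCA(sim$matrix[sample(30), ], K = 3)
  e <- matrix(rnorm(40 * 2), 40, 2)
  expect_equal(unname(reliabilityScores(coords(p1), e, 50)),
               unname(reliabilityScores(coords(p2), e, 50)),
               tolerance = 1e-8)
})

test_that("perfectly equidistant neighbors give an undefined score", {
  ang <- 2 * pi * (0:4) / 5
  emb <- rbind(c(0, 0), cbind(cos(ang), sin(ang)))
  sc <- reliabilityScores(emb, emb, 40)  # m = 2 of cell 1's equal distances
  expect_true(is.na(sc[1]))
  # circle cells see distinct distances (1 vs the 1.18 chord): defined
  expect_true(all(!is.na(sc[-1])))
})

test_that("the null pipeline is deterministic and bounded", {
  sim <- simulateClusters(nCells = 100, nGenes = 60, kClusters = 3,
                          separation = 8, seed = 27)
  s1 <- nullReliabilityScores(sim$matrix, tsneSetting(10), numPCs = 5)
  s2 <- nullReliabilityScores(sim$matrix, tsneSetting(10), numPCs = 5)
  expect_identical(s1, s2)
  expect_true(all(is.na(s1) | (s1 >= -1 & s1 <= 1)))
})

test_that("null scores sit well below the original scores' upper tail", {
  sim <- simulateClusters(nCells = 150, nGenes = 100, kClusters = 3,
                          separation = 8, seed = 28)
  pre <- computePCA(sim$matrix, K = 5)
  emb <- embed2D(pre, tsneSetting(15))
  orig <- reliabilityScores(pre, emb, 50)
  for (s in 101:105) {
    nullSc <- nullReliabilityScores(sim$matrix, tsneSetting(15), numPCs = 5,
                                    permuteSeed = s)
    expect_lt(median(nullSc, na.rm = TRUE), quantile(orig, 0.9, na.rm = TRUE))
  }
})

test_that("cutoffs follow the interpolated-quantile worked example", {
  null <- seq(0.1, 1, by = 0.1)
  r <- classifyCells(c(0.10, 0.50, 0.96), null)
  # h = 1 + p (n - 1): 1.45 -> 0.1 + 0.45 * 0.1; 9.55 -> 0.9 + 0.55 * 0.1
  expect_equal(unname(cutoffs(r)), c(0.145, 0.955))
  expect_identical(unname(cellLabels(r)),
                   c("dubious", "intermediate", "trustworthy"))
  # nearest-rank alternative
  r2 <- classifyCells(c(0.10, 0.50, 0.96), null,
                      quantileType = "nearest_rank")
  expect_equal(unname(cutoffs(r2)), c(0.1, 1.0))
})

test_that("classification is self-calibrated on its own null", {
  set.seed(29)
  null <- tanh(rnorm(200))  # distinct values on the score scale
  r <- classifyCells(null, null)
  n <- length(null)
  expect_lt(abs(mean(cellLabels(r) == "dubious") - 0.05), 1 / n + 1e-9)
  expect_lt(abs(mean(cellLabels(r) == "trustworthy") - 0.05), 1 / n + 1e-9)
})

test_that("labels follow the cutoff rules exactly", {
  null <- seq(-0.9, 0.9, length.out = 50)
  sc <- c(a = -0.9, b = 0, c = 0.9, d = NA)
  r <- classifyCells(sc, null)
  qs <- cutoffs(r)
  lab <- cellLabels(r)
  expect_identical(unname(lab[is.na(sc)]), "undefined")
  ok <- !is.na(sc)
  expect_identical(unname(lab[ok]),
                   unname(ifelse(sc[ok] <= qs[1], "dubious",
                                 ifelse(sc[ok] >= qs[2], "trustworthy",
                                        "intermediate"))))
  # dominance: every score above the whole null is trustworthy
  rAll <- classifyCells(rep(1, 10), null)
  expect_true(all(cellLabels(rAll) == "trustworthy"))
})

test_that("undefined null scores are dropped, fully undefined nulls error", {
  expect_message(r <- classifyCells(c(0.5), c(seq(0, 1, 0.1), NA, NA)),
                 "2 undefined")
  expect_error(classifyCells(c(0.5), c(NA_real_, NA_real_)),
               "all null")
})

test_that("end-to-end scoring is reproducible and returns a valid object", {
  sim <- simulateClusters(nCells = 100, nGenes = 50, kClusters = 3,
                          separation = 8, seed = 30)
  r1 <- scoreEmbedding(sim$matrix, tsneSetting(12), numPCs = 5)
  r2 <- scoreEmbedding(sim$matrix, tsneSetting(12), numPCs = 5)
  expect_identical(scores(r1), scores(r2))
  expect_identical(nullScores(r1), nullScores(r2))
  expect_s4_class(r1, "EmbeddingReliability")
  expect_identical(neighborhoodSize(r1), 50L)
  expect_true(validObject(r1))
  # user-supplied pre-embedding route
  pre <- coords(computePCA(sim$matrix, K = 4))
  r3 <- scoreEmbedding(preCoords = pre, setting = tsneSetting(12))
  expect_s4_class(r3, "EmbeddingReliability")
  expect_identical(cellIds(r3), colnames(sim$matrix))
})
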