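test_that("spearmanRho handles monotone, anti-monotone and tied data", {
  expect_identical(spearmanRho(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_identical(spearmanRho(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_lt(abs(spearmanRho(c(1, 2, 2, 4), c(1, 3, 2, 4)) -
                oracleSpearman(c(1, 2, 2, 4), c(1, 3, 2, 4))), 1e-12)
  expect_error(spearmanRho(1:2, 1:2), "at least 3")
  expect_error(spearmanRho(1:4, 1:5), "equal length")
  expect_warning(r <- spearmanRho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_identical(r, 0)
})

test_that("spearmanRho matches the hand-coded oracle on random tied vectors", {
  set.seed(1)
  for (i in 1:200) {
    n <- sample(3:20, 1)
    x <- round(rnorm(n), 1)  # rounding forces ties
    y <- round(rnorm(n), 1)
    if (var(x) == 0 || var(y) == 0) next
    expect_lt(abs(spearmanRho(x, y) - oracleSpearman(x, y)), 1e-12)
  }
})

test_that("spearmanRho is invariant under strictly increasing transforms", {
  set.seed(2)
  for (i in 1:25) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(spearmanRho(exp(x), y^3 + 5 * y), spearmanRho(x, y),
                 tolerance = 1e-12)
  }
})

test_that("weight and delta follow the half-sum / half-difference formulas", {
  wd <- edgeWeightDelta(0.8, 0.8)
  expect_identical(c(wd$weight, wd$delta), c(0.8, 0))
  wd <- edgeWeightDelta(0.6, -0.6)
  expect_identical(c(wd$weight, wd$delta), c(0, 0.6))
  wd <- edgeWeightDelta(0.9, 0.3)
  expect_equal(c(wd$weight, wd$delta), c(0.6, 0.3), tolerance = 1e-15)
  # triangle bound
  set.seed(3)
  r1 <- runif(1e4, -1, 1); r2 <- runif(1e4, -1, 1)
  wd <- edgeWeightDelta(r1, r2)
  expect_true(all(wd$weight + wd$delta <= 1 + 1e-12))
})

test_that("weightEdges drops absent edges and matches per-edge spearmanRho", {
  x <- makeToyExperiment(nGenes = 8, n1 = 5, n2 = 5, seed = 4)
  el <- EdgeList(c("G1", "G1", "G2", "G9"), c("G3", "G4", "G5", "G1"))
  expect_message(net <- weightEdges(x, el), "dropped 1 edge")
  ed <- edges(net)
  expect_identical(nrow(ed), 3L)
  M <- exprValues(x); g <- sampleGroups(x)
  for (k in seq_len(nrow(ed))) {
    r1 <- spearmanRho(M[ed$tf[k], g == levels(g)[1]],
                      M[ed$target[k], g == levels(g)[1]])
    r2 <- spearmanRho(M[ed$tf[k], g == levels(g)[2]],
                      M[ed$target[k], g == levels(g)[2]])
    expect_equal(ed$r_group1[k], r1, tolerance = 1e-12)
    expect_equal(ed$r_group2[k], r2, tolerance = 1e-12)
    expect_equal(ed$weight[k], 0.5 * abs(r1 + r2), tolerance = 1e-12)
    expect_equal(ed$delta[k], 0.5 * abs(r1 - r2), tolerance = 1e-12)
  }
  expect_error(weightEdges(x, EdgeList("Z1", "Z2")), "no edge")
})

test_that("swapping group labels leaves weight and delta unchanged", {
  x <- makeToyExperiment(nGenes = 10, n1 = 4, n2 = 6, seed = 6)
  g <- sampleGroups(x)
  swapped <- setNames(ifelse(g == levels(g)[1], levels(g)[2], levels(g)[1]),
                      names(g))
  y <- TwoGroupExperiment(exprValues(x), swapped)
  el <- EdgeList(rep("G1", 5), paste0("G", 2:6))
  a <- edges(weightEdges(x, el)); b <- edges(weightEdges(y, el))
  expect_equal(b$weight, a$weight, tolerance = 1e-12)
  expect_equal(b$delta, a$delta, tolerance = 1e-12)
  expect_equal(b$r_group1, a$r_group2, tolerance = 1e-12)
})

test_that("duplicated-group data has zero deltas and nothing passes keep_above", {
  set.seed(10)
  half <- matrix(rnorm(20 * 10, 8), nrow = 20)
  m <- cbind(half, half)
  dimnames(m) <- list(paste0("G", 1:20), paste0("S", 1:20))
  x <- TwoGroupExperiment(m, setNames(rep(c("a", "b"), each = 10), colnames(m)))
  el <- EdgeList(rep("G1", 10), paste0("G", 2:11))
  net <- weightEdges(x, el)
  expect_true(all(edges(net)$delta == 0))
  suppressMessages(
    net <- permutationFilter(x, net, nPermutations = 100, quantile = 0.9,
                             seed = 1))
  expect_false(any(edges(net)$passed_filter))
})

test_that("permutation filter validates inputs and is seed-deterministic", {
  x <- makeToyExperiment(nGenes = 12, n1 = 5, n2 = 5, seed = 12)
  el <- EdgeList(rep("G1", 8), paste0("G", 2:9))
  net <- weightEdges(x, el)
  expect_error(permutationFilter(x, net, nPermutations = 50, seed = 1), ">= 100")
  expect_error(permutationFilter(x, net, quantile = 1.5, seed = 1), "quantile")
  suppressMessages({
    a <- permutationFilter(x, net, nPermutations = 100, seed = 5)
    b <- permutationFilter(x, net, nPermutations = 100, seed = 5)
  })
  expect_identical(edges(a), edges(b))
  expect_identical(a@threshold, b@threshold)
})

test_that("raising the quantile never increases the passing count", {
  cfg <- simulationConfig(nGroup1 = 15, nGroup2 = 15, nGenes = 100, nTfs = 5,
                          targetsPerTf = c(10, 10), nPlantedDegs = 0,
                          nPlantedDiffcoregTfs = 1, seed = 13)
  sim <- simulateDataset(cfg)
  net <- weightEdges(sim$experiment, sim$edges)
  counts <- vapply(c(0.5, 0.7, 0.9, 0.95), function(q) {
    suppressMessages(f <- permutationFilter(sim$experiment, net,
                                            nPermutations = 100, quantile = q,
                                            seed = 2))
    sum(edges(f)$passed_filter)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted differential co-regulation passes the filter with high power", {
  cfg <- simulationConfig(nGroup1 = 30, nGroup2 = 30, nGenes = 200, nTfs = 5,
                          targetsPerTf = c(20, 20), nPlantedDegs = 0,
                          nPlantedDiffcoregTfs = 1, plantedRhoGroup1 = 0.8,
                          plantedRhoGroup2 = -0.2, seed = 14)
  sim <- simulateDataset(cfg)
  net <- weightEdges(sim$experiment, sim$edges)
  suppressMessages(
    net <- permutationFilter(sim$experiment, net, nPermutations = 200,
                             quantile = 0.9, seed = 3))
  ed <- edges(net)
  planted <- ed$tf %in% sim$truth$true_diffcoreg_tf_ids
  expect_gte(mean(ed$passed_filter[planted]), 0.9)
})
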