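test_that("hub selection uses a strict degree cut-off with deterministic order", {
  tf <- c(rep("TFA", 16), rep("TFB", 15), rep("TFC", 30))
  net <- makeNetworkFromCors(tf, paste0("g", seq_along(tf)),
                             r1 = rep(0.5, length(tf)), r2 = rep(-0.5, length(tf)))
  hubs <- selectHubTFs(net, minDegree = 15)
  expect_identical(as.character(hubs), c("TFC", "TFA"))  # TFB at 15 excluded
  expect_identical(attr(hubs, "degree"), c(30L, 16L))
  expect_message(h0 <- selectHubTFs(net, minDegree = 100), "no TF")
  expect_identical(length(h0), 0L)
})

test_that("degree source switches between passing and all edges", {
  tf <- rep(c("TFA", "TFB"), each = 20)
  passed <- c(rep(TRUE, 20), rep(c(TRUE, FALSE), 10))
  net <- makeNetworkFromCors(tf, paste0("g", seq_along(tf)),
                             r1 = rep(0.6, 40), r2 = rep(-0.6, 40),
                             passed = passed)
  expect_identical(as.character(selectHubTFs(net, 15, "passing")), "TFA")
  expect_identical(as.character(selectHubTFs(net, 15, "all")), c("TFA", "TFB"))
})

test_that("extreme membership placements give the expected ES", {
  w <- seq(10, 1)
  m <- c(TRUE, rep(FALSE, 9))
  top <- runningES(w, m)
  expect_equal(top$es, 1 - 0, tolerance = 1e-15)  # all hit mass before any miss
  expect_identical(top$leadingEdge, 1L)

  bottom <- runningES(w, rev(m))
  expect_equal(bottom$es, 0, tolerance = 1e-15)   # curves only meet at the end
  expect_identical(bottom$argmax, 10L)
})

test_that("running ES equals the brute-force scan on a worked example", {
  w <- c(5, 4, 3, 2, 1)
  m <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  got <- runningES(w, m, pExponent = 1)
  o <- oracleES(w, m, p = 1)
  expect_equal(got$es, o$es, tolerance = 1e-12)
  expect_identical(got$argmax, o$argmax)
})

test_that("running ES is validated at the boundaries", {
  expect_error(runningES(c(3, 2, 1), c(TRUE, TRUE, TRUE)), "whole background")
  expect_error(runningES(c(3, 2, 1), c(FALSE, FALSE, FALSE)), "empty")
  expect_error(runningES(c(1, 2, 3), c(TRUE, FALSE, FALSE)), "descending")
  expect_error(runningES(c(0, 0, 0), c(TRUE, TRUE, FALSE)), "zero")
})

test_that("running ES matches the oracle exhaustively for small N", {
  set.seed(20)
  for (N in 2:8) {
    w <- sort(runif(N, 0.1, 5), decreasing = TRUE)
    for (mask in seq_len(2^N - 2)) {
      m <- as.logical(bitwAnd(mask, 2^(seq_len(N) - 1)))
      got <- runningES(w, m)
      o <- oracleES(w, m)
      expect_equal(got$es, o$es, tolerance = 1e-12)
      expect_gte(got$es, -1)
      expect_lte(got$es, 1 + 1e-12)
    }
  }
})

test_that("ES is invariant to positive rescaling of the weights", {
  set.seed(21)
  w <- sort(runif(30, 0, 2), decreasing = TRUE)
  m <- rep(FALSE, 30); m[sample(30, 7)] <- TRUE
  expect_equal(runningES(w * 37.5, m)$es, runningES(w, m)$es, tolerance = 1e-12)
})

test_that("with tied weights, promoting a member edge never decreases the ES", {
  # With unequal weights the N_R renormalization can shrink earlier hit
  # increments, so monotonicity under promotion only holds for tied weights.
  set.seed(22)
  for (rep in 1:20) {
    N <- 15
    w <- rep(1, N)
    m <- rep(FALSE, N); m[sample(N, 4)] <- TRUE
    es0 <- runningES(w, m)$es
    i <- which(m & c(FALSE, !m[-N]))[1]  # a member right below a non-member
    if (is.na(i)) next
    m2 <- m; m2[i] <- FALSE; m2[i - 1] <- TRUE
    expect_gte(runningES(w, m2)$es + 1e-12, es0)
  }
})

test_that("running ES agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(23)
  for (rep in 1:20) {
    N <- 50
    w <- sort(runif(N, 0.05, 4), decreasing = TRUE)
    m <- rep(FALSE, N); m[sample(10, 4)] <- TRUE  # members near the top
    got <- runningES(w, m, convention = "absolute")
    ref <- fgsea::calcGseaStat(w, which(m), gseaParam = 1)
    if (got$es > 0 && ref > 0)
      expect_equal(got$es, ref, tolerance = 1e-10)
  }
})

test_that("subnet scoring standardizes against a size-matched null", {
  set.seed(24)
  n <- 60
  r1 <- runif(n, -1, 1); r2 <- runif(n, -1, 1)
  tf <- c(rep("TFA", 20), rep("TFB", 40))
  net <- makeNetworkFromCors(tf, paste0("g", 1:n), r1, r2)
  sc <- scoreSubnet(net, "TFA", nNull = 500, seed = 9)
  expect_s4_class(sc, "SubnetScore")
  expect_identical(nrow(sc@memberEdges), 20L)
  expect_true(all(sc@leadingEdge$tf == "TFA"))
  expect_equal(sc@zS, (sc@es - sc@nullMean) / sc@nullSD, tolerance = 1e-12)
  expect_gte(sc@es, -1); expect_lte(sc@es, 1)
  # determinism
  sc2 <- scoreSubnet(net, "TFA", nNull = 500, seed = 9)
  expect_identical(sc@nullES, sc2@nullES)
  expect_error(scoreSubnet(net, "TFZ", nNull = 100, seed = 1), "no passing")
})

test_that("a TF holding the top-delta edges outscores a random TF", {
  set.seed(25)
  wins <- 0L
  for (rep in 1:50) {
    n <- 80
    delta <- sort(runif(n, 0, 1), decreasing = TRUE)
    r1 <- pmin(1, 2 * delta); r2 <- r1 - 2 * delta  # realize the deltas
    tf <- rep("bg", n)
    tf[1:12] <- "planted"                      # owns the top deltas
    tf[sample(which(tf == "bg"), 12)] <- "null"
    net <- makeNetworkFromCors(tf, paste0("g", 1:n), r1, r2)
    zp <- scoreSubnet(net, "planted", nNull = 200, seed = rep)@zS
    zn <- scoreSubnet(net, "null", nNull = 200, seed = rep + 1000)@zS
    wins <- wins + (zp > zn)
  }
  expect_gte(wins / 50, 0.95)
})
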