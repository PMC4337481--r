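# A minimal SubnetScore to feed the gene-level stage directly.
makeSubnet <- function(tf, targets, zS = 2, degenerate = FALSE) {
  ed <- data.frame(tf = tf, target = targets, delta = seq(1, 0.5,
                   length.out = length(targets)), stringsAsFactors = FALSE)
  new("SubnetScore", tfId = tf, memberEdges = ed, es = 0.5, leadingEdge = ed,
      nullES = rnorm(100, 0.2, 0.1), nullMean = 0.5 - zS * 0.1, nullSD = 0.1,
      zS = zS, degenerate = degenerate)
}

makeDegRecords <- function(geneIds, p, fc = NULL) {
  if (is.null(fc)) fc <- rep(2, length(geneIds))
  data.frame(gene_id = geneIds, log2fc = fc, t_stat = 0, p_value = p,
             p_adjusted = pmin(1, p * 2),
             is_deg = p < 0.05 & abs(fc) > 1.5,
             direction = ifelse(fc > 0, "up", "down"), stringsAsFactors = FALSE)
}

test_that("trimmed genes at the top of the DEG ranking give ES = 1", {
  ids <- paste0("g", 1:10)
  p <- sort(c(1e-8, 1e-7, seq(0.2, 0.9, length.out = 8)))
  rec <- makeDegRecords(ids, p)  # g1, g2 hold the two smallest p
  sn <- makeSubnet("TFX", c("g1", "g2"))
  cs <- scoreTrimmedGenes(rec, sn, nNull = 200, seed = 1, includeTf = FALSE)
  expect_equal(cs@esGenes, 1, tolerance = 1e-12)
  expect_identical(sort(cs@leadingGenes), c("g1", "g2"))
})

test_that("gene-level ES matches the brute-force scan on the worked example", {
  ids <- paste0("g", 1:6)
  p <- c(1e-4, 1e-3, 1e-2, 0.05, 0.5, 0.9)
  rec <- makeDegRecords(ids, p)
  sn <- makeSubnet("TFX", c("g1", "g4"))  # members at ranks 1 and 4
  cs <- scoreTrimmedGenes(rec, sn, nNull = 100, seed = 2, includeTf = FALSE)
  w <- sort(-log10(p), decreasing = TRUE)
  o <- oracleES(w, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(cs@esGenes, o$es, tolerance = 1e-12)
})

test_that("z_trimmed standardizes the gene ES and z_combined is additive", {
  set.seed(3)
  ids <- paste0("g", 1:40)
  rec <- makeDegRecords(ids, runif(40, 1e-6, 1))
  sn <- makeSubnet("TFX", sample(ids, 6), zS = 1.7)
  cs <- scoreTrimmedGenes(rec, sn, nNull = 400, seed = 4, includeTf = FALSE)
  expect_equal(cs@zCombined, cs@zS + cs@zTrimmed, tolerance = 1e-12)
  expect_identical(cs@zS, 1.7)
  # changing only the gene-level null (different seed) shifts z_combined by
  # exactly the change in z_trimmed
  cs2 <- scoreTrimmedGenes(rec, sn, nNull = 400, seed = 5, includeTf = FALSE)
  expect_equal(cs2@zCombined - cs@zCombined, cs2@zTrimmed - cs@zTrimmed,
               tolerance = 1e-12)
})

test_that("the TF joins its trimmed set only when expressed and requested", {
  ids <- c("TFX", paste0("g", 1:9))
  rec <- makeDegRecords(ids, seq(0.001, 0.9, length.out = 10))
  sn <- makeSubnet("TFX", c("g1", "g2"))
  withTf <- scoreTrimmedGenes(rec, sn, nNull = 100, seed = 6)
  expect_true("TFX" %in% withTf@trimmedGenes)
  without <- scoreTrimmedGenes(rec, sn, nNull = 100, seed = 6, includeTf = FALSE)
  expect_false("TFX" %in% without@trimmedGenes)
  # absent genes are dropped with a message; empty intersection errors
  snBad <- makeSubnet("TFY", c("zz1", "g1"))
  expect_message(ok <- scoreTrimmedGenes(rec, snBad, nNull = 100, seed = 7,
                                         includeTf = FALSE), "absent")
  expect_identical(ok@trimmedGenes, "g1")
  snAll <- makeSubnet("TFZ", c("zz1", "zz2"))
  expect_error(scoreTrimmedGenes(rec, snAll, nNull = 100, seed = 8,
                                 includeTf = FALSE), "empty")
})

test_that("DEG annotation intersects trimmed genes with the DEG flags", {
  ids <- c("TFX", paste0("g", 1:5))
  rec <- makeDegRecords(ids, c(0.01, 0.01, 0.01, 0.5, 0.5, 0.01))
  sn <- makeSubnet("TFX", c("g1", "g2", "g3"))
  cs <- scoreTrimmedGenes(rec, sn, nNull = 100, seed = 9, includeTf = FALSE)
  cs <- annotateRegulatedDEGs(cs, rec)
  expect_identical(cs@regulatedDEGs, c("g1", "g2"))  # g3 fails p, g5 not trimmed
  expect_true(cs@tfIsDEG)
  # no DEGs among trimmed genes -> empty but still reported
  recNull <- makeDegRecords(ids, rep(0.9, 6))
  cs2 <- annotateRegulatedDEGs(cs, recNull)
  expect_identical(cs2@regulatedDEGs, character(0))
  expect_false(cs2@tfIsDEG)
})

test_that("candidate ranking sorts by combined Z with lexicographic ties", {
  mk <- function(tf, zS, zT) {
    new("CombinedScore", tfId = tf, trimmedGenes = c("a", "b"), esGenes = 0.4,
        leadingGenes = "a", zTrimmed = zT, zS = zS, zCombined = zS + zT,
        regulatedDEGs = character(0), tfIsDEG = FALSE, degenerate = FALSE)
  }
  res <- list(mk("TFA", 2.0, 1.1), mk("TFB", 1.0, 0.2), mk("TFC", 1.5, 0.5))
  top2 <- rankCandidates(res, topK = 2)
  expect_identical(top2$tf_id, c("TFA", "TFC"))
  expect_identical(top2$rank, 1:2)
  tied <- list(mk("TFB", 1.0, 0.5), mk("TFA", 0.5, 1.0))
  expect_identical(rankCandidates(tied, topK = 2)$tf_id, c("TFA", "TFB"))
  expect_error(rankCandidates(res, topK = 0), ">= 1")
})

test_that("re-standardized ranking keeps additivity over its own components", {
  mk <- function(tf, zS, zT) {
    new("CombinedScore", tfId = tf, trimmedGenes = "a", esGenes = 0.1,
        leadingGenes = "a", zTrimmed = zT, zS = zS, zCombined = zS + zT,
        regulatedDEGs = character(0), tfIsDEG = FALSE, degenerate = FALSE)
  }
  res <- list(mk("TFA", 3, 0.5), mk("TFB", 1, 2.5), mk("TFC", -1, 0))
  tab <- rankCandidates(res, topK = 3, standardize = TRUE)
  expect_equal(tab$z_combined, tab$z_s + tab$z_trimmed, tolerance = 1e-12)
})
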