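# Synthetic two-group expression data with planted, known ground truth:
# log2-scale Gaussian baseline, planted fold changes, a TF->target network
# with hub TFs, and TF-target pairs whose within-group correlation differs
# between groups (Gaussian copula construction).

#' Simulation configuration
#'
#' Defaults mirror the unbalanced two-group microarray design the pipeline is
#' aimed at (23 vs 77 samples) with log2-scale Gaussian expression around a
#' baseline of 8. Planted differentially expressed genes shift the group-2 mean
#' by \code{degLog2fc}; planted differentially co-regulated TFs drive their
#' targets with within-group correlation \code{plantedRhoGroup1} in group 1 and
#' \code{plantedRhoGroup2} in group 2 via a Gaussian copula
#' (\eqn{z_{target} = \rho z_{tf} + \sqrt{1-\rho^2}\,\epsilon}), which plants
#' the population correlation exactly.
#'
#' @param nGroup1,nGroup2 samples per group (>= 3 each).
#' @param nGenes size of the non-TF gene pool (TF genes are added on top).
#' @param nTfs number of TF genes; each receives a target set drawn from the
#'   gene pool.
#' @param targetsPerTf length-2 integer range (min, max) of targets per TF.
#' @param nPlantedDegs genes given a planted log2 fold change.
#' @param degLog2fc planted shift of the group-2 mean, log2 units.
#' @param nPlantedDiffcoregTfs TFs whose target edges get planted within-group
#'   correlations.
#' @param plantedRhoGroup1,plantedRhoGroup2 planted correlations, in [-1, 1].
#' @param noiseSd per-gene, per-sample Gaussian noise sd (log2 units).
#' @param seed integer RNG seed; fully determines the dataset.
#' @param overlapDegsWithPlantedTargets when \code{TRUE}, planted DEGs are
#'   drawn first from the planted TFs' targets (so differential co-regulation
#'   and differential expression coincide); default \code{FALSE} keeps the two
#'   signals on disjoint genes where possible.
#' @param groupLabels two group labels; the second is the "case" group whose
#'   mean is shifted.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nGroup1 = 23, nGroup2 = 77, nGenes = 1000,
                             nTfs = 20, targetsPerTf = c(5, 30),
                             nPlantedDegs = 50, degLog2fc = 2,
                             nPlantedDiffcoregTfs = 2,
                             plantedRhoGroup1 = 0.8, plantedRhoGroup2 = -0.2,
                             noiseSd = 0.5, seed,
                             overlapDegsWithPlantedTargets = FALSE,
                             groupLabels = c("control", "tumor")) {
  if (missing(seed)) stop("'seed' is required for reproducibility")
  cfg <- list(nGroup1 = as.integer(nGroup1), nGroup2 = as.integer(nGroup2),
              nGenes = as.integer(nGenes), nTfs = as.integer(nTfs),
              targetsPerTf = as.integer(targetsPerTf),
              nPlantedDegs = as.integer(nPlantedDegs),
              degLog2fc = as.numeric(degLog2fc),
              nPlantedDiffcoregTfs = as.integer(nPlantedDiffcoregTfs),
              plantedRhoGroup1 = as.numeric(plantedRhoGroup1),
              plantedRhoGroup2 = as.numeric(plantedRhoGroup2),
              noiseSd = as.numeric(noiseSd), seed = as.integer(seed),
              overlapDegsWithPlantedTargets =
                isTRUE(overlapDegsWithPlantedTargets),
              groupLabels = as.character(groupLabels))
  with(cfg, {
    if (nGroup1 < 3L || nGroup2 < 3L) stop("each group needs >= 3 samples")
    if (nGenes < 1L) stop("'nGenes' must be positive")
    if (nTfs < 0L) stop("'nTfs' must be non-negative")
    if (length(targetsPerTf) != 2L || targetsPerTf[1] < 1L ||
        targetsPerTf[1] > targetsPerTf[2])
      stop("'targetsPerTf' must be an increasing (min, max) pair of counts")
    if (nTfs > 0L && targetsPerTf[2] > nGenes)
      stop("targetsPerTf max exceeds the gene pool")
    if (nPlantedDegs > nGenes) stop("more planted DEGs than genes")
    if (nPlantedDiffcoregTfs > nTfs) stop("more planted TFs than TFs")
    if (abs(plantedRhoGroup1) > 1 || abs(plantedRhoGroup2) > 1)
      stop("planted correlations must lie in [-1, 1]")
    if (noiseSd <= 0) stop("'noiseSd' must be positive")
    if (length(groupLabels) != 2L || groupLabels[1] == groupLabels[2])
      stop("'groupLabels' must be two distinct labels")
  })
  structure(cfg, class = "SimulationConfig")
}

#' Preset for the unbalanced cohort design
#'
#' Convenience wrapper around \code{\link{simulationConfig}} pinning the
#' unbalanced 23 vs 77 two-group design typical of tumour/non-tumour cohort
#' series, to exercise unequal-group code paths explicitly.
#'
#' @param seed integer RNG seed.
#' @param ... overrides passed on to \code{\link{simulationConfig}}.
#' @export
unbalancedDesignConfig <- function(seed, ...)
  simulationConfig(nGroup1 = 23, nGroup2 = 77, seed = seed, ...)

#' Simulate an expression dataset with planted ground truth
#'
#' Generates the expression matrix, TF->target edge list and ground-truth
#' record from a \code{\link{simulationConfig}}. Baseline expression is
#' \eqn{N(8, \sigma^2)} per gene and sample. Planted DEGs have the group-2 mean
#' shifted by \code{degLog2fc}. Targets of planted TFs are built on
#' standardized scales as \eqn{\rho_g z_{tf} + \sqrt{1-\rho_g^2}\,\epsilon}
#' within each group, then rescaled to the baseline mean/sd (plus the DEG shift
#' where applicable), so the planted within-group population correlation is
#' exact. All remaining genes and edges carry no systematic signal.
#'
#' @param config a \code{"SimulationConfig"}.
#' @return A list with elements \code{experiment}
#'   (\linkS4class{TwoGroupExperiment}), \code{edges}
#'   (\linkS4class{EdgeList}) and \code{truth} (list with
#'   \code{true_deg_ids}, \code{true_diffcoreg_tf_ids}, \code{edge_truth}
#'   data.frame of planted per-edge correlations, and the emitted
#'   \code{gene_universe} / \code{tf_universe}).
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  c0 <- config
  set.seed(c0$seed)

  genePool <- sprintf("G%05d", seq_len(c0$nGenes))
  tfIds <- if (c0$nTfs > 0L) sprintf("TF%03d", seq_len(c0$nTfs)) else character(0)
  allIds <- c(tfIds, genePool)
  n1 <- c0$nGroup1; n2 <- c0$nGroup2; n <- n1 + n2
  sampleIds <- sprintf("S%03d", seq_len(n))
  design <- setNames(rep(c0$groupLabels, c(n1, n2)), sampleIds)
  g2 <- (n1 + 1L):n

  # network: per-TF target sets drawn without replacement from the pool
  tf <- character(0); target <- character(0)
  for (t in tfIds) {
    k <- if (c0$targetsPerTf[1] == c0$targetsPerTf[2]) c0$targetsPerTf[1]
         else sample(c0$targetsPerTf[1]:c0$targetsPerTf[2], 1L)
    target <- c(target, sample(genePool, k))
    tf <- c(tf, rep(t, k))
  }
  el <- EdgeList(tf, target)

  plantedTfs <- if (c0$nPlantedDiffcoregTfs > 0L)
    sort(sample(tfIds, c0$nPlantedDiffcoregTfs)) else character(0)
  plantedTargets <- unique(target[tf %in% plantedTfs])

  degIds <- character(0)
  if (c0$nPlantedDegs > 0L) {
    if (c0$overlapDegsWithPlantedTargets && length(plantedTargets)) {
      first <- sample(plantedTargets, min(length(plantedTargets), c0$nPlantedDegs))
      rest <- setdiff(genePool, first)
      extra <- c0$nPlantedDegs - length(first)
      degIds <- sort(c(first, if (extra > 0L) sample(rest, extra)))
    } else {
      pref <- setdiff(genePool, plantedTargets)
      if (length(pref) >= c0$nPlantedDegs) degIds <- sort(sample(pref, c0$nPlantedDegs))
      else degIds <- sort(c(pref, sample(plantedTargets,
                                         c0$nPlantedDegs - length(pref))))
    }
  }

  # baseline z-scores for every gene, then copula overwrite for planted targets
  Z <- matrix(rnorm(length(allIds) * n), nrow = length(allIds),
              dimnames = list(allIds, sampleIds))
  edgeTruth <- data.frame(tf = tf, target = target,
                          rho_group1 = rep(0, length(tf)),
                          rho_group2 = rep(0, length(tf)),
                          stringsAsFactors = FALSE)
  for (t in plantedTfs) {
    tg <- target[tf == t]
    ztf <- Z[t, ]
    for (gene in tg) {
      eps <- rnorm(n)
      zt <- numeric(n)
      zt[-g2] <- c0$plantedRhoGroup1 * ztf[-g2] +
        sqrt(1 - c0$plantedRhoGroup1^2) * eps[-g2]
      zt[g2] <- c0$plantedRhoGroup2 * ztf[g2] +
        sqrt(1 - c0$plantedRhoGroup2^2) * eps[g2]
      Z[gene, ] <- zt
    }
    hit <- edgeTruth$tf == t
    edgeTruth$rho_group1[hit] <- c0$plantedRhoGroup1
    edgeTruth$rho_group2[hit] <- c0$plantedRhoGroup2
  }

  X <- 8 + c0$noiseSd * Z
  if (length(degIds)) X[degIds, g2] <- X[degIds, g2] + c0$degLog2fc

  truth <- list(true_deg_ids = degIds,
                true_diffcoreg_tf_ids = plantedTfs,
                edge_truth = edgeTruth,
                gene_universe = allIds,
                tf_universe = tfIds)
  list(experiment = TwoGroupExperiment(X, design), edges = el, truth = truth)
}

#' Simulate GMT-style gene sets with one DEG-enriched set
#'
#' The first set draws at least 60\% of its members from the planted DEG ids
#' (fewer when fewer exist); the remaining sets are uniform draws from the
#' gene universe.
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{simulateDataset}}.
#' @param nSets number of sets (>= 1).
#' @param seed integer RNG seed.
#' @param setSize members per set.
#' @param enrichedFraction target fraction of true DEGs in the first set.
#' @return A \linkS4class{GeneSetList}; the enriched set is named
#'   \code{"SET001"}.
#' @export
simulateGeneSets <- function(truth, nSets, seed, setSize = 20,
                             enrichedFraction = 0.6) {
  if (nSets < 1L) stop("'nSets' must be >= 1")
  set.seed(as.integer(seed))
  uni <- truth$gene_universe
  if (setSize > length(uni)) stop("'setSize' exceeds the gene universe")
  sets <- list()
  nDeg <- min(length(truth$true_deg_ids), ceiling(enrichedFraction * setSize))
  core <- if (nDeg > 0L) sample(truth$true_deg_ids, nDeg) else character(0)
  fill <- sample(setdiff(uni, core), setSize - length(core))
  sets[["SET001"]] <- c(core, fill)
  for (i in seq_len(nSets - 1L))
    sets[[sprintf("SET%03d", i + 1L)]] <- sample(uni, setSize)
  desc <- setNames(c("planted DEG-enriched set",
                     rep("random set", nSets - 1L))[seq_len(nSets)],
                   names(sets))
  GeneSetList(sets, desc)
}
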