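# S4 containers for the pipeline: expression data with a two-group design,
# TF->target edge lists, gene-set collections, weighted/filtered networks,
# and per-TF enrichment results.

#' @import methods
#' @importFrom stats cor p.adjust phyper pt quantile rnorm sd setNames var
#' @importFrom utils head packageVersion read.delim write.table
NULL

#' Two-group expression experiment
#'
#' A \linkS4class{SummarizedExperiment} restricted to the design every stage of
#' the pipeline assumes: a genes x samples matrix of finite log2-scale
#' expression values (assay \code{"exprs"}) and a \code{group} factor in
#' \code{colData} with exactly two levels, each holding at least three samples.
#' Gene and sample identifiers must be unique.
#'
#' @slot .Data inherited \code{SummarizedExperiment} internals.
#' @seealso \code{\link{TwoGroupExperiment}} (constructor),
#'   \code{\link{readExpressionMatrix}}, \code{\link{simulateDataset}}
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass TwoGroupExperiment
setClass("TwoGroupExperiment", contains = "SummarizedExperiment")

setValidity("TwoGroupExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  gn <- rownames(object)
  sn <- colnames(object)
  if (is.null(gn) || anyDuplicated(gn))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(sn) || anyDuplicated(sn))
    msg <- c(msg, "sample ids must be present and unique")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object))) {
    msg <- c(msg, "colData must contain a 'group' factor")
  } else {
    g <- SummarizedExperiment::colData(object)$group
    if (!is.factor(g)) msg <- c(msg, "'group' must be a factor")
    else {
      if (nlevels(g) != 2L)
        msg <- c(msg, sprintf("design must have exactly two groups, found %d",
                              nlevels(g)))
      else if (any(table(g) < 3L))
        msg <- c(msg, "each group must contain at least 3 samples")
    }
  }
  if ("exprs" %in% SummarizedExperiment::assayNames(object)) {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(v)) msg <- c(msg, "expression values must be numeric")
    else if (!all(is.finite(v))) msg <- c(msg, "all expression values must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' TF-to-target edge list
#'
#' A directed edge list of putative regulatory interactions (one row per
#' TF, target pair). No self-loops, no duplicated pairs; first-seen order is
#' preserved.
#'
#' @slot edges \code{data.frame} with character columns \code{tf} and
#'   \code{target}.
#' @seealso \code{\link{readEdgeList}}, \code{\link{weightEdges}}
#' @exportClass EdgeList
setClass("EdgeList", representation(edges = "data.frame"))

setValidity("EdgeList", function(object) {
  ed <- object@edges
  msg <- character()
  if (!all(c("tf", "target") %in% colnames(ed)))
    return("edges must have columns 'tf' and 'target'")
  if (nrow(ed)) {
    if (!is.character(ed$tf) || !is.character(ed$target))
      msg <- c(msg, "'tf' and 'target' must be character")
    if (any(ed$tf == ed$target))
      msg <- c(msg, "self-loops (tf == target) are not allowed")
    if (anyDuplicated(paste(ed$tf, ed$target, sep = "\r")))
      msg <- c(msg, "duplicated (tf, target) pairs are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Gene-set collection
#'
#' Named gene sets as read from a GMT file: each set has a description and a
#' non-empty, duplicate-free member vector.
#'
#' @slot sets named \code{list} of character vectors (members per set).
#' @slot descriptions named \code{character}, parallel to \code{sets}.
#' @seealso \code{\link{readGMT}}, \code{\link{hypergeomORA}}
#' @exportClass GeneSetList
setClass("GeneSetList",
         representation(sets = "list", descriptions = "character"))

setValidity("GeneSetList", function(object) {
  msg <- character()
  ids <- names(object@sets)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "set ids must be present and unique")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "every set must be non-empty")
  if (!identical(names(object@descriptions), ids))
    msg <- c(msg, "descriptions must be named parallel to sets")
  if (length(msg)) msg else TRUE
})

#' Weighted (and optionally permutation-filtered) regulatory network
#'
#' Each edge carries the two within-group Spearman coefficients
#' \code{r_group1}, \code{r_group2}, the weight \eqn{\frac12|r_1 + r_2|}, the
#' differential coefficient (delta) \eqn{\frac12|r_1 - r_2|}, and a
#' \code{passed_filter} flag set by \code{\link{permutationFilter}} (all
#' \code{NA} before filtering). Filter metadata (null threshold, permutation
#' count, quantile, mode, seed) is stored alongside.
#'
#' @slot edges \code{data.frame} with columns \code{tf}, \code{target},
#'   \code{r_group1}, \code{r_group2}, \code{weight}, \code{delta},
#'   \code{passed_filter}.
#' @slot threshold numeric; permutation-null delta quantile (\code{NA} before
#'   filtering).
#' @slot nPermutations integer; permutations used (0 before filtering).
#' @slot quantile numeric; the null quantile level.
#' @slot mode character; \code{"keep_above"} or \code{"drop_above"}.
#' @slot seed integer; RNG seed of the filter.
#' @seealso \code{\link{weightEdges}}, \code{\link{permutationFilter}},
#'   \code{\link{selectHubTFs}}
#' @exportClass WeightedNetwork
setClass("WeightedNetwork",
         representation(edges = "data.frame", threshold = "numeric",
                        nPermutations = "integer", quantile = "numeric",
                        mode = "character", seed = "integer"))

setValidity("WeightedNetwork", function(object) {
  ed <- object@edges
  need <- c("tf", "target", "r_group1", "r_group2", "weight", "delta",
            "passed_filter")
  if (!all(need %in% colnames(ed)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(ed)) {
    if (any(abs(ed$r_group1) > 1 + 1e-12) || any(abs(ed$r_group2) > 1 + 1e-12))
      msg <- c(msg, "correlations must lie in [-1, 1]")
    if (max(abs(ed$weight - 0.5 * abs(ed$r_group1 + ed$r_group2))) > 1e-12)
      msg <- c(msg, "weight must equal |r_group1 + r_group2| / 2")
    if (max(abs(ed$delta - 0.5 * abs(ed$r_group1 - ed$r_group2))) > 1e-12)
      msg <- c(msg, "delta must equal |r_group1 - r_group2| / 2")
    if (!is.logical(ed$passed_filter))
      msg <- c(msg, "'passed_filter' must be logical")
  }
  if (length(msg)) msg else TRUE
})

#' Edge-level enrichment score of one TF's subnetwork
#'
#' Result of \code{\link{scoreSubnet}}: the TF's passing edges (objective set
#' S), the running-sum enrichment score over the ranked background of all
#' passing edges, the leading-edge (trimmed) members, the random-subset null
#' distribution and the standardized score
#' \eqn{Z_s = (ES - \overline{ES}) / S'}.
#'
#' @slot tfId character; the hub TF.
#' @slot memberEdges \code{data.frame} (\code{tf}, \code{target},
#'   \code{delta}): the TF's passing edges.
#' @slot es numeric enrichment score.
#' @slot leadingEdge \code{data.frame}, subset of \code{memberEdges} at ranks
#'   up to the ES position.
#' @slot nullES numeric vector of null enrichment scores.
#' @slot nullMean,nullSD numeric summaries of the null.
#' @slot zS numeric standardized score (\code{NA} when degenerate).
#' @slot degenerate logical; \code{TRUE} when the null has zero spread.
#' @exportClass SubnetScore
setClass("SubnetScore",
         representation(tfId = "character", memberEdges = "data.frame",
                        es = "numeric", leadingEdge = "data.frame",
                        nullES = "numeric", nullMean = "numeric",
                        nullSD = "numeric", zS = "numeric",
                        degenerate = "logical"))

setValidity("SubnetScore", function(object) {
  msg <- character()
  if (length(object@tfId) != 1L) msg <- c(msg, "tfId must be length 1")
  if (nrow(object@leadingEdge) > nrow(object@memberEdges))
    msg <- c(msg, "leading edge cannot exceed member edges")
  if (!object@degenerate && length(object@zS) == 1L && !is.na(object@zS) &&
      length(object@nullSD) == 1L && object@nullSD > 0 &&
      abs(object@zS - (object@es - object@nullMean) / object@nullSD) > 1e-12)
    msg <- c(msg, "zS must equal (es - nullMean) / nullSD")
  if (length(msg)) msg else TRUE
})

#' Combined gene-level and edge-level score of one TF
#'
#' Result of \code{\link{scoreTrimmedGenes}}: the trimmed-subnet gene set, the
#' gene-level enrichment score over the expression-wide ranked differential
#' expression profile, its standardized value \code{zTrimmed}, and the combined
#' score \code{zCombined = zS + zTrimmed} used for ranking. DEG annotation is
#' filled by \code{\link{annotateRegulatedDEGs}}.
#'
#' @slot tfId character.
#' @slot trimmedGenes character; genes of the trimmed subnet (objective set).
#' @slot esGenes numeric gene-level enrichment score.
#' @slot leadingGenes character; genes contributing to the ES.
#' @slot zTrimmed,zS,zCombined numeric scores.
#' @slot regulatedDEGs character; trimmed genes flagged as DEGs.
#' @slot tfIsDEG logical; whether the TF itself is differentially expressed.
#' @slot degenerate logical.
#' @exportClass CombinedScore
setClass("CombinedScore",
         representation(tfId = "character", trimmedGenes = "character",
                        esGenes = "numeric", leadingGenes = "character",
                        zTrimmed = "numeric", zS = "numeric",
                        zCombined = "numeric", regulatedDEGs = "character",
                        tfIsDEG = "logical", degenerate = "logical"))

setValidity("CombinedScore", function(object) {
  msg <- character()
  if (!all(object@leadingGenes %in% object@trimmedGenes))
    msg <- c(msg, "leadingGenes must be a subset of trimmedGenes")
  if (!all(object@regulatedDEGs %in% object@trimmedGenes))
    msg <- c(msg, "regulatedDEGs must be a subset of trimmedGenes")
  if (!object@degenerate && !anyNA(c(object@zCombined, object@zS, object@zTrimmed)) &&
      abs(object@zCombined - (object@zS + object@zTrimmed)) > 1e-12)
    msg <- c(msg, "zCombined must equal zS + zTrimmed")
  if (length(msg)) msg else TRUE
})
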