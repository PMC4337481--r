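#' Extract edges
#'
#' @param x an \linkS4class{EdgeList} or \linkS4class{WeightedNetwork}.
#' @param ... unused.
#' @return A \code{data.frame} of edges (all columns the object carries).
#' @export
setGeneric("edges", function(x, ...) standardGeneric("edges"))

#' Edges that passed the permutation filter
#'
#' @param x a \linkS4class{WeightedNetwork} after
#'   \code{\link{permutationFilter}}.
#' @param ... unused.
#' @return A \code{data.frame} of passing edges.
#' @export
setGeneric("passingEdges", function(x, ...) standardGeneric("passingEdges"))

#' Per-TF out-degree
#'
#' @param x a \linkS4class{WeightedNetwork}.
#' @param source count degrees over \code{"passing"} edges (default) or
#'   \code{"all"} edges.
#' @return Named integer vector of out-degrees, sorted decreasing (ties by TF
#'   id).
#' @export
setGeneric("tfDegrees", function(x, source = c("passing", "all"))
  standardGeneric("tfDegrees"))

#' Gene-set members
#'
#' @param x a \linkS4class{GeneSetList}.
#' @return Named list of character member vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Gene-set descriptions
#'
#' @param x a \linkS4class{GeneSetList}.
#' @return Named character vector.
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' Expression matrix of a two-group experiment
#'
#' @param x a \linkS4class{TwoGroupExperiment}.
#' @return Numeric genes x samples matrix (log2 scale).
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Sample group assignment
#'
#' @param x a \linkS4class{TwoGroupExperiment}.
#' @return Factor of group labels, named by sample id. Level order is the
#'   sorted label order; log2 fold changes are level 2 minus level 1.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
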