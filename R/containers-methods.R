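#' Construct an edge list
#'
#' @param tf,target character vectors of equal length, or a two-column
#'   \code{data.frame} passed as \code{tf}.
#' @return An \linkS4class{EdgeList}.
#' @export
EdgeList <- function(tf, target = NULL) {
  if (is.data.frame(tf)) {
    ed <- data.frame(tf = as.character(tf[[1]]), target = as.character(tf[[2]]),
                     stringsAsFactors = FALSE)
  } else {
    ed <- data.frame(tf = as.character(tf), target = as.character(target),
                     stringsAsFactors = FALSE)
  }
  rownames(ed) <- NULL
  new("EdgeList", edges = ed)
}

#' @rdname edges
#' @export
setMethod("edges", "EdgeList", function(x, ...) x@edges)

setMethod("show", "EdgeList", function(object) {
  ed <- object@edges
  cat("EdgeList:", nrow(ed), "TF->target pairs,",
      length(unique(ed$tf)), "TFs,",
      length(unique(ed$target)), "targets\n")
})

#' Construct a gene-set collection
#'
#' @param sets named list of character member vectors (duplicates removed).
#' @param descriptions optional named character vector; defaults to empty
#'   strings.
#' @return A \linkS4class{GeneSetList}.
#' @export
GeneSetList <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  new("GeneSetList", sets = sets,
      descriptions = descriptions[names(sets)])
}

#' @rdname geneSets
#' @export
setMethod("geneSets", "GeneSetList", function(x) x@sets)

#' @rdname setDescriptions
#' @export
setMethod("setDescriptions", "GeneSetList", function(x) x@descriptions)

setMethod("show", "GeneSetList", function(object) {
  cat("GeneSetList:", length(object@sets), "sets; sizes",
      paste(range(lengths(object@sets)), collapse = "-"), "\n")
})

#' @rdname edges
#' @export
setMethod("edges", "WeightedNetwork", function(x, ...) x@edges)

#' @rdname passingEdges
#' @export
setMethod("passingEdges", "WeightedNetwork", function(x, ...) {
  ed <- x@edges
  if (all(is.na(ed$passed_filter)))
    stop("network has not been permutation-filtered yet")
  ed[which(ed$passed_filter), , drop = FALSE]
})

#' @rdname tfDegrees
#' @export
setMethod("tfDegrees", "WeightedNetwork", function(x, source = c("passing", "all")) {
  source <- match.arg(source)
  ed <- if (source == "passing") passingEdges(x) else x@edges
  if (!nrow(ed)) return(setNames(integer(0), character(0)))
  tab <- table(ed$tf)
  deg <- setNames(as.integer(tab), names(tab))
  deg[order(-deg, names(deg))]
})

setMethod("show", "WeightedNetwork", function(object) {
  ed <- object@edges
  cat("WeightedNetwork:", nrow(ed), "weighted TF->target edges\n")
  if (nrow(ed) && !all(is.na(ed$passed_filter))) {
    cat(sprintf("  permutation filter: mode=%s, quantile=%.3g, threshold=%.4g, %d permutations, seed=%d\n",
                object@mode, object@quantile, object@threshold,
                object@nPermutations, object@seed))
    cat(sprintf("  passing edges: %d of %d\n", sum(ed$passed_filter), nrow(ed)))
  } else {
    cat("  not yet permutation-filtered\n")
  }
})

setMethod("show", "SubnetScore", function(object) {
  cat(sprintf("SubnetScore for %s: %d member edges, ES=%.4f, leading edge %d, Z_s=%s%s\n",
              object@tfId, nrow(object@memberEdges), object@es,
              nrow(object@leadingEdge),
              ifelse(is.na(object@zS), "NA", sprintf("%.3f", object@zS)),
              if (object@degenerate) " [degenerate null]" else ""))
})

setMethod("show", "CombinedScore", function(object) {
  cat(sprintf("CombinedScore for %s: %d trimmed genes, ES=%.4f, Z_s=%.3f, Z_trimmed=%.3f, Z_combined=%.3f\n",
              object@tfId, length(object@trimmedGenes), object@esGenes,
              object@zS, object@zTrimmed, object@zCombined))
  if (length(object@regulatedDEGs))
    cat("  regulated DEGs:", paste(object@regulatedDEGs, collapse = ", "), "\n")
})
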