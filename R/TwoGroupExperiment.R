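#' Construct a two-group expression experiment
#'
#' Wraps a genes x samples log2 expression matrix and a sample-to-group
#' assignment into a validated \linkS4class{TwoGroupExperiment}. Group levels
#' are ordered by sorting the two labels; every downstream log2 fold change is
#' mean(level 2) - mean(level 1).
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames); all values finite, assumed log2 scale.
#' @param design named character (or factor) vector mapping sample id to group
#'   label, covering every column of \code{values}; exactly two distinct
#'   labels, each with at least 3 samples.
#' @return A \linkS4class{TwoGroupExperiment}.
#' @examples
#' m <- matrix(rnorm(24, 8), 4, 6,
#'             dimnames = list(paste0("G", 1:4), paste0("S", 1:6)))
#' des <- setNames(rep(c("control", "tumor"), each = 3), colnames(m))
#' TwoGroupExperiment(m, des)
#' @export
TwoGroupExperiment <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  sn <- colnames(values)
  if (is.null(sn)) stop("'values' must have sample ids as column names")
  design <- vapply(design, as.character, character(1))
  missing <- setdiff(sn, names(design))
  if (length(missing))
    stop("sample(s) missing from design: ", paste(missing, collapse = ", "))
  grp <- design[sn]
  lv <- sort(unique(grp))
  if (length(lv) != 2L)
    stop(sprintf("design must define exactly two groups, found %d (%s)",
                 length(lv), paste(lv, collapse = ", ")))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(group = factor(grp, levels = lv),
                                   row.names = sn))
  new("TwoGroupExperiment", se)
}

#' @rdname exprValues
#' @export
setMethod("exprValues", "TwoGroupExperiment", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "TwoGroupExperiment", function(x) {
  g <- SummarizedExperiment::colData(x)$group
  names(g) <- colnames(x)
  g
})

setMethod("show", "TwoGroupExperiment", function(object) {
  g <- sampleGroups(object)
  tab <- table(g)
  cat("TwoGroupExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  cat(sprintf("  groups: %s (n=%d) vs %s (n=%d); log2FC = %s - %s\n",
              levels(g)[1], tab[1], levels(g)[2], tab[2],
              levels(g)[2], levels(g)[1]))
})
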