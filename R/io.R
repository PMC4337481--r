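# Readers and writers for the external formats the pipeline touches:
# TSV expression matrix + design, two-column edge list, GMT gene sets,
# SIF network export with a sibling attribute table.

.num15 <- function(x) sprintf("%.15g", x)

#' Read a TSV expression matrix with its design file
#'
#' The matrix file has a header row of sample ids and gene ids in the first
#' column; values must be numeric (log2 scale is assumed, no renormalization is
#' performed). The design file is a two-column TSV (sample_id, group); a header
#' row starting with \code{sample} is tolerated. Duplicated gene ids are
#' collapsed to the row with the highest variance across samples (a message
#' reports the count).
#'
#' @param path expression matrix TSV.
#' @param designPath two-column design TSV.
#' @return A \linkS4class{TwoGroupExperiment}.
#' @export
readExpressionMatrix <- function(path, designPath) {
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2L) stop("expression matrix must have at least one sample column")
  geneIds <- as.character(tab[[1]])
  sampleIds <- colnames(tab)[-1]
  vals <- tab[-1]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1]
      stop(sprintf("non-numeric value '%s' at row %d (gene '%s'), column '%s'",
                   col[bad], bad, geneIds[bad], sampleIds[j]))
    }
  }
  m <- as.matrix(vals)
  dimnames(m) <- list(geneIds, sampleIds)

  if (anyDuplicated(geneIds)) {
    v <- apply(m, 1L, var)
    keep <- unlist(lapply(split(seq_along(geneIds), geneIds),
                          function(i) i[which.max(v[i])]), use.names = FALSE)
    keep <- sort(keep)  # preserve file order
    message(sprintf("collapsed %d duplicated gene row(s) to the max-variance copy",
                    length(geneIds) - length(keep)))
    m <- m[keep, , drop = FALSE]
  }

  des <- read.delim(designPath, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(des) < 2L) stop("design file must have two columns (sample_id, group)")
  if (tolower(des[1, 1]) %in% c("sample", "sample_id", "sampleid"))
    des <- des[-1, , drop = FALSE]
  design <- setNames(as.character(des[[2]]), as.character(des[[1]]))
  TwoGroupExperiment(m, design)
}

#' Write an expression matrix and design to TSV
#'
#' Inverse of \code{\link{readExpressionMatrix}}; numeric values are written
#' with 15 significant digits so a round trip is stable to 1e-12.
#'
#' @param x a \linkS4class{TwoGroupExperiment}.
#' @param path,designPath output TSV paths.
#' @return Invisibly, \code{c(path, designPath)}.
#' @export
writeExpressionMatrix <- function(x, path, designPath) {
  m <- exprValues(x)
  out <- data.frame(gene_id = rownames(m),
                    apply(m, 2L, .num15),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- sampleGroups(x)
  write.table(data.frame(sample_id = names(g), group = as.character(g)),
              designPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, designPath))
}

#' Read a two-column TF->target edge list
#'
#' Lines are whitespace- or tab-separated (tf, target); lines starting with
#' \code{#} and blank lines are skipped. Self-loops and duplicated pairs are
#' dropped with a message; first-seen order is preserved.
#'
#' @param path edge-list file.
#' @return An \linkS4class{EdgeList}.
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) stop("edge list file is empty: ", path)
  parts <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("malformed edge line %d: '%s' (expected 2 fields)",
                 keep[bad[1]], lines[keep[bad[1]]]))
  tf <- vapply(parts, `[`, character(1), 1L)
  tg <- vapply(parts, `[`, character(1), 2L)
  loop <- tf == tg
  if (any(loop))
    message(sprintf("dropped %d self-loop(s)", sum(loop)))
  tf <- tf[!loop]; tg <- tg[!loop]
  key <- paste(tf, tg, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    message(sprintf("dropped %d duplicated pair(s)", sum(dup)))
  EdgeList(tf[!dup], tg[!dup])
}

#' Write an edge list to a two-column TSV
#'
#' @param x an \linkS4class{EdgeList}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeEdgeList <- function(x, path) {
  write.table(edges(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: set id, description, then one member per tab field. Duplicate
#' members within a set are stored once.
#'
#' @param path GMT file.
#' @return A \linkS4class{GeneSetList}.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list(); desc <- character()
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(f) < 3L || !length(members))
      stop(sprintf("GMT line %d: expected set id, description and >= 1 member", i))
    if (f[1] %in% names(sets))
      stop(sprintf("GMT line %d: duplicated set id '%s'", i, f[1]))
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  GeneSetList(sets, desc)
}

#' Write a gene-set collection to GMT
#'
#' @param x a \linkS4class{GeneSetList}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGMT <- function(x, path) {
  lines <- vapply(names(geneSets(x)), function(id)
    paste(c(id, setDescriptions(x)[[id]], geneSets(x)[[id]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a weighted network as SIF plus an edge-attribute table
#'
#' Writes \code{tf TAB regulates TAB target} lines and a sibling TSV with
#' columns \code{tf, target, r_group1, r_group2, weight, delta} (15 significant
#' digits, so re-reading reproduces values to 1e-12).
#'
#' @param x a \linkS4class{WeightedNetwork} (or an edge \code{data.frame} with
#'   those columns).
#' @param path SIF output path.
#' @param attrPath attribute TSV path; default replaces the extension with
#'   \code{_attributes.tsv}.
#' @param passingOnly write only edges that passed the permutation filter.
#' @return Invisibly, \code{c(path, attrPath)}.
#' @export
writeNetworkSIF <- function(x, path,
                            attrPath = paste0(tools::file_path_sans_ext(path),
                                              "_attributes.tsv"),
                            passingOnly = FALSE) {
  ed <- if (is.data.frame(x)) x else if (passingOnly) passingEdges(x) else edges(x)
  if (!nrow(ed)) {
    warning("writing an empty network")
    writeLines(character(0), path)
    writeLines(paste(c("tf", "target", "r_group1", "r_group2", "weight", "delta"),
                     collapse = "\t"), attrPath)
    return(invisible(c(path, attrPath)))
  }
  writeLines(sprintf("%s\tregulates\t%s", ed$tf, ed$target), path)
  attrs <- data.frame(tf = ed$tf, target = ed$target,
                      r_group1 = .num15(ed$r_group1),
                      r_group2 = .num15(ed$r_group2),
                      weight = .num15(ed$weight),
                      delta = .num15(ed$delta),
                      stringsAsFactors = FALSE)
  write.table(attrs, attrPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, attrPath))
}

#' Read a network edge-attribute table written by \code{writeNetworkSIF}
#'
#' @param path attribute TSV path.
#' @return \code{data.frame} with numeric \code{r_group1}, \code{r_group2},
#'   \code{weight}, \code{delta}.
#' @export
readNetworkAttributes <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c("character", "character", rep("numeric", 4)))
}
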