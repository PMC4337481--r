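# Gene-level scoring of trimmed subnets against the ranked differential
# expression profile, and combined-Z ranking of candidate TFs.

#' Score a trimmed subnet's genes against the DEG profile
#'
#' The background L is the whole expression universe (every gene in
#' \code{degRecords}); genes are ranked by \eqn{-\log_{10} p} descending (the
#' magnitude of differential expression; p is floored at the smallest positive
#' double before the log), ties broken by gene id. The objective set
#' \eqn{S_{trimmed}} holds the distinct target genes of the subnet's
#' leading-edge pairs, plus the TF itself when it is in the universe
#' (\code{includeTf}); genes absent from the universe are dropped with a
#' message. The gene-level ES uses the same running-sum engine with P = 1;
#' genes beyond the ES position are excluded from \code{leadingGenes}.
#' \code{zTrimmed} standardizes the ES against \code{nNull} size-matched random
#' gene sets, and \code{zCombined = zS + zTrimmed}.
#'
#' @param degRecords output of \code{\link{moderatedTTest}} covering the
#'   expression universe.
#' @param subnet a \linkS4class{SubnetScore}.
#' @param nNull null gene sets (default 1000).
#' @param seed integer RNG seed.
#' @param includeTf include the TF in the objective set when expressed
#'   (default TRUE).
#' @param convention ES convention, see \code{\link{runningES}}.
#' @return A \linkS4class{CombinedScore} (DEG annotation empty until
#'   \code{\link{annotateRegulatedDEGs}}).
#' @export
scoreTrimmedGenes <- function(degRecords, subnet, nNull = 1000, seed,
                              includeTf = TRUE,
                              convention = c("positive", "absolute")) {
  convention <- match.arg(convention)
  stopifnot(is(subnet, "SubnetScore"))
  if (missing(seed)) stop("'seed' is required")
  universe <- degRecords$gene_id
  if (anyDuplicated(universe)) stop("duplicated gene ids in 'degRecords'")
  sTrim <- unique(subnet@leadingEdge$target)
  if (includeTf) sTrim <- unique(c(sTrim, subnet@tfId))
  absent <- setdiff(sTrim, universe)
  if (length(absent))
    message(sprintf("%d trimmed-subnet gene(s) absent from the universe: %s",
                    length(absent), paste(head(absent, 5), collapse = ", ")))
  sTrim <- intersect(sTrim, universe)
  if (!length(sTrim)) stop("trimmed subnet is empty after intersection with the universe")

  score <- -log10(pmax(degRecords$p_value, .Machine$double.xmin))
  o <- order(-score, degRecords$gene_id)
  rankedGenes <- degRecords$gene_id[o]
  w <- score[o]
  member <- rankedGenes %in% sTrim
  run <- runningES(w, member, pExponent = 1, convention = convention)
  leadingGenes <- rankedGenes[run$leadingEdge]

  set.seed(as.integer(seed))
  M <- length(w); MH <- sum(member)
  nullES <- numeric(nNull)
  for (b in seq_len(nNull)) {
    mb <- logical(M)
    mb[sample.int(M, MH)] <- TRUE
    if (sum(w[mb]) == 0) { nullES[b] <- NA_real_; next }
    nullES[b] <- .runningSum(w, mb, convention)$es
  }
  nullES <- nullES[!is.na(nullES)]
  nm <- mean(nullES); nsd <- sd(nullES)
  degenerate <- subnet@degenerate || !is.finite(nsd) || nsd == 0
  zT <- if (!is.finite(nsd) || nsd == 0) NA_real_ else (run$es - nm) / nsd
  zC <- if (degenerate || is.na(zT) || is.na(subnet@zS)) NA_real_
        else subnet@zS + zT
  new("CombinedScore", tfId = subnet@tfId, trimmedGenes = sort(sTrim),
      esGenes = run$es, leadingGenes = leadingGenes,
      zTrimmed = if (is.na(zT)) NA_real_ else zT,
      zS = subnet@zS, zCombined = zC,
      regulatedDEGs = character(0), tfIsDEG = NA, degenerate = degenerate)
}

#' Annotate a combined score with the DEGs it regulates
#'
#' Fills \code{regulatedDEGs} with the trimmed-subnet genes flagged
#' \code{is_deg}, and \code{tfIsDEG} with whether the TF itself is a DEG.
#'
#' @param result a \linkS4class{CombinedScore}.
#' @param degRecords output of \code{\link{moderatedTTest}} (with DEG flags).
#' @return The updated \linkS4class{CombinedScore}.
#' @export
annotateRegulatedDEGs <- function(result, degRecords) {
  stopifnot(is(result, "CombinedScore"))
  degIds <- degRecords$gene_id[degRecords$is_deg]
  initialize(result,
             regulatedDEGs = sort(intersect(result@trimmedGenes, degIds)),
             tfIsDEG = result@tfId %in% degIds)
}

#' Rank candidate TFs by combined Z-score
#'
#' Sorts scored TFs by \code{zCombined} descending (ties broken by TF id,
#' \code{NA} scores last), assigns ranks 1..n and returns the top \code{topK}
#' rows. With \code{standardize = TRUE} the edge-level and gene-level Z values
#' are first re-standardized across the scored TFs before summing.
#'
#' @param results list of \linkS4class{CombinedScore} objects.
#' @param topK rows to return (default 5; capped at the number of results).
#' @param standardize re-standardize the two Z components across TFs.
#' @return \code{data.frame} with columns \code{tf_id}, \code{n_trimmed},
#'   \code{es_genes}, \code{z_s}, \code{z_trimmed}, \code{z_combined},
#'   \code{rank}, \code{regulated_degs} (comma-joined), \code{tf_is_deg}.
#' @export
rankCandidates <- function(results, topK = 5, standardize = FALSE) {
  if (topK < 1) stop("'topK' must be >= 1")
  if (!length(results)) stop("no results to rank")
  stopifnot(all(vapply(results, is, logical(1), "CombinedScore")))
  zs <- vapply(results, function(r) r@zS, numeric(1))
  zt <- vapply(results, function(r) r@zTrimmed, numeric(1))
  if (standardize) {
    std <- function(z) if (sd(z, na.rm = TRUE) > 0)
      (z - mean(z, na.rm = TRUE)) / sd(z, na.rm = TRUE) else z * 0
    zs <- std(zs); zt <- std(zt)
  }
  zc <- zs + zt
  df <- data.frame(
    tf_id = vapply(results, function(r) r@tfId, character(1)),
    n_trimmed = vapply(results, function(r) length(r@trimmedGenes), integer(1)),
    es_genes = vapply(results, function(r) r@esGenes, numeric(1)),
    z_s = zs, z_trimmed = zt, z_combined = zc,
    regulated_degs = vapply(results, function(r)
      paste(r@regulatedDEGs, collapse = ","), character(1)),
    tf_is_deg = vapply(results, function(r) isTRUE(r@tfIsDEG), logical(1)),
    stringsAsFactors = FALSE)
  o <- order(-df$z_combined, df$tf_id, na.last = TRUE)
  df <- df[o, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df <- df[, c("tf_id", "n_trimmed", "es_genes", "z_s", "z_trimmed",
               "z_combined", "rank", "regulated_degs", "tf_is_deg")]
  head(df, min(topK, nrow(df)))
}
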