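# Hypergeometric over-representation analysis against GMT gene sets.

#' Hypergeometric over-representation test
#'
#' For each gene set (intersected with the universe first) tests
#' \eqn{P(X \ge \mathrm{overlap})} under the hypergeometric distribution with
#' population \code{universe}, successes = set size in universe, draws = gene
#' list size. One-sided over-representation only; BH adjustment across the
#' tested sets; results sorted by p ascending (ties by set id). Sets with no
#' member in the universe are skipped with a message.
#'
#' @param degIds character gene list (e.g. DEG ids); must be a subset of
#'   \code{universeIds}.
#' @param universeIds character background universe (typically all genes on
#'   the expression matrix after collapse).
#' @param sets a \linkS4class{GeneSetList}.
#' @return \code{data.frame} with columns \code{set_id}, \code{overlap},
#'   \code{set_size}, \code{list_size}, \code{universe_size}, \code{p_value},
#'   \code{p_adjusted}, \code{overlapping_genes} (comma-joined).
#' @export
hypergeomORA <- function(degIds, universeIds, sets) {
  stopifnot(is(sets, "GeneSetList"))
  degIds <- unique(as.character(degIds))
  universeIds <- unique(as.character(universeIds))
  bad <- setdiff(degIds, universeIds)
  if (length(bad))
    stop("gene list members outside the universe: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10) else "")
  N <- length(universeIds)
  nList <- length(degIds)
  rows <- lapply(names(geneSets(sets)), function(id) {
    members <- intersect(geneSets(sets)[[id]], universeIds)
    if (!length(members)) return(NULL)
    ov <- intersect(members, degIds)
    K <- length(members); k <- length(ov)
    p <- phyper(k - 1, K, N - K, nList, lower.tail = FALSE)
    data.frame(set_id = id, overlap = k, set_size = K, list_size = nList,
               universe_size = N, p_value = p,
               overlapping_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0L)
    message(sprintf("skipped %d set(s) with no member in the universe", skipped))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no gene set overlaps the universe")
  res <- do.call(rbind, rows)
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res <- res[, c("set_id", "overlap", "set_size", "list_size", "universe_size",
                 "p_value", "p_adjusted", "overlapping_genes")]
  res[order(res$p_value, res$set_id), , drop = FALSE]
}
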