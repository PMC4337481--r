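# Hub-TF subnetwork scoring: weighted running-sum enrichment score over the
# ranked edge background, leading-edge trimming, and standardization against
# a size-matched random-subset null.

# Core running-sum scan shared by runningES() and the null loops.
# wp: weights already raised to the exponent; membership: logical.
# Returns list(es, argmax, dev).
.runningSum <- function(wp, membership, convention = "positive") {
  N <- length(wp)
  NH <- sum(membership)
  NR <- sum(wp[membership])
  hit <- ifelse(membership, wp / NR, 0)
  miss <- ifelse(membership, 0, 1 / (N - NH))
  dev <- cumsum(hit) - cumsum(miss)
  i <- if (convention == "positive") which.max(dev) else which.max(abs(dev))
  list(es = dev[i], argmax = i, dev = dev)
}

#' Weighted running-sum enrichment score over a ranked background
#'
#' Walks the ranked background: members add \eqn{|r_j|^P / N_R}
#' (\eqn{N_R = \sum_{j \in S} |r_j|^P}) to the hit curve, non-members add
#' \eqn{1/(N - N_H)} to the miss curve. The enrichment score is the maximum
#' deviation between the two curves; under the default \code{"positive"}
#' convention the maximum of (hit - miss), under \code{"absolute"} the signed
#' deviation of largest magnitude. The leading edge is the set of member
#' positions at ranks up to the ES position (for a negative absolute-convention
#' ES, members beyond it) — members outside it do not contribute to the ES.
#'
#' @param rankedWeights non-negative weights (e.g. |r_j|), sorted descending —
#'   the caller ranks; the order is validated.
#' @param membership logical vector marking the objective set S, same length;
#'   needs \eqn{1 \le N_H < N}.
#' @param pExponent weight exponent P (default 1).
#' @param convention \code{"positive"} (default) or \code{"absolute"}.
#' @return list with \code{es}, \code{leadingEdge} (member indices), and
#'   \code{argmax} (rank position where the ES is attained).
#' @examples
#' runningES(c(5, 4, 3, 2, 1), c(TRUE, FALSE, TRUE, FALSE, FALSE))
#' @export
runningES <- function(rankedWeights, membership, pExponent = 1,
                      convention = c("positive", "absolute")) {
  convention <- match.arg(convention)
  N <- length(rankedWeights)
  if (length(membership) != N) stop("'membership' length must match weights")
  if (N < 2L) stop("need at least 2 ranked elements")
  if (any(!is.finite(rankedWeights)) || any(rankedWeights < 0))
    stop("weights must be finite and non-negative")
  if (any(diff(rankedWeights) > 1e-12))
    stop("'rankedWeights' must be sorted in descending order")
  membership <- as.logical(membership)
  NH <- sum(membership)
  if (NH == 0L) stop("the objective set is empty")
  if (NH == N) stop("the objective set cannot cover the whole background")
  wp <- rankedWeights^pExponent
  if (sum(wp[membership]) == 0) stop("all member weights are zero")
  rs <- .runningSum(wp, membership, convention)
  memberIdx <- which(membership)
  le <- if (rs$es >= 0) memberIdx[memberIdx <= rs$argmax]
        else memberIdx[memberIdx > rs$argmax]
  list(es = rs$es, leadingEdge = le, argmax = rs$argmax)
}

#' Select hub TFs by out-degree
#'
#' TFs whose out-degree exceeds \code{minDegree} (strict), sorted by degree
#' descending with ties broken by TF id. Degrees are counted over passing
#' edges by default; \code{degreeSource = "all"} counts over the unfiltered
#' network.
#'
#' @param network a \linkS4class{WeightedNetwork}.
#' @param minDegree strict degree cut-off (default 15).
#' @param degreeSource \code{"passing"} (default) or \code{"all"}.
#' @return Character vector of hub TF ids (degrees as the \code{"degree"}
#'   attribute); empty with a message when no TF qualifies.
#' @export
selectHubTFs <- function(network, minDegree = 15,
                         degreeSource = c("passing", "all")) {
  degreeSource <- match.arg(degreeSource)
  deg <- tfDegrees(network, source = degreeSource)
  hubs <- deg[deg > minDegree]
  if (!length(hubs)) message("no TF exceeds the degree cut-off")
  structure(names(hubs), degree = unname(hubs))
}

#' Score one TF's subnetwork against the ranked edge background
#'
#' The background E is all passing edges ranked by delta (the differential
#' coefficient) descending, ties broken by \code{tf->target} id; the objective
#' set S is the TF's passing edges; \eqn{r_j} is the delta of edge j with
#' exponent P = 1. The ES and leading edge come from \code{\link{runningES}};
#' the null is \code{nNull} uniform size-matched subsets of E drawn without
#' replacement, and \eqn{Z_s = (ES - \overline{ES}) / S'}. A null with zero
#' spread flags the score degenerate (\code{zS = NA}) rather than dividing by
#' zero.
#'
#' @param network a permutation-filtered \linkS4class{WeightedNetwork} with at
#'   least 2 passing edges.
#' @param tfId the hub TF to score; must have at least one passing edge.
#' @param nNull null subsets (default 1000).
#' @param seed integer RNG seed.
#' @param convention ES convention, see \code{\link{runningES}}.
#' @return A \linkS4class{SubnetScore}.
#' @export
scoreSubnet <- function(network, tfId, nNull = 1000, seed,
                        convention = c("positive", "absolute")) {
  convention <- match.arg(convention)
  if (missing(seed)) stop("'seed' is required")
  ed <- passingEdges(network)
  if (nrow(ed) < 2L) stop("network needs at least 2 passing edges")
  edgeId <- paste(ed$tf, ed$target, sep = "->")
  o <- order(-ed$delta, edgeId)
  ed <- ed[o, , drop = FALSE]
  member <- ed$tf == tfId
  NH <- sum(member)
  if (NH == 0L) stop(sprintf("TF '%s' has no passing edges", tfId))
  if (NH == nrow(ed))
    stop(sprintf("TF '%s' owns every passing edge; no background remains", tfId))
  w <- ed$delta
  run <- runningES(w, member, pExponent = 1, convention = convention)

  set.seed(as.integer(seed))
  N <- nrow(ed)
  nullES <- numeric(nNull)
  for (b in seq_len(nNull)) {
    mb <- logical(N)
    mb[sample.int(N, NH)] <- TRUE
    if (sum(w[mb]) == 0) { nullES[b] <- NA_real_; next }
    nullES[b] <- .runningSum(w, mb, convention)$es
  }
  if (anyNA(nullES)) {
    message(sprintf("dropped %d degenerate null draw(s) with zero member weight",
                    sum(is.na(nullES))))
    nullES <- nullES[!is.na(nullES)]
  }
  nm <- mean(nullES); nsd <- sd(nullES)
  degenerate <- !is.finite(nsd) || nsd == 0
  zS <- if (degenerate) NA_real_ else (run$es - nm) / nsd
  if (degenerate) message(sprintf("TF '%s': degenerate null (zero spread)", tfId))
  memberDf <- ed[member, c("tf", "target", "delta"), drop = FALSE]
  rownames(memberDf) <- NULL
  leadDf <- ed[run$leadingEdge, c("tf", "target", "delta"), drop = FALSE]
  rownames(leadDf) <- NULL
  new("SubnetScore", tfId = tfId, memberEdges = memberDf, es = run$es,
      leadingEdge = leadDf, nullES = nullES, nullMean = nm, nullSD = nsd,
      zS = zS, degenerate = degenerate)
}
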