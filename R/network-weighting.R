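# Edge weighting by within-group Spearman correlation: per-edge weight
# |r1 + r2|/2, differential coefficient |r1 - r2|/2, and a permutation null
# built by reshuffling the sample->group assignment.

#' Spearman rank correlation
#'
#' Pearson product-moment correlation computed on average ranks (ties share the
#' mean rank). A constant vector has undefined ranks; the coefficient is
#' defined as 0 with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3, all finite.
#' @return Correlation in [-1, 1].
#' @examples
#' spearmanRho(c(1, 2, 3, 4), c(2, 4, 6, 8))  # 1
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    warning("constant vector: Spearman coefficient defined as 0")
    return(0)
  }
  cor(rx, ry)
}

#' Edge weight and differential coefficient from two correlations
#'
#' \code{weight = |r1 + r2| / 2}, \code{delta = |r1 - r2| / 2}. The weight
#' measures consistent co-expression; the delta (the "weighted coefficient")
#' measures differential co-regulation between the groups. Their sum is
#' bounded by 1.
#'
#' @param r1,r2 within-group Spearman coefficients in [-1, 1] (vectorized).
#' @return \code{data.frame} with columns \code{weight} and \code{delta}.
#' @export
edgeWeightDelta <- function(r1, r2) {
  if (any(abs(r1) > 1) || any(abs(r2) > 1))
    stop("correlations must lie in [-1, 1]")
  data.frame(weight = 0.5 * abs(r1 + r2), delta = 0.5 * abs(r1 - r2))
}

# Row ranks of a matrix (average ranks for ties).
.rankRows <- function(M) {
  if (ncol(M) == 0L) return(M)
  t(apply(M, 1L, rank))
}

# Spearman coefficients for many edges at once within one sample set.
# M: expression submatrix (unique edge genes x all samples); cols: sample
# indices of the group; ti/gi: row indices of tf/target per edge.
# Constant rows yield 0.
.edgeSpearman <- function(M, cols, ti, gi) {
  R <- .rankRows(M[, cols, drop = FALSE])
  C <- R - rowMeans(R)
  ss <- rowSums(C * C)
  r <- rowSums(C[ti, , drop = FALSE] * C[gi, , drop = FALSE]) /
    sqrt(ss[ti] * ss[gi])
  r[!is.finite(r)] <- 0
  r
}

#' Weight TF->target edges by within-group Spearman correlations
#'
#' Edges whose TF or target is absent from the expression matrix are dropped
#' with a message (none left is an error). For each retained edge the Spearman
#' coefficient is computed within each group's samples; weight and delta follow
#' from \code{\link{edgeWeightDelta}}. Constant within-group expression yields
#' a coefficient of 0 (counted in a message).
#'
#' @param x a \linkS4class{TwoGroupExperiment}.
#' @param edgeList an \linkS4class{EdgeList}.
#' @return An unfiltered \linkS4class{WeightedNetwork}
#'   (\code{passed_filter = NA}).
#' @export
weightEdges <- function(x, edgeList) {
  stopifnot(is(x, "TwoGroupExperiment"), is(edgeList, "EdgeList"))
  ed <- edges(edgeList)
  M <- exprValues(x)
  present <- ed$tf %in% rownames(M) & ed$target %in% rownames(M)
  if (any(!present))
    message(sprintf("dropped %d edge(s) absent from the expression matrix",
                    sum(!present)))
  ed <- ed[present, , drop = FALSE]
  if (!nrow(ed)) stop("no edge has both TF and target in the expression matrix")
  g <- sampleGroups(x)
  genes <- unique(c(ed$tf, ed$target))
  sub <- M[genes, , drop = FALSE]
  ti <- match(ed$tf, genes); gi <- match(ed$target, genes)
  r1 <- .edgeSpearman(sub, which(g == levels(g)[1]), ti, gi)
  r2 <- .edgeSpearman(sub, which(g == levels(g)[2]), ti, gi)
  wd <- edgeWeightDelta(r1, r2)
  out <- data.frame(tf = ed$tf, target = ed$target,
                    r_group1 = r1, r_group2 = r2,
                    weight = wd$weight, delta = wd$delta,
                    passed_filter = NA, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  new("WeightedNetwork", edges = out, threshold = NA_real_,
      nPermutations = 0L, quantile = NA_real_, mode = NA_character_,
      seed = NA_integer_)
}

#' Filter edges against a permutation null of the differential coefficient
#'
#' Builds a pooled null by reshuffling the sample->group assignment (group
#' sizes preserved) \code{nPermutations} times and recomputing every edge's
#' delta; the threshold is the \code{quantile} quantile of the pooled null
#' deltas. Under the default \code{mode = "keep_above"} an edge passes iff its
#' observed delta exceeds the threshold (retaining differentially co-regulated
#' edges); \code{"drop_above"} inverts the rule to match a literal
#' high-delta-excluded reading.
#'
#' @param x the \linkS4class{TwoGroupExperiment} the network was weighted on.
#' @param network a \linkS4class{WeightedNetwork} from
#'   \code{\link{weightEdges}}.
#' @param nPermutations number of label permutations (>= 100; default 1000).
#' @param quantile null quantile in (0, 1); default 0.90.
#' @param mode \code{"keep_above"} (default) or \code{"drop_above"}.
#' @param seed integer RNG seed; fully determines the result.
#' @return The network with \code{passed_filter} set and filter metadata
#'   recorded.
#' @export
permutationFilter <- function(x, network, nPermutations = 1000, quantile = 0.90,
                              mode = c("keep_above", "drop_above"), seed) {
  stopifnot(is(x, "TwoGroupExperiment"), is(network, "WeightedNetwork"))
  mode <- match.arg(mode)
  if (missing(seed)) stop("'seed' is required")
  if (nPermutations < 100) stop("'nPermutations' must be >= 100")
  if (quantile <= 0 || quantile >= 1) stop("'quantile' must lie in (0, 1)")
  ed <- network@edges
  M <- exprValues(x)
  g <- sampleGroups(x)
  n <- length(g)
  genes <- unique(c(ed$tf, ed$target))
  sub <- M[genes, , drop = FALSE]
  ti <- match(ed$tf, genes); gi <- match(ed$target, genes)
  i1 <- which(g == levels(g)[1])

  set.seed(as.integer(seed))
  nullDeltas <- vector("list", nPermutations)
  for (p in seq_len(nPermutations)) {
    perm <- sample.int(n)
    c1 <- perm[seq_along(i1)]
    c2 <- perm[-seq_along(i1)]
    r1 <- .edgeSpearman(sub, c1, ti, gi)
    r2 <- .edgeSpearman(sub, c2, ti, gi)
    nullDeltas[[p]] <- 0.5 * abs(r1 - r2)
  }
  nullDeltas <- unlist(nullDeltas, use.names = FALSE)
  thr <- stats::quantile(nullDeltas, probs = quantile, names = FALSE, type = 7)
  passed <- if (mode == "keep_above") ed$delta > thr else ed$delta <= thr
  ed$passed_filter <- passed
  message(sprintf("permutation filter (%s, q=%.2f): threshold %.4f; %d of %d edge(s) pass",
                  mode, quantile, thr, sum(passed), nrow(ed)))
  initialize(network, edges = ed, threshold = thr,
             nPermutations = as.integer(nPermutations),
             quantile = quantile, mode = mode, seed = as.integer(seed))
}
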