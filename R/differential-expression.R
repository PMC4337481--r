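# Two-group differential expression with empirical-Bayes variance moderation.

#' Moderated two-sample t-test
#'
#' Per gene: \code{log2fc} is mean(group 2) - mean(group 1) (group levels are
#' the sorted labels). The pooled residual variance \eqn{s^2} (df
#' \eqn{d = n_1 + n_2 - 2}) is shrunk toward the prior
#' \eqn{s_0^2 = \mathrm{mean}(s^2)} as
#' \eqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)} with \code{priorDf}
#' \eqn{= d_0}; the t statistic \eqn{t = \mathrm{log2fc} /
#' \sqrt{\tilde{s}^2 (1/n_1 + 1/n_2)}} is referred to a t distribution on
#' \eqn{d + d_0} degrees of freedom (two-sided). \code{priorDf = 0} recovers
#' the classical pooled t-test exactly. P-values are BH-adjusted; rows are
#' sorted by p ascending (ties by gene id).
#'
#' Zero-variance genes with \code{priorDf = 0} are guarded with an
#' infinitesimal variance (so a zero fold change still yields p = 1, anything
#' else an extreme t); the guard count is reported via \code{message}.
#'
#' @param x a \linkS4class{TwoGroupExperiment}.
#' @param priorDf prior degrees of freedom \eqn{d_0 \ge 0} (may be
#'   \code{Inf}); default 4.
#' @param pCut,fcCut thresholds for the DEG flag: \code{is_deg} is
#'   \code{p_value < pCut & |log2fc| > fcCut} (both strict).
#' @return \code{data.frame} with columns \code{gene_id}, \code{log2fc},
#'   \code{t_stat}, \code{p_value}, \code{p_adjusted}, \code{is_deg},
#'   \code{direction}.
#' @examples
#' sim <- simulateDataset(simulationConfig(nGroup1 = 10, nGroup2 = 10,
#'   nGenes = 50, nTfs = 0, nPlantedDegs = 5, seed = 1))
#' head(moderatedTTest(sim$experiment))
#' @export
moderatedTTest <- function(x, priorDf = 4, pCut = 0.05, fcCut = 1.5) {
  stopifnot(is(x, "TwoGroupExperiment"))
  if (priorDf < 0) stop("'priorDf' must be non-negative")
  M <- exprValues(x)
  g <- sampleGroups(x)
  i1 <- which(g == levels(g)[1]); i2 <- which(g == levels(g)[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  m1 <- rowMeans(M[, i1, drop = FALSE]); m2 <- rowMeans(M[, i2, drop = FALSE])
  fc <- m2 - m1
  ss1 <- rowSums((M[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((M[, i2, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d
  s0 <- mean(s2)
  s2mod <- if (is.infinite(priorDf)) rep(s0, length(s2))
           else (priorDf * s0 + d * s2) / (priorDf + d)
  nzero <- sum(s2mod == 0)
  if (nzero > 0L) {
    message(sprintf("%d zero-variance gene(s): applying infinitesimal-variance guard",
                    nzero))
    s2mod[s2mod == 0] <- .Machine$double.eps
  }
  tstat <- fc / sqrt(s2mod * (1 / n1 + 1 / n2))
  dfTot <- if (is.infinite(priorDf)) Inf else d + priorDf
  p <- 2 * pt(abs(tstat), df = dfTot, lower.tail = FALSE)
  padj <- p.adjust(p, method = "BH")
  res <- data.frame(gene_id = rownames(M), log2fc = fc, t_stat = tstat,
                    p_value = p, p_adjusted = padj,
                    is_deg = p < pCut & abs(fc) > fcCut,
                    direction = ifelse(fc > 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res[order(res$p_value, res$gene_id), , drop = FALSE]
}

#' Partition DEG records into up- and downregulated lists
#'
#' Splits records with \code{is_deg = TRUE} by the sign of \code{log2fc}; both
#' lists are sorted by \code{|log2fc|} descending. Thresholds can be
#' re-applied by passing \code{pCut}/\code{fcCut}.
#'
#' @param records output of \code{\link{moderatedTTest}}.
#' @param pCut,fcCut optional thresholds to recompute the DEG flag (strict
#'   inequalities).
#' @return list with \code{up}, \code{down} (data.frames) and \code{records}
#'   (the full table with the flags used).
#' @export
callDEGs <- function(records, pCut = NULL, fcCut = NULL) {
  if (!is.null(pCut) || !is.null(fcCut)) {
    if (is.null(pCut) || is.null(fcCut))
      stop("provide both 'pCut' and 'fcCut' or neither")
    records$is_deg <- records$p_value < pCut & abs(records$log2fc) > fcCut
    records$direction <- ifelse(records$log2fc > 0, "up", "down")
  }
  deg <- records[records$is_deg, , drop = FALSE]
  ord <- function(d) d[order(-abs(d$log2fc), d$gene_id), , drop = FALSE]
  list(up = ord(deg[deg$log2fc > 0, , drop = FALSE]),
       down = ord(deg[deg$log2fc < 0, , drop = FALSE]),
       records = records)
}
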