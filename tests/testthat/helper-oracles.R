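# Independent oracles, coded from first principles and kept free of any
# package internals.

# Spearman: average ranks by hand, then the textbook Pearson formula.
oracleSpearman <- function(x, y) {
  avgRank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2
    r
  }
  rx <- avgRank(x); ry <- avgRank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Classical two-sample pooled-variance t-test, two-sided.
oraclePooledT <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(abs(t), df = n1 + n2 - 2, lower.tail = FALSE))
}

# Running-sum enrichment score by explicit position-by-position scan.
oracleES <- function(w, member, p = 1, convention = "positive") {
  N <- length(w); NH <- sum(member)
  NR <- sum(w[member]^p)
  phit <- 0; pmiss <- 0
  dev <- numeric(N)
  for (i in seq_len(N)) {
    if (member[i]) phit <- phit + w[i]^p / NR
    else pmiss <- pmiss + 1 / (N - NH)
    dev[i] <- phit - pmiss
  }
  i <- if (convention == "positive") which.max(dev) else which.max(abs(dev))
  list(es = dev[i], argmax = i)
}

# Hypergeometric upper tail from the choose() sum (no phyper).
oracleHyperChoose <- function(N, K, n, ov) {
  ks <- max(ov, 0):min(K, n)
  ks <- ks[ks >= n - (N - K)]
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Hypergeometric upper tail by exhaustive enumeration of every possible draw.
oracleHyperEnumerate <- function(N, K, n, ov) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # successes are items 1..K
  mean(hits >= ov)
}

# BH step-up adjustment from the definition.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
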