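# Small fixtures built in code at test time.

# A deterministic toy experiment: nGenes x (n1 + n2), seeded noise around 8.
makeToyExperiment <- function(nGenes = 6, n1 = 3, n2 = 3, seed = 1,
                              labels = c("control", "tumor")) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * (n1 + n2), mean = 8, sd = 0.5), nrow = nGenes,
              dimnames = list(sprintf("G%d", seq_len(nGenes)),
                              sprintf("S%d", seq_len(n1 + n2))))
  design <- setNames(rep(labels, c(n1, n2)), colnames(m))
  TwoGroupExperiment(m, design)
}

writeLinesTmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Expression TSV + design TSV files for reader tests.
writeMatrixFixture <- function(mat, design) {
  mpath <- tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  dpath <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = names(design), group = unname(design)),
              dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mpath, design = dpath)
}

# Weighted network built directly from chosen correlations (bypasses data).
makeNetworkFromCors <- function(tf, target, r1, r2, passed = TRUE) {
  ed <- data.frame(tf = tf, target = target, r_group1 = r1, r_group2 = r2,
                   weight = 0.5 * abs(r1 + r2), delta = 0.5 * abs(r1 - r2),
                   passed_filter = rep(passed, length.out = length(tf)),
                   stringsAsFactors = FALSE)
  new("WeightedNetwork", edges = ed, threshold = 0, nPermutations = 100L,
      quantile = 0.9, mode = "keep_above", seed = 1L)
}
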