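# End-to-end orchestration: simulate/read inputs -> DEGs -> (optional) ORA ->
# edge weighting + permutation filter -> hub subnet scoring -> gene scoring ->
# combined-Z ranking, with every artifact written as TSV/SIF/JSON and a run
# manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the field's standard defaults:
#' DEG cut-offs p < 0.05 and |log2FC| > 1.5 (strict), permutation filter at the
#' null 0.90 quantile, hub degree > 15, top 5 candidate TFs. Inputs come either
#' from files (\code{matrixPath}/\code{designPath}/\code{edgesPath}) or from a
#' \code{\link{simulationConfig}} via \code{simulate}.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @param matrixPath,designPath,edgesPath,gmtPath input files (ignored when
#'   \code{simulate} is given; \code{gmtPath}/ORA is optional).
#' @param simulate optional \code{\link{simulationConfig}} replacing file
#'   inputs.
#' @param pCut,fcCut DEG thresholds.
#' @param priorDf moderation prior degrees of freedom.
#' @param nPermutations,permQuantile,permMode permutation-filter settings.
#' @param minDegree,degreeSource hub selection settings.
#' @param nNull null draws for subnet and gene scoring.
#' @param topK candidate TFs to report.
#' @param includeTf include the TF in its trimmed gene set.
#' @return A validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(outDir, seed,
                           matrixPath = NULL, designPath = NULL,
                           edgesPath = NULL, gmtPath = NULL, simulate = NULL,
                           pCut = 0.05, fcCut = 1.5, priorDf = 4,
                           nPermutations = 1000, permQuantile = 0.90,
                           permMode = c("keep_above", "drop_above"),
                           minDegree = 15,
                           degreeSource = c("passing", "all"),
                           nNull = 1000, topK = 5, includeTf = TRUE) {
  if (missing(outDir) || missing(seed)) stop("'outDir' and 'seed' are required")
  permMode <- match.arg(permMode)
  degreeSource <- match.arg(degreeSource)
  if (pCut <= 0 || fcCut <= 0) stop("thresholds must be positive")
  if (permQuantile <= 0 || permQuantile >= 1)
    stop("'permQuantile' must lie in (0, 1)")
  if (nPermutations < 100) stop("'nPermutations' must be >= 100")
  if (topK < 1) stop("'topK' must be >= 1")
  if (is.null(simulate)) {
    for (p in c(matrixPath, designPath, edgesPath, gmtPath))
      if (!file.exists(p)) stop("input file not found: ", p)
    if (is.null(matrixPath) || is.null(designPath) || is.null(edgesPath))
      stop("provide matrix/design/edges paths or a 'simulate' config")
  } else stopifnot(inherits(simulate, "SimulationConfig"))
  structure(list(outDir = outDir, seed = as.integer(seed),
                 matrixPath = matrixPath, designPath = designPath,
                 edgesPath = edgesPath, gmtPath = gmtPath, simulate = simulate,
                 pCut = pCut, fcCut = fcCut, priorDf = priorDf,
                 nPermutations = as.integer(nPermutations),
                 permQuantile = permQuantile, permMode = permMode,
                 minDegree = minDegree, degreeSource = degreeSource,
                 nNull = as.integer(nNull), topK = as.integer(topK),
                 includeTf = isTRUE(includeTf)),
            class = "PipelineConfig")
}

.writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], .num15)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Derived per-stage seeds, kept well below 2^31.
.stageSeed <- function(seed, offset) (as.integer(seed) %% 1000000L) * 1000L + offset

#' Run the whole pipeline
#'
#' Executes every stage in order, writes each stage's artifact under
#' \code{config$outDir} (\code{degs.tsv}, optional \code{enrichment.tsv},
#' \code{network.sif} + \code{network_attributes.tsv} +
#' \code{network_meta.json}, \code{subnet_scores.tsv}, \code{tf_ranking.tsv})
#' plus \code{manifest.json}, and returns the manifest invisibly alongside the
#' in-memory results. Identical config and inputs give byte-identical result
#' tables.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return Invisibly, a list with \code{manifest} and the per-stage results
#'   (\code{experiment}, \code{degs}, \code{enrichment}, \code{network},
#'   \code{hubs}, \code{subnetScores}, \code{combined}, \code{ranking},
#'   \code{truth} when simulated).
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stages <- list()
  tick <- function(name, start) round(as.numeric(Sys.time() - start, units = "secs"), 3)

  withStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s (partial outputs in %s)",
                   name, conditionMessage(e), config$outDir), call. = FALSE))
  }

  # inputs
  s <- Sys.time()
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- withStage("simulate", simulateDataset(config$simulate))
    x <- sim$experiment; el <- sim$edges; truth <- sim$truth
    writeExpressionMatrix(x, file.path(config$outDir, "expression.tsv"),
                          file.path(config$outDir, "design.tsv"))
    writeEdgeList(el, file.path(config$outDir, "edges.tsv"))
    jsonlite::write_json(truth[c("true_deg_ids", "true_diffcoreg_tf_ids")],
                         file.path(config$outDir, "truth.json"))
  } else {
    x <- withStage("read", readExpressionMatrix(config$matrixPath, config$designPath))
    el <- withStage("read", readEdgeList(config$edgesPath))
  }
  stages$input <- list(genes = nrow(x), samples = ncol(x),
                       edges = nrow(edges(el)), seconds = tick("input", s))

  # differential expression
  s <- Sys.time()
  degs <- withStage("deg", moderatedTTest(x, priorDf = config$priorDf,
                                          pCut = config$pCut, fcCut = config$fcCut))
  parts <- callDEGs(degs)
  .writeTsv(degs, file.path(config$outDir, "degs.tsv"))
  stages$deg <- list(n_deg = sum(degs$is_deg), n_up = nrow(parts$up),
                     n_down = nrow(parts$down), seconds = tick("deg", s))

  # optional over-representation analysis
  enr <- NULL
  if (!is.null(config$gmtPath)) {
    s <- Sys.time()
    sets <- withStage("enrich", readGMT(config$gmtPath))
    enr <- withStage("enrich",
                     hypergeomORA(degs$gene_id[degs$is_deg], degs$gene_id, sets))
    .writeTsv(enr, file.path(config$outDir, "enrichment.tsv"))
    stages$enrich <- list(n_sets = nrow(enr), seconds = tick("enrich", s))
  }

  # weighting + permutation filter
  s <- Sys.time()
  net <- withStage("weight-network", weightEdges(x, el))
  net <- withStage("weight-network",
                   permutationFilter(x, net, nPermutations = config$nPermutations,
                                     quantile = config$permQuantile,
                                     mode = config$permMode,
                                     seed = .stageSeed(config$seed, 1L)))
  writeNetworkSIF(net, file.path(config$outDir, "network.sif"))
  jsonlite::write_json(
    list(threshold = net@threshold, n_permutations = net@nPermutations,
         quantile = net@quantile, mode = net@mode, seed = net@seed,
         n_edges = nrow(edges(net)), n_passing = sum(edges(net)$passed_filter)),
    file.path(config$outDir, "network_meta.json"), auto_unbox = TRUE, digits = NA)
  stages$weight <- list(n_edges = nrow(edges(net)),
                        n_passing = sum(edges(net)$passed_filter),
                        n_excluded = sum(!edges(net)$passed_filter),
                        threshold = net@threshold, seconds = tick("weight", s))

  # hub subnet scoring
  s <- Sys.time()
  hubs <- withStage("score-subnets",
                    selectHubTFs(net, minDegree = config$minDegree,
                                 degreeSource = config$degreeSource))
  passTf <- unique(passingEdges(net)$tf)
  scorable <- hubs[hubs %in% passTf]
  if (length(scorable) < length(hubs))
    message(sprintf("skipping %d hub(s) with no passing edges",
                    length(hubs) - length(scorable)))
  subnets <- list()
  for (i in seq_along(scorable))
    subnets[[scorable[i]]] <- withStage("score-subnets",
      scoreSubnet(net, scorable[i], nNull = config$nNull,
                  seed = .stageSeed(config$seed, 2L) + i))
  if (length(subnets)) {
    subTab <- data.frame(
      tf_id = names(subnets),
      degree = vapply(subnets, function(s) nrow(s@memberEdges), integer(1)),
      es = vapply(subnets, function(s) s@es, numeric(1)),
      n_leading = vapply(subnets, function(s) nrow(s@leadingEdge), integer(1)),
      null_mean = vapply(subnets, function(s) s@nullMean, numeric(1)),
      null_sd = vapply(subnets, function(s) s@nullSD, numeric(1)),
      z_s = vapply(subnets, function(s) s@zS, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    .writeTsv(subTab[order(-subTab$z_s, subTab$tf_id), ],
              file.path(config$outDir, "subnet_scores.tsv"))
  }
  stages$subnets <- list(n_hubs = length(hubs), n_scored = length(subnets),
                         seconds = tick("subnets", s))

  # gene-level scoring + ranking
  s <- Sys.time()
  combined <- list(); ranking <- NULL
  if (length(subnets)) {
    for (i in seq_along(subnets)) {
      cs <- withStage("rank-tfs",
        scoreTrimmedGenes(degs, subnets[[i]], nNull = config$nNull,
                          seed = .stageSeed(config$seed, 3L) + i,
                          includeTf = config$includeTf))
      combined[[names(subnets)[i]]] <- annotateRegulatedDEGs(cs, degs)
    }
    ranking <- withStage("rank-tfs",
                         rankCandidates(combined, topK = length(combined)))
    .writeTsv(ranking, file.path(config$outDir, "tf_ranking_full.tsv"))
    .writeTsv(head(ranking, config$topK), file.path(config$outDir, "tf_ranking.tsv"))
  }
  stages$ranking <- list(n_ranked = length(combined),
                         top_k = min(config$topK, length(combined)),
                         seconds = tick("ranking", s))

  manifest <- list(
    tool = "dcTFnet", version = as.character(packageVersion("dcTFnet")),
    seed = config$seed,
    config = config[setdiff(names(config), c("simulate"))],
    simulate = if (!is.null(config$simulate)) unclass(config$simulate),
    stages = stages,
    total_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(manifest = manifest, experiment = x, degs = degs,
                 enrichment = enr, network = net, hubs = hubs,
                 subnetScores = subnets, combined = combined,
                 ranking = ranking, truth = truth))
}
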