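#' End-to-end bootstrap stability analysis
#'
#' Runs the full pipeline on a genotype dataset: SNP-bootstrap replicates are
#' generated and embedded ([runBootstrap()]), the overall embedding stability
#' score is the mean pairwise Procrustes similarity across replicates
#' ([embeddingStability()]), the cluster stability score is the mean pairwise
#' Fowlkes-Mallows agreement of k-means clusterings of Procrustes-matched
#' replicate pairs ([clusterStability()]), and per-row bootstrap support
#' values summarize each individual's projection dispersion
#' ([supportValues()]).
#'
#' @param x a [GenotypeData-class] object.
#' @param method `"pca"` (default) or `"mds"`.
#' @param nComponents components per embedding; defaults to 10 for PCA and 2
#'   for MDS.
#' @param projectIds individual ids to project rather than fit (PCA only).
#' @param distanceMetric,distanceLevel distance specification for MDS
#'   (defaults: euclidean, individual level).
#' @param nMax maximum bootstrap replicates (default 100).
#' @param tolerance convergence tolerance (default 0.05).
#' @param disableConvergence compute all `nMax` replicates.
#' @param threads parallel workers.
#' @param seed master seed; the whole analysis is reproducible from it.
#' @param k number of k-means clusters; `NULL` selects k by BIC grid search
#'   ([optimalK()]) on the embedding of the input dataset.
#' @param computeClusterStability logical; skip the (k-means) cluster
#'   stability when `FALSE`.
#' @param verbose progress messages to stderr.
#' @param fixIdentityIndices test hook forwarded to [runBootstrap()]: all
#'   replicates use the identity SNP indices.
#' @return a [StabilityResult-class] object.
#' @examples
#' g <- simulateGenotypes(nPopulations = 2, nPerPopulation = 8,
#'                        nSnps = 300, divergenceFst = 0.3, seed = 3)
#' analyzeStability(g, method = "pca", nComponents = 2, nMax = 10,
#'                  k = 3, seed = 3)
#' @export
analyzeStability <- function(x, method = c("pca", "mds"),
                             nComponents = NULL,
                             projectIds = character(0),
                             distanceMetric = "euclidean",
                             distanceLevel = "individual",
                             nMax = 100L, tolerance = 0.05,
                             disableConvergence = FALSE,
                             threads = 1L, seed = 42L,
                             k = NULL, computeClusterStability = TRUE,
                             verbose = FALSE,
                             fixIdentityIndices = FALSE) {
  stopifnot(is(x, "GenotypeData"))
  method <- match.arg(method)
  run <- runBootstrap(
    x, method = method, nComponents = nComponents, projectIds = projectIds,
    distanceMetric = distanceMetric, distanceLevel = distanceLevel,
    nMax = nMax, tolerance = tolerance,
    disableConvergence = disableConvergence,
    threads = threads, seed = seed, verbose = verbose,
    fixIdentityIndices = fixIdentityIndices
  )
  ps <- embeddingStability(run)
  doPcs <- isTRUE(computeClusterStability)
  kUsed <- NA_integer_
  pcs <- NA_real_
  if (doPcs) {
    if (is.null(k)) {
      baseEmbedding <- embedReplicate(
        x, method,
        if (method == "pca") {
          list(nComponents = as.integer(nComponents %||% 10L),
               projectIds = projectIds)
        } else {
          list(nComponents = as.integer(nComponents %||% 2L),
               distance = list(metric = distanceMetric, level = distanceLevel))
        }
      )
      lvlPops <- if (distanceLevel == "population" && method == "mds") NULL
                 else x@populations
      kUsed <- optimalK(baseEmbedding, populations = lvlPops,
                        seed = as.integer(seed))
    } else {
      kUsed <- as.integer(k)
    }
    pcs <- clusterStability(run, k = kUsed, seed = as.integer(seed))
  }
  psv <- supportValues(run)
  new("StabilityResult",
      stability = ps,
      clusterStab = pcs,
      k = kUsed,
      support = psv,
      nReplicates = run@nComputed,
      converged = run@converged,
      seed = as.integer(seed))
}

#' Write an embedding as TSV
#'
#' Layout mirrors the smartpca `.evec` convention: one row per embedding
#' row with its label, optional population, and the coordinates.
#'
#' @param e a [GenotypeEmbedding-class] object.
#' @param path output file path.
#' @param populations optional named or positional population labels.
#' @return invisibly, `path`.
#' @export
writeEmbedding <- function(e, path, populations = NULL) {
  cc <- e@coords
  df <- data.frame(row_label = rownames(cc), stringsAsFactors = FALSE)
  if (!is.null(populations)) df$population <- populations
  dims <- as.data.frame(cc)
  names(dims) <- paste0("dim_", seq_len(ncol(cc)))
  utils::write.table(cbind(df, dims), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix as square TSV with header labels
#'
#' @param d a [GenotypeDistances-class] object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeDistances <- function(d, path) {
  utils::write.table(d@values, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Write a stability report to an output directory
#'
#' Emits `report.json` (scores, replicate count, convergence flag, seed and
#' a configuration echo), `support_values.tsv` (sorted ascending so the
#' least stable rows come first) and, optionally, one TSV per replicate
#' embedding.
#'
#' @param result a [StabilityResult-class] object.
#' @param outputDir directory (created if needed).
#' @param config named list echoed verbatim into the report.
#' @param run optional [BootstrapEmbeddings-class]; when given, replicate
#'   embeddings are dumped as TSV under `replicates/`.
#' @return invisibly, the path to `report.json`.
#' @export
writeStabilityReport <- function(result, outputDir, config = list(), run = NULL) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    schema_version = "1.0",
    stability = result@stability,
    cluster_stability = if (is.na(result@clusterStab)) NULL else result@clusterStab,
    k = if (is.na(result@k)) NULL else result@k,
    n_replicates = result@nReplicates,
    converged = result@converged,
    seed = result@seed,
    config = config
  )
  reportPath <- file.path(outputDir, "report.json")
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  writeSupportValues(result@support, file.path(outputDir, "support_values.tsv"))
  if (!is.null(run)) {
    repDir <- file.path(outputDir, "replicates")
    dir.create(repDir, showWarnings = FALSE)
    for (i in seq_along(run@embeddings)) {
      writeEmbedding(run@embeddings[[i]],
                     file.path(repDir, sprintf("replicate_%03d.tsv", i)))
    }
  }
  invisible(reportPath)
}
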