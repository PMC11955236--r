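#' @describeIn accessors M x K dosage matrix (NA = missing).
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosages)

#' @describeIn accessors logical M x K matrix flagging missing genotypes.
#' @export
setMethod("missingMask", "GenotypeData", function(x) is.na(x@dosages))

#' @describeIn accessors individual identifiers (length M).
#' @export
setMethod("individualIds", "GenotypeData", function(x) x@individualIds)

#' @describeIn accessors population labels (length M, `""` when unknown).
#' @export
setMethod("populations", "GenotypeData", function(x) x@populations)

#' @describeIn accessors SNP identifiers (length K).
#' @export
setMethod("snpIds", "GenotypeData", function(x) x@snpIds)

#' @describeIn accessors number of individuals M.
#' @export
setMethod("nIndividuals", "GenotypeData", function(x) nrow(x@dosages))

#' @describeIn accessors number of SNPs K.
#' @export
setMethod("nSnps", "GenotypeData", function(x) ncol(x@dosages))

#' @describeIn accessors R x D coordinate matrix.
#' @export
setMethod("coords", "GenotypeEmbedding", function(x) x@coords)

#' @describeIn accessors embedding row labels.
#' @export
setMethod("rowLabels", "GenotypeEmbedding", function(x) rownames(x@coords))

#' @describeIn accessors `"individual"` or `"population"`.
#' @export
setMethod("embeddingLevel", "GenotypeEmbedding", function(x) x@level)

#' @describeIn accessors per-component explained-variance ratios (PCA only).
#' @export
setMethod("explainedVariance", "GenotypeEmbedding", function(x) x@explainedVariance)

#' @describeIn accessors symmetric distance matrix.
#' @export
setMethod("distanceValues", "GenotypeDistances", function(x) x@values)

#' @describeIn accessors distance-matrix row labels.
#' @export
setMethod("rowLabels", "GenotypeDistances", function(x) rownames(x@values))

#' @describeIn accessors metric name of a distance matrix.
#' @export
setMethod("distanceMetric", "GenotypeDistances", function(x) x@metric)

#' @describeIn accessors Procrustes disparity.
#' @export
setMethod("disparity", "ProcrustesComparison", function(x) x@disparity)

#' @describeIn accessors Procrustes similarity (1 - disparity).
#' @export
setMethod("similarity", "ProcrustesComparison", function(x) x@similarity)

#' @describeIn accessors list of replicate embeddings of a bootstrap run.
#' @export
setMethod("replicateEmbeddings", "BootstrapEmbeddings", function(x) x@embeddings)

#' @describeIn accessors convergence flag of a bootstrap run.
#' @export
setMethod("converged", "BootstrapEmbeddings", function(x) x@converged)

#' @describeIn accessors convergence flag recorded in a stability report.
#' @export
setMethod("converged", "StabilityResult", function(x) x@converged)

#' @describeIn accessors overall embedding stability score.
#' @export
setMethod("stabilityScore", "StabilityResult", function(x) x@stability)

#' @describeIn accessors cluster stability score (NA when not computed).
#' @export
setMethod("clusterStabilityScore", "StabilityResult", function(x) x@clusterStab)

#' @describeIn accessors named per-row support values.
#' @export
setMethod("supportValueVector", "StabilityResult", function(x) x@support)

setMethod("show", "GenotypeData", function(object) {
  miss <- mean(is.na(object@dosages))
  npop <- length(unique(object@populations[nzchar(object@populations)]))
  cat(sprintf(
    "GenotypeData: %d individuals x %d SNPs (%.1f%% missing, %d population%s)\n",
    nrow(object@dosages), ncol(object@dosages), 100 * miss,
    npop, if (npop == 1L) "" else "s"
  ))
})

setMethod("show", "GenotypeEmbedding", function(object) {
  cat(sprintf(
    "GenotypeEmbedding: %d %ss x %d components\n",
    nrow(object@coords), object@level, ncol(object@coords)
  ))
  if (length(object@explainedVariance)) {
    cat(sprintf(
      "  explained variance: %s\n",
      paste(sprintf("%.3f", object@explainedVariance), collapse = " ")
    ))
  }
})

setMethod("show", "GenotypeDistances", function(object) {
  cat(sprintf(
    "GenotypeDistances: %d x %d (%s, %s level)\n",
    nrow(object@values), ncol(object@values), object@metric, object@level
  ))
})

setMethod("show", "ProcrustesComparison", function(object) {
  cat(sprintf(
    "ProcrustesComparison: disparity %.6f, similarity %.6f, scale %.4f\n",
    object@disparity, object@similarity, object@scale
  ))
})

setMethod("show", "BootstrapEmbeddings", function(object) {
  cat(sprintf(
    "BootstrapEmbeddings: %d replicate embeddings (%s)\n",
    object@nComputed,
    if (isTRUE(object@converged)) "converged early" else "no early convergence"
  ))
})

setMethod("show", "StabilityResult", function(object) {
  cat("StabilityResult\n")
  cat(sprintf("  embedding stability : %.4f\n", object@stability))
  if (!is.na(object@clusterStab)) {
    cat(sprintf("  cluster stability   : %.4f (k = %d)\n",
                object@clusterStab, object@k))
  }
  cat(sprintf("  support values      : median %.4f, min %.4f (%s)\n",
              stats::median(object@support), min(object@support),
              names(object@support)[which.min(object@support)]))
  cat(sprintf("  replicates          : %d (%s), seed %d\n",
              object@nReplicates,
              if (isTRUE(object@converged)) "converged" else "max reached",
              object@seed))
})
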