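#' Pairwise distance matrix for MDS
#'
#' Computes the symmetric distance matrix consumed by [mdsEmbed()].
#' Individual-level metrics operate on the mean-imputed dosage matrix:
#' `euclidean` and `manhattan` via [stats::dist()], `hamming` as the count of
#' unequal rounded dosages (genotype codes are discrete, so imputed values
#' are rounded back to \{0, 1, 2\} first).  The population-level default is
#' the Hudson FST between every pair of populations, aggregated over SNPs as
#' a ratio of averages.
#'
#' @param x a [GenotypeData-class] object.
#' @param metric one of `"fst"` (population level only), `"euclidean"`,
#'   `"manhattan"`, `"hamming"`.
#' @param level `"individual"` or `"population"`.
#' @return a [GenotypeDistances-class] object.
#' @examples
#' g <- genotypeMatrix(rbind(a = c(0, 2), b = c(2, 0)))
#' distanceValues(pairwiseDistance(g, "manhattan"))
#' @export
pairwiseDistance <- function(x, metric = c("euclidean", "manhattan", "hamming", "fst"),
                             level = c("individual", "population")) {
  stopifnot(is(x, "GenotypeData"))
  metric <- match.arg(metric)
  level <- match.arg(level)
  if (metric == "fst" && level == "individual") {
    stop("FST is a between-population distance; use level = 'population'")
  }
  if (level == "population") {
    pops <- x@populations
    if (!all(nzchar(pops))) {
      stop("population-level distances require population labels for every individual")
    }
    if (metric == "fst") {
      v <- fstDistanceMatrix(x)
    } else {
      # non-FST population metrics: distance between per-population mean
      # dosage profiles
      imp <- meanImpute(x@dosages)
      prof <- rowsum(imp, pops) / as.vector(table(pops)[sort(unique(pops))])
      prof <- prof[sort(unique(pops)), , drop = FALSE]
      v <- metricDistance(prof, metric)
      rownames(v) <- colnames(v) <- sort(unique(pops))
    }
  } else {
    imp <- meanImpute(x@dosages)
    v <- metricDistance(imp, metric)
    rownames(v) <- colnames(v) <- x@individualIds
  }
  new("GenotypeDistances", values = v, level = level, metric = metric)
}

metricDistance <- function(m, metric) {
  if (metric == "hamming") {
    r <- round(m)
    n <- nrow(r)
    v <- matrix(0, n, n)
    # count of differing codes = sum over levels of mismatched indicators / 2
    for (lev in unique(as.vector(r))) {
      ind <- (r == lev) * 1
      v <- v + as.matrix(stats::dist(ind, method = "manhattan"))
    }
    v <- v / 2
  } else {
    v <- as.matrix(stats::dist(m, method = metric))
  }
  diag(v) <- 0
  (v + t(v)) / 2
}

#' Hudson FST (ratio of averages) between two populations
#'
#' Aggregates the per-SNP Hudson numerator and denominator across loci:
#' `N_s = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D_s = p1(1-p2) + p2(1-p1)`, returning `sum(N) / sum(D)` clamped to
#' \[0, 1\].  The ratio-of-averages form is the recommended way to combine
#' loci (per-SNP ratios are unstable at low diversity).
#'
#' @param p1,p2 per-SNP allele frequencies in \[0, 1\].
#' @param n1,n2 per-SNP haploid sample sizes (>= 2); recycled if scalar.
#' @return a single FST value in \[0, 1\].  SNPs with any non-finite input
#'   are skipped; if no SNP contributes a positive denominator the value is
#'   defined as 0 with a warning.
#' @examples
#' hudsonFst(p1 = 0, p2 = 1, n1 = 20, n2 = 20)  # fixed difference -> 1
#' @export
hudsonFst <- function(p1, n1, p2, n2) {
  L <- max(length(p1), length(p2))
  p1 <- rep_len(p1, L); p2 <- rep_len(p2, L)
  n1 <- rep_len(n1, L); n2 <- rep_len(n2, L)
  keep <- is.finite(p1) & is.finite(p2) & is.finite(n1) & is.finite(n2) &
    n1 >= 2 & n2 >= 2
  p1 <- p1[keep]; p2 <- p2[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  if (!length(p1)) {
    warning("no SNP usable for FST; returning 0")
    return(0)
  }
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (sum(den) <= 0) {
    warning("no polymorphism between the two populations; FST defined as 0")
    return(0)
  }
  min(max(sum(num) / sum(den), 0), 1)
}

fstDistanceMatrix <- function(x) {
  pops <- sort(unique(x@populations))
  if (length(pops) < 2L) stop("FST requires at least 2 populations")
  d <- x@dosages
  # per population: allele frequency and haploid sample size per SNP
  freqs <- lapply(pops, function(pp) {
    sub <- d[x@populations == pp, , drop = FALSE]
    nObs <- colSums(!is.na(sub))
    p <- colSums(sub, na.rm = TRUE) / (2 * nObs)
    p[nObs == 0] <- NA_real_
    list(p = p, n = 2 * nObs)
  })
  names(freqs) <- pops
  R <- length(pops)
  v <- matrix(0, R, R, dimnames = list(pops, pops))
  for (i in seq_len(R - 1L)) {
    for (j in seq((i + 1L), R)) {
      v[i, j] <- v[j, i] <- hudsonFst(freqs[[i]]$p, freqs[[i]]$n,
                                      freqs[[j]]$p, freqs[[j]]$n)
    }
  }
  v
}
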