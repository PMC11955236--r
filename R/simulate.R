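#' Simulate structured genotype data under the Balding-Nichols model
#'
#' Generates a multi-population biallelic dataset: per SNP an ancestral
#' allele frequency is drawn from Uniform(0.05, 0.95); each population draws
#' its own frequency from the Balding-Nichols Beta distribution
#' `Beta(p (1 - F) / F, (1 - p) (1 - F) / F)` whose divergence parameter F
#' equals the expected pairwise FST; each individual's dosage is
#' Binomial(2, p_pop).  This emulates the clearly structured multi-population
#' datasets used to validate bootstrap stability estimation, with a tunable
#' differentiation level, at desk scale.
#'
#' @param nPopulations number of populations (default 2).
#' @param nPerPopulation individuals per population (default 50).
#' @param nSnps number of SNPs (default 5000).
#' @param divergenceFst Balding-Nichols divergence parameter F in (0, 1)
#'   (default 0.1, a typical between-continental-group value).
#' @param missingProportion proportion of cells set missing after simulation
#'   via [injectMissing()] (default 0).
#' @param noiseProportion proportion of cells perturbed after simulation via
#'   [injectNoise()] (default 0).
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return a [GenotypeData-class] with populations labelled
#'   `pop_0 ... pop_{n-1}` and individuals `pop_j:ind_i`.
#' @examples
#' g <- simulateGenotypes(nPopulations = 2, nPerPopulation = 10,
#'                        nSnps = 500, divergenceFst = 0.2, seed = 1)
#' g
#' @export
simulateGenotypes <- function(nPopulations = 2L, nPerPopulation = 50L,
                              nSnps = 5000L, divergenceFst = 0.1,
                              missingProportion = 0, noiseProportion = 0,
                              seed = 1L) {
  if (nPopulations < 1L) stop("nPopulations must be >= 1")
  if (nPerPopulation < 2L) stop("nPerPopulation must be >= 2")
  if (nSnps < 1L) stop("nSnps must be >= 1")
  if (divergenceFst <= 0 || divergenceFst >= 1) {
    stop("divergenceFst must lie in (0, 1)")
  }
  if (missingProportion < 0 || missingProportion >= 1) {
    stop("missingProportion must lie in [0, 1)")
  }
  if (noiseProportion < 0 || noiseProportion >= 1) {
    stop("noiseProportion must lie in [0, 1)")
  }
  FF <- divergenceFst
  M <- nPopulations * nPerPopulation
  d <- withr::with_seed(as.integer(seed), {
    p <- stats::runif(nSnps, 0.05, 0.95)
    out <- matrix(NA_real_, nrow = M, ncol = nSnps)
    for (j in seq_len(nPopulations)) {
      pj <- stats::rbeta(nSnps, p * (1 - FF) / FF, (1 - p) * (1 - FF) / FF)
      rows <- seq((j - 1L) * nPerPopulation + 1L, j * nPerPopulation)
      out[rows, ] <- matrix(
        stats::rbinom(nPerPopulation * nSnps, 2L, rep(pj, each = nPerPopulation)),
        nrow = nPerPopulation
      )
    }
    out
  })
  pops <- rep(paste0("pop_", seq_len(nPopulations) - 1L), each = nPerPopulation)
  ids <- paste0(pops, ":ind_", rep(seq_len(nPerPopulation) - 1L, nPopulations))
  g <- newGenotypeData(d, ids, pops, paste0("snp_", seq_len(nSnps) - 1L))
  if (noiseProportion > 0) g <- injectNoise(g, noiseProportion, seed = seed + 1L)
  if (missingProportion > 0) g <- injectMissing(g, missingProportion, seed = seed + 2L)
  g
}

#' Replace a fixed proportion of genotype cells with missing values
#'
#' Exactly `floor(proportion * M * K)` distinct cells, chosen uniformly at
#' random, become missing.  Matrix dimensions are unchanged.
#'
#' @param x a [GenotypeData-class] object.
#' @param proportion proportion of cells in \[0, 1).
#' @param seed integer seed.
#' @return distorted [GenotypeData-class] object.
#' @export
injectMissing <- function(x, proportion, seed = 1L) {
  stopifnot(is(x, "GenotypeData"))
  if (proportion < 0 || proportion >= 1) stop("proportion must lie in [0, 1)")
  nCells <- length(x@dosages)
  nPick <- floor(proportion * nCells)
  if (nPick == 0L) return(x)
  pick <- withr::with_seed(as.integer(seed),
                           sample.int(nCells, nPick, replace = FALSE))
  d <- x@dosages
  d[pick] <- NA_real_
  newGenotypeData(d, x@individualIds, x@populations, x@snpIds,
                  x@snpChrom, x@snpPos)
}

#' Perturb a fixed proportion of genotype cells with random noise
#'
#' Exactly `floor(proportion * M * K)` distinct non-missing cells, chosen
#' uniformly at random, are replaced by a uniformly random genotype code in
#' \{0, 1, 2\} that differs from the current one — so the nominal noise
#' proportion equals the effective proportion of altered cells.  Missing
#' cells are never selected.
#'
#' @param x a [GenotypeData-class] object.
#' @param proportion proportion of all M x K cells in \[0, 1).
#' @param seed integer seed.
#' @return distorted [GenotypeData-class] object.
#' @export
injectNoise <- function(x, proportion, seed = 1L) {
  stopifnot(is(x, "GenotypeData"))
  if (proportion < 0 || proportion >= 1) stop("proportion must lie in [0, 1)")
  nCells <- length(x@dosages)
  nPick <- floor(proportion * nCells)
  if (nPick == 0L) return(x)
  observed <- which(!is.na(x@dosages))
  if (nPick > length(observed)) {
    stop(sprintf(
      "cannot alter %d cells: only %d non-missing cells available",
      nPick, length(observed)
    ))
  }
  d <- x@dosages
  withr::with_seed(as.integer(seed), {
    pick <- sample(observed, nPick, replace = FALSE)
    # draw from the 2 codes differing from the current one
    shift <- sample.int(2L, nPick, replace = TRUE)
    d[pick] <- (d[pick] + shift) %% 3
  })
  newGenotypeData(d, x@individualIds, x@populations, x@snpIds,
                  x@snpChrom, x@snpPos)
}
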