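test_that("PCA separates two perfectly homogeneous groups on PC1", {
  d <- rbind(matrix(0, 5, 30), matrix(2, 5, 30))
  g <- genotypeMatrix(d)
  e <- pcaEmbed(g, nComponents = 2)
  pc1 <- round(coords(e)[, 1], 10)
  expect_length(unique(pc1), 2L)
  expect_length(unique(pc1[1:5]), 1L)
  expect_length(unique(pc1[6:10]), 1L)
  expect_true(unique(pc1[1:5]) != unique(pc1[6:10]))
})

test_that("PCA scores match a dense eigendecomposition oracle", {
  g <- randomGenotypes(20, 100, seed = 42)
  e <- pcaEmbed(g, nComponents = 5)

  # independent route: explicitly form the scaled matrix and the K x K
  # covariance eigendecomposition (the implementation goes through the
  # M x M cross-product instead)
  d <- dosages(g)
  mu <- colMeans(d)
  p <- mu / 2
  sdv <- sqrt(p * (1 - p))
  X <- sweep(d, 2, mu, "-")
  keep <- sdv > 0 & apply(d, 2, function(cc) length(unique(cc)) > 1)
  X[, keep] <- sweep(X[, keep], 2, sdv[keep], "/")
  X[, !keep] <- 0
  cov <- crossprod(X) / (nrow(X) - 1)
  eg <- eigen(cov, symmetric = TRUE)
  scoresOracle <- X %*% eg$vectors[, 1:5]

  for (j in 1:5) {
    obs <- coords(e)[, j]
    ora <- scoresOracle[, j]
    expect_lt(min(max(abs(obs - ora)), max(abs(obs + ora))), 1e-8)
  }
  evOracle <- eg$values[1:5] / sum(pmax(eg$values, 0))
  expect_equal(explainedVariance(e), evOracle, tolerance = 1e-8)
})

test_that("PCA score columns are orthogonal with variances equal to the eigenvalues", {
  g <- randomGenotypes(15, 80, seed = 3)
  e <- pcaEmbed(g, nComponents = 4)
  S <- coords(e)
  cp <- crossprod(S)
  expect_lt(max(abs(cp - diag(diag(cp)))), 1e-8)
  # eigenvalue_j = var(scores_j): both equal d_j^2 / (M - 1)
  ratios <- apply(S, 2, stats::var)
  expect_equal(unname(ratios / sum(ratios)),
               explainedVariance(e) / sum(explainedVariance(e)),
               tolerance = 1e-8)
})

test_that("PCA is equivariant to individual reordering and deterministic", {
  g <- randomGenotypes(12, 60, seed = 9)
  e1 <- pcaEmbed(g, nComponents = 3)
  expect_identical(coords(e1), coords(pcaEmbed(g, nComponents = 3)))

  perm <- withr::with_seed(1, sample(nIndividuals(g)))
  gp <- genotypeMatrix(dosages(g)[perm, ], missingCode = NA,
                       individualIds = individualIds(g)[perm])
  e2 <- pcaEmbed(gp, nComponents = 3)
  expect_equal(coords(e2)[individualIds(g), ], coords(e1), tolerance = 1e-8)
})

test_that("a fully observed projected individual lands on its own fit score", {
  g0 <- randomGenotypes(15, 120, seed = 5)
  # duplicate individual 1 as a 'projected' copy
  d <- rbind(dosages(g0), dosages(g0)[1, ])
  g <- genotypeMatrix(d, missingCode = NA,
                      individualIds = c(individualIds(g0), "copy"))
  e <- pcaEmbed(g, nComponents = 4, projectIds = "copy")
  expect_equal(coords(e)["copy", ], coords(e)[1, ], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("projection with heavy missingness still places individuals near kin", {
  g <- simulateGenotypes(nPopulations = 2, nPerPopulation = 15, nSnps = 2000,
                         divergenceFst = 0.3, seed = 21)
  # degrade one individual of pop_1 to 70% missing and project it
  d <- dosages(g)
  target <- which(populations(g) == "pop_1")[1]
  miss <- withr::with_seed(99, sample(nSnps(g), 1400))
  d[target, miss] <- NA
  g2 <- genotypeMatrix(d, missingCode = NA,
                       individualIds = individualIds(g),
                       populations = populations(g))
  e <- pcaEmbed(g2, nComponents = 2, projectIds = individualIds(g)[target])
  pc1 <- coords(e)[, 1]
  own <- setdiff(which(populations(g) == "pop_1"), target)
  other <- which(populations(g) == "pop_0")
  expect_lt(abs(pc1[target] - mean(pc1[own])),
            abs(pc1[target] - mean(pc1[other])))
})

test_that("pcaEmbed validates its parameters", {
  g <- randomGenotypes(5, 10, seed = 1)
  expect_error(pcaEmbed(g, nComponents = 5), "exceeds")
  expect_error(pcaEmbed(g, nComponents = 2,
                        projectIds = individualIds(g)[1:4]),
               "fewer than 2")
  expect_error(pcaEmbed(g, nComponents = 2, projectIds = "nonexistent"),
               "not found")
})

test_that("individual-level distances match hand-computed formulas", {
  g <- genotypeMatrix(rbind(a = c(0, 2), b = c(2, 0)))
  expect_equal(distanceValues(pairwiseDistance(g, "euclidean"))[1, 2], sqrt(8))
  expect_equal(distanceValues(pairwiseDistance(g, "manhattan"))[1, 2], 4)
  expect_equal(distanceValues(pairwiseDistance(g, "hamming"))[1, 2], 2)
})

test_that("identical rows are at distance zero for every metric", {
  g <- genotypeMatrix(rbind(a = c(1, 2, 0), b = c(1, 2, 0), c = c(0, 0, 2)))
  for (m in c("euclidean", "manhattan", "hamming")) {
    v <- distanceValues(pairwiseDistance(g, m))
    expect_equal(v[1, 2], 0)
    expect_true(isSymmetric(v))
    expect_equal(diag(v), c(a = 0, b = 0, c = 0))
  }
})

test_that("permuting individuals permutes the distance matrix identically", {
  g <- randomGenotypes(8, 40, seed = 13)
  v <- distanceValues(pairwiseDistance(g, "euclidean"))
  perm <- withr::with_seed(2, sample(8))
  gp <- genotypeMatrix(dosages(g)[perm, ], missingCode = NA,
                       individualIds = individualIds(g)[perm])
  vp <- distanceValues(pairwiseDistance(gp, "euclidean"))
  expect_equal(vp[individualIds(g), individualIds(g)], v, tolerance = 1e-12)
})

test_that("Hudson FST matches hand computation and boundary cases", {
  # fixed difference: N = 1, D = 1 -> 1 (n terms vanish as p(1-p) = 0)
  expect_equal(hudsonFst(0, 20, 1, 20), 1)
  # no differentiation at finite n: estimator is negative, clamped to 0
  expect_equal(hudsonFst(rep(0.5, 50), 20, rep(0.5, 50), 20), 0)
  # two-SNP hand computation
  p1 <- c(0.2, 0.5); p2 <- c(0.8, 0.5); n <- 20
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n - 1) - p2 * (1 - p2) / (n - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_equal(hudsonFst(p1, n, p2, n), sum(num) / sum(den))
  # symmetric in population order
  expect_equal(hudsonFst(p1, n, p2, n), hudsonFst(p2, n, p1, n))
  # degenerate: no polymorphism at all
  expect_warning(z <- hudsonFst(rep(0, 5), 10, rep(0, 5), 10), "polymorphism")
  expect_equal(z, 0)
})

test_that("FST distance matrices are population-level only", {
  g <- simulateGenotypes(nPopulations = 3, nPerPopulation = 10, nSnps = 500,
                         divergenceFst = 0.1, seed = 2)
  dm <- pairwiseDistance(g, "fst", level = "population")
  expect_equal(dim(distanceValues(dm)), c(3L, 3L))
  expect_true(all(distanceValues(dm) >= 0 & distanceValues(dm) <= 1))
  expect_error(pairwiseDistance(g, "fst", level = "individual"),
               "population")
  noPop <- randomGenotypes(4, 10, seed = 1)
  expect_error(pairwiseDistance(noPop, "fst", level = "population"),
               "population labels")
})

test_that("MDS reproduces a Euclidean-realizable configuration", {
  # 3 collinear points at 0, 1, 2
  delta <- as.matrix(dist(matrix(c(0, 1, 2), ncol = 1)))
  rownames(delta) <- colnames(delta) <- c("a", "b", "c")
  e <- mdsEmbed(delta, nComponents = 2)
  dd <- as.matrix(dist(coords(e)))
  expect_equal(dd[upper.tri(dd)], delta[upper.tri(delta)], tolerance = 1e-6)
})

test_that("MDS handles the all-zero distance matrix and monotone stress", {
  zeros <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  e <- mdsEmbed(zeros, nComponents = 2)
  expect_true(all(coords(e) == 0))

  # random non-Euclidean target: final stress <= classical-scaling stress
  delta <- withr::with_seed(8, {
    m <- matrix(runif(36, 1, 3), 6, 6)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  })
  rownames(delta) <- colnames(delta) <- paste0("x", 1:6)
  e <- mdsEmbed(delta, nComponents = 2)
  stressOf <- function(X) {
    dX <- as.matrix(dist(X))
    sum((delta[upper.tri(delta)] - dX[upper.tri(dX)])^2)
  }
  init <- stats::cmdscale(delta, k = 2)
  expect_lte(stressOf(coords(e)), stressOf(init) + 1e-12)
})

test_that("MDS validates its input", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(mdsEmbed(bad), "symmetric")
  delta <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(mdsEmbed(delta, nComponents = 2), "exceeds")
})
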