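# Fixture builders and independent oracles shared across the test files.

# quick embedding from a coordinate matrix
makeEmbedding <- function(cc, labels = NULL, level = "individual") {
  if (is.null(labels)) labels <- paste0("r", seq_len(nrow(cc)))
  rownames(cc) <- labels
  new("GenotypeEmbedding", coords = as.matrix(cc), level = level,
      explainedVariance = numeric(0))
}

# random dataset with a known missing pattern
randomGenotypes <- function(M, K, missingProp = 0, seed = 1) {
  d <- withr::with_seed(seed, {
    d <- matrix(sample(0:2, M * K, replace = TRUE), M, K)
    if (missingProp > 0) {
      d[sample.int(M * K, floor(missingProp * M * K))] <- NA
    }
    d
  })
  genotypeMatrix(d, missingCode = NA)
}

# brute-force 2-D Procrustes disparity: grid over rotation angles x
# {reflection, no reflection}, closed-form scale per candidate
bruteForceDisparity2D <- function(cu, cv, nAngles = 20000L) {
  X <- scale(cu, scale = FALSE); X <- X / sqrt(sum(X^2))
  Y <- scale(cv, scale = FALSE); Y <- Y / sqrt(sum(Y^2))
  best <- Inf
  for (refl in c(1, -1)) {
    for (theta in seq(0, 2 * pi, length.out = nAngles)) {
      Q <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
      Q[, 2] <- refl * Q[, 2]
      XQ <- X %*% Q
      # optimal scale b for min ||b XQ - Y||^2 with ||XQ|| = 1
      b <- sum(XQ * Y)
      resid <- sum((b * XQ - Y)^2)
      if (resid < best) best <- resid
    }
  }
  best
}

# brute-force Fowlkes-Mallows by pair enumeration
bruteForceFM <- function(a, b) {
  n <- length(a)
  tp <- fp <- fn <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      inA <- a[i] == a[j]
      inB <- b[i] == b[j]
      if (inA && inB) tp <- tp + 1
      else if (inA) fp <- fp + 1
      else if (inB) fn <- fn + 1
    }
  }
  if (tp + fp == 0 || tp + fn == 0) return(0)
  tp / sqrt((tp + fp) * (tp + fn))
}

# double-loop Gini-dispersion support oracle on a list of coordinate matrices
bruteForceSupport <- function(mats) {
  N <- length(mats)
  R <- nrow(mats[[1]])
  vapply(seq_len(R), function(i) {
    sumDist <- 0
    for (u in seq_len(N - 1)) {
      for (v in seq(u + 1, N)) {
        sumDist <- sumDist + sqrt(sum((mats[[u]][i, ] - mats[[v]][i, ])^2))
      }
    }
    sumNorm <- sum(vapply(mats, function(m) sqrt(sum(m[i, ]^2)), numeric(1)))
    min(max(1 - sumDist / (N * sumNorm), 0), 1)
  }, numeric(1))
}

# three well-separated Gaussian blobs in 2-D (optimum of k-means is unique)
separatedBlobs <- function(kTrue = 3, perBlob = 10, spread = 0.05, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(c(0, 0, 10, 0, 5, 10, -8, 8, 12, -9), ncol = 2,
                      byrow = TRUE)[seq_len(kTrue), , drop = FALSE]
    cc <- do.call(rbind, lapply(seq_len(kTrue), function(j) {
      sweep(matrix(rnorm(perBlob * 2, sd = spread), ncol = 2), 2,
            centers[j, ], "+")
    }))
    list(coords = cc, labels = rep(seq_len(kTrue), each = perBlob))
  })
}
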