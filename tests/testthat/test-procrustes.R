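test_that("standardization centers, normalizes, and is idempotent", {
  cc <- matrix(c(1, -1, 1, -1), 2, 2, dimnames = list(c("a", "b"), NULL))
  s <- standardizeEmbedding(cc)
  expect_equal(s, matrix(c(0.5, -0.5, 0.5, -0.5), 2, 2,
                         dimnames = dimnames(cc)))
  expect_equal(colMeans(s), c(0, 0))
  expect_equal(sum(s^2), 1)  # trace(P P') = 1

  # invariance to adding a constant vector to every row
  shifted <- sweep(cc, 2, c(100, -7), "+")
  expect_equal(standardizeEmbedding(shifted), s, ignore_attr = TRUE)
  # idempotence
  expect_equal(standardizeEmbedding(s), s, tolerance = 1e-12)
  # degenerate input
  expect_error(standardizeEmbedding(matrix(3, 4, 2,
                                           dimnames = list(letters[1:4], NULL))),
               "degenerate")
})

test_that("disparity is 0 for exact copies and for similarity-transformed copies", {
  cc <- withr::with_seed(1, matrix(rnorm(16), 8, 2))
  rownames(cc) <- paste0("i", 1:8)
  expect_equal(disparity(procrustesDisparity(cc, cc)), 0, tolerance = 1e-12)

  theta <- 0.7
  Q <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  refl <- diag(c(1, -1))
  tr <- cc %*% Q %*% refl * 3.7
  tr <- sweep(tr, 2, c(5, -2), "+")
  rownames(tr) <- rownames(cc)
  expect_lt(disparity(procrustesDisparity(cc, tr)), 1e-10)
  expect_equal(similarity(procrustesDisparity(cc, tr)), 1, tolerance = 1e-10)
})

test_that("disparity matches the rotation-grid brute-force oracle on many instances", {
  nCases <- 100
  for (case in seq_len(nCases)) {
    pair <- withr::with_seed(1000 + case, {
      list(u = matrix(rnorm(12), 6, 2), v = matrix(rnorm(12), 6, 2))
    })
    rownames(pair$u) <- rownames(pair$v) <- paste0("i", 1:6)
    got <- disparity(procrustesDisparity(pair$u, pair$v))
    oracle <- bruteForceDisparity2D(pair$u, pair$v, nAngles = 3000L)
    expect_lt(abs(got - oracle), 1e-4)
  }
})

test_that("disparity agrees with vegan's Procrustes residual on standardized input", {
  skip_if_not_installed("vegan")
  pair <- withr::with_seed(7, list(u = matrix(rnorm(30), 10, 3),
                                   v = matrix(rnorm(30), 10, 3)))
  rownames(pair$u) <- rownames(pair$v) <- paste0("i", 1:10)
  got <- disparity(procrustesDisparity(pair$u, pair$v))
  fit <- vegan::procrustes(standardizeEmbedding(pair$v),
                           standardizeEmbedding(pair$u), symmetric = FALSE)
  expect_equal(got, sum((fit$Yrot - fit$X)^2), tolerance = 1e-8)
})

test_that("disparity is symmetric, bounded, and detects label mismatches", {
  for (case in 1:20) {
    pair <- withr::with_seed(2000 + case, {
      list(u = matrix(rnorm(20), 10, 2), v = matrix(rnorm(20), 10, 2))
    })
    rownames(pair$u) <- rownames(pair$v) <- paste0("i", 1:10)
    duv <- disparity(procrustesDisparity(pair$u, pair$v))
    dvu <- disparity(procrustesDisparity(pair$v, pair$u))
    expect_lt(abs(duv - dvu), 1e-10)
    expect_gte(duv, 0)
    expect_lte(duv, 1)
  }
  a <- matrix(rnorm(8), 4, 2, dimnames = list(c("a", "b", "c", "d"), NULL))
  b <- a
  rownames(b) <- c("a", "b", "X", "d")
  expect_error(procrustesDisparity(a, b), "row 3.*'c' vs 'X'")
  expect_error(procrustesDisparity(a, matrix(0, 3, 2)), "shapes differ")
})

test_that("the fitted transform is orthogonal and reproduces the alignment", {
  pair <- withr::with_seed(5, list(u = matrix(rnorm(20), 10, 2),
                                   v = matrix(rnorm(20), 10, 2)))
  rownames(pair$u) <- rownames(pair$v) <- paste0("i", 1:10)
  comp <- procrustesDisparity(pair$u, pair$v)
  Q <- comp@rotation
  expect_equal(crossprod(Q), diag(2), tolerance = 1e-10)
  X <- standardizeEmbedding(pair$u)
  Y <- standardizeEmbedding(pair$v)
  expect_equal(sum((X %*% Q * comp@scale - Y)^2), disparity(comp),
               tolerance = 1e-10)
})

test_that("overall stability averages pairwise similarities", {
  cc <- withr::with_seed(3, matrix(rnorm(20), 10, 2))
  rownames(cc) <- paste0("i", 1:10)
  e <- makeEmbedding(cc, labels = rownames(cc))
  # N identical embeddings -> stability 1
  expect_equal(embeddingStability(list(e, e, e)), 1, tolerance = 1e-12)

  # stability is the plain mean over the three unordered pairs
  es <- withr::with_seed(4, lapply(1:3, function(i) {
    makeEmbedding(matrix(rnorm(20), 10, 2), labels = rownames(cc))
  }))
  pairMean <- mean(c(
    similarity(procrustesDisparity(coords(es[[1]]), coords(es[[2]]))),
    similarity(procrustesDisparity(coords(es[[1]]), coords(es[[3]]))),
    similarity(procrustesDisparity(coords(es[[2]]), coords(es[[3]])))
  ))
  expect_equal(embeddingStability(es), pairMean, tolerance = 1e-12)
  expect_error(embeddingStability(es[1]), "at least 2")
})

test_that("stability is invariant to per-embedding orthogonal maps", {
  es <- withr::with_seed(6, lapply(1:4, function(i) {
    makeEmbedding(matrix(rnorm(16), 8, 2), labels = paste0("i", 1:8))
  }))
  base <- embeddingStability(es)
  rotated <- lapply(seq_along(es), function(i) {
    theta <- i * 0.9
    Q <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    if (i %% 2 == 0) Q <- Q %*% diag(c(-1, 1))
    makeEmbedding(coords(es[[i]]) %*% Q, labels = paste0("i", 1:8))
  })
  expect_equal(embeddingStability(rotated), base, tolerance = 1e-10)
})
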