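test_that("EIGENSTRAT triplet is decoded per the format definition", {
  dir <- withr::local_tempdir()
  writeLines(c("01", "29", "10"), file.path(dir, "toy.geno"))
  writeLines(c("snp0 1 0.0 100 A C", "snp1 1 0.0 200 A C", "snp2 1 0.0 300 A C"),
             file.path(dir, "toy.snp"))
  writeLines(c("ind1 M popA", "ind2 F popB"), file.path(dir, "toy.ind"))

  g <- readEigenstrat(prefix = file.path(dir, "toy"))
  expect_equal(nIndividuals(g), 2L)
  expect_equal(nSnps(g), 3L)
  # .geno is SNP-major: line s column i -> dosages[i, s]
  expect_equal(dosages(g)[1, ], c(0, 2, 1))
  expect_equal(dosages(g)[2, c(1, 3)], c(1, 0))
  expect_true(is.na(dosages(g)[2, 2]))
  expect_equal(missingMask(g), rbind(c(FALSE, FALSE, FALSE),
                                     c(FALSE, TRUE, FALSE)))
  expect_equal(populations(g), c("popA", "popB"))
  expect_equal(snpIds(g), c("snp0", "snp1", "snp2"))
})

test_that("malformed EIGENSTRAT input raises format errors naming the line", {
  dir <- withr::local_tempdir()
  writeLines(c("01", "2"), file.path(dir, "bad.geno"))
  writeLines(c("s0 1 0 1 A C", "s1 1 0 2 A C"), file.path(dir, "bad.snp"))
  writeLines(c("i1 M p", "i2 M p"), file.path(dir, "bad.ind"))
  expect_error(readEigenstrat(prefix = file.path(dir, "bad")), "line 2")

  writeLines(c("01", "23"), file.path(dir, "bad.geno"))
  expect_error(readEigenstrat(prefix = file.path(dir, "bad")), "invalid character '3'")

  writeLines(c("01", "20"), file.path(dir, "bad.geno"))
  writeLines("s0 1 0 1 A C", file.path(dir, "bad.snp"))
  expect_error(readEigenstrat(prefix = file.path(dir, "bad")), "\\.snp")
})

test_that("EIGENSTRAT write/read round trip is the identity", {
  g <- simulateGenotypes(nPopulations = 2, nPerPopulation = 3, nSnps = 20,
                         divergenceFst = 0.2, missingProportion = 0.15,
                         seed = 11)
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "rt")
  writeEigenstrat(g, prefix)
  g2 <- readEigenstrat(prefix = prefix)
  expect_equal(dosages(g2), dosages(g))
  expect_equal(missingMask(g2), missingMask(g))
  expect_equal(individualIds(g2), individualIds(g))
  expect_equal(populations(g2), populations(g))
  expect_equal(snpIds(g2), snpIds(g))
  # missing cells render as '9' in the .geno file
  genoLines <- readLines(paste0(prefix, ".geno"))
  nNines <- sum(vapply(strsplit(genoLines, ""), function(ch) sum(ch == "9"),
                       numeric(1)))
  expect_equal(nNines, sum(missingMask(g)))
})

test_that("PLINK .ped decoding matches hand-decoded dosages", {
  dir <- withr::local_tempdir()
  # SNP1 alleles {A,G} (ref A), SNP2 alleles {C,T} (ref C)
  writeLines(c(
    "fam1 i1 0 0 1 -9 A A C T",
    "fam1 i2 0 0 2 -9 A G T T",
    "fam2 i3 0 0 1 -9 G G 0 0"
  ), file.path(dir, "toy.ped"))
  writeLines(c("1 rs1 0 100", "1 rs2 0 200"), file.path(dir, "toy.map"))
  g <- readPlinkPed(file.path(dir, "toy.ped"), file.path(dir, "toy.map"))
  expect_equal(dosages(g)[, 1], c(2, 1, 0))
  expect_equal(dosages(g)[1:2, 2], c(1, 0))
  expect_true(is.na(dosages(g)[3, 2]))
  expect_equal(populations(g), c("fam1", "fam1", "fam2"))
  expect_equal(snpIds(g), c("rs1", "rs2"))
})

test_that("PLINK decoding is invariant to allele-column order and rejects >2 alleles", {
  dir <- withr::local_tempdir()
  writeLines(c("f a 0 0 1 -9 A G", "f b 0 0 1 -9 G A", "f c 0 0 1 -9 A A"),
             file.path(dir, "swap.ped"))
  writeLines("1 rs1 0 1", file.path(dir, "swap.map"))
  g <- readPlinkPed(file.path(dir, "swap.ped"), file.path(dir, "swap.map"))
  expect_equal(dosages(g)[1, 1], dosages(g)[2, 1])  # A G == G A

  writeLines(c("f a 0 0 1 -9 A G", "f b 0 0 1 -9 C A"),
             file.path(dir, "tri.ped"))
  writeLines("1 rs9 0 1", file.path(dir, "tri.map"))
  expect_error(readPlinkPed(file.path(dir, "tri.ped"), file.path(dir, "tri.map")),
               "rs9")

  writeLines("f a 0 0 1 -9 A G A", file.path(dir, "odd.ped"))
  expect_error(readPlinkPed(file.path(dir, "odd.ped"), file.path(dir, "swap.map")),
               "odd")
})

test_that("matrix ingestion validates codes and synthesizes metadata", {
  g <- genotypeMatrix(rbind(c(0, 1), c(2, 9)))
  expect_equal(individualIds(g), c("ind_0", "ind_1"))
  expect_equal(populations(g), c("", ""))
  expect_true(is.na(dosages(g)[2, 2]))
  expect_equal(sum(missingMask(g)), 1L)
  expect_error(genotypeMatrix(matrix(3, 2, 1)), "not in")
})

test_that("delimited-text round trip preserves dosages and mask", {
  g <- randomGenotypes(10, 50, missingProp = 0.2, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeTable(g, path)
  g2 <- readGenotypeTable(path)
  expect_equal(dosages(g2), dosages(g))
  expect_equal(missingMask(g2), missingMask(g))
  expect_equal(individualIds(g2), individualIds(g))
})

test_that("mean imputation fills missing cells with SNP means and only those", {
  g <- genotypeMatrix(rbind(c(0, 1, 9), c(2, 9, 9), c(9, 1, 9)))
  expect_warning(imp <- meanImpute(g), "entirely missing")
  expect_equal(imp[, 1], c(0, 2, 1))      # mean of {0,2} fills the NA
  expect_equal(imp[, 2], c(1, 1, 1))
  expect_equal(imp[, 3], c(0, 0, 0))      # all-missing column -> 0
  expect_false(anyNA(imp))

  full <- genotypeMatrix(rbind(c(0, 1), c(2, 2)))
  expect_identical(meanImpute(full), dosages(full))
})

test_that("GenotypeData validity rejects inconsistent construction", {
  expect_error(genotypeMatrix(matrix(0, 1, 3)), "2 individuals")
  expect_error(
    genotypeMatrix(rbind(c(0, 1), c(1, 2)), individualIds = c("a", "a")),
    "unique"
  )
  expect_error(
    genotypeMatrix(rbind(c(0, 1), c(1, 2)), populations = "only_one"),
    "populations"
  )
})
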