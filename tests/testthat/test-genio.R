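# Genotype I/O, QC filters and allele frequencies.

test_that("genotype_table enforces its invariants", {
  expect_error(mk_gt(matrix(3, 2, 2)), "invalid dosage")
  expect_error(mk_gt(matrix(0, 2, 2), bp = c(200, 100)),
               "strictly increasing")
  expect_error(genotype_table(matrix(0, 2, 3),
                              data.frame(id = c("a", "b"), chr = "1",
                                         bp = 1:2),
                              data.frame(id = c("x", "y"))),
               "structural error")
  # empty SNP list is a valid table
  empty <- genotype_table(matrix(0, 3, 0),
                          data.frame(id = character(), chr = character(),
                                     bp = numeric()),
                          data.frame(id = c("a", "b", "c")))
  expect_equal(n_snps(empty), 0L)
  expect_equal(n_individuals(empty), 3L)
})

test_that("write/read round trip reproduces dosages in every format", {
  set.seed(42)
  d <- matrix(sample(c(0:2, NA), 60, replace = TRUE, prob = c(3, 3, 3, 1)),
              10, 6)
  gt <- mk_gt(d, chr = rep(c("1", "2"), each = 3), bp = rep(1:3 * 1e5, 2))
  for (fmt in c("plink-text", "plink-binary", "tsv")) {
    prefix <- file.path(withr::local_tempdir(), "rt")
    write_genotypes(gt, prefix, fmt)
    back <- read_genotypes(prefix, fmt)
    expect_equal(unname(back$dosages), unname(gt$dosages),
                 info = fmt)
    expect_equal(back$snp_map$bp, gt$snp_map$bp, info = fmt)
    expect_equal(back$individuals$id, gt$individuals$id, info = fmt)
  }
})

test_that("a small .ped/.map fixture is read as hand-expected", {
  dir <- withr::local_tempdir()
  writeLines(c("1 2 0 4", "1 5 0 9"), file.path(dir, "toy.map"))
  writeLines(c("F1 i1 0 0 1 -9 A A A C",
               "F1 i2 0 0 2 -9 A C C C",
               "F1 i3 0 0 1 -9 0 0 A C"),
             file.path(dir, "toy.ped"))
  gt <- read_genotypes(file.path(dir, "toy"), "plink-text")
  # counted allele is the alphabetically larger one (C)
  expect_equal(unname(gt$dosages),
               rbind(c(0, 1), c(1, 2), c(NA, 1)))
  expect_equal(gt$individuals$sex, c("M", "F", "M"))
  writeLines(c("F1 i1 0 0 1 -9 A A"), file.path(dir, "bad.ped"))
  writeLines(c("1 2 0 4", "1 5 0 9"), file.path(dir, "bad.map"))
  expect_error(read_genotypes(file.path(dir, "bad"), "plink-text"),
               "line 1")
})

test_that("QC thresholds are strict and applied in the documented order", {
  # one heterozygote among 10 individuals: MAF exactly 0.05 -> removed
  d <- cbind(c(1, rep(0, 9)), rep(c(0, 2), 5))
  gt <- mk_gt(d)
  kept <- filter_genotypes(gt, maf_min = 0.05, snp_callrate_min = 0,
                           ind_callrate_min = 0)
  expect_equal(n_snps(kept), 1L)
  expect_equal(kept$snp_map$id, "s2")
  # SNP missing in 2 of 10 individuals: call rate 0.8 -> removed at 0.95
  d2 <- cbind(c(NA, NA, rep(1, 8)), rep(1, 10))
  kept2 <- filter_genotypes(mk_gt(d2), maf_min = 0,
                            snp_callrate_min = 0.95, ind_callrate_min = 0)
  expect_equal(kept2$snp_map$id, "s2")
  # clean panel at MAF 0.5 is untouched
  d3 <- matrix(rep(c(0, 1, 2, 1), 5), 4, 5)
  expect_equal(filter_genotypes(mk_gt(d3))$dosages, mk_gt(d3)$dosages)
  expect_warning(filter_genotypes(mk_gt(matrix(0, 4, 2))), "empty panel")
})

test_that("filter_genotypes is idempotent", {
  set.seed(7)
  d <- matrix(sample(c(0:2, NA), 300, replace = TRUE,
                     prob = c(5, 2, 5, 1)), 20, 15)
  once <- filter_genotypes(mk_gt(d))
  twice <- filter_genotypes(once)
  expect_identical(once$dosages, twice$dosages)
})

test_that("allele frequencies match hand counts and flag empty groups", {
  gt <- mk_gt(cbind(c(0, 0, 0), c(0, 1, 2), c(2, NA, 0)))
  af <- allele_frequencies(gt, rep("P", 3))
  expect_equal(unname(af$freq[, "P"]), c(0, 0.5, 0.5))
  expect_equal(unname(af$counts[, "P"]), c(6, 6, 4))
  # a population with no calls at a SNP is flagged missing
  af2 <- allele_frequencies(mk_gt(rbind(NA_real_, 2)), c("A", "B"))
  expect_true(is.na(af2$freq["s1", "A"]))
  expect_equal(unname(af2$freq["s1", "B"]), 1)
  expect_error(allele_frequencies(gt, c("A", "B")), "exactly one")
})

test_that("allele frequencies are order-invariant and flip under relabeling", {
  set.seed(11)
  d <- matrix(sample(0:2, 80, TRUE), 8, 10)
  gt <- mk_gt(d, line = rep(c("A", "B"), 4))
  af <- allele_frequencies(gt)
  perm <- sample(8)
  af_perm <- allele_frequencies(subset_genotypes(gt, individuals = perm))
  expect_equal(af$freq, af_perm$freq)
  flipped <- allele_frequencies(mk_gt(2 - d, line = rep(c("A", "B"), 4)))
  expect_equal(flipped$freq, 1 - af$freq)
})
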