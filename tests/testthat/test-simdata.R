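# Breeding-scheme simulator: founders, architecture, selection response.

test_that("founder haplotypes are mosaics of the ancestral pool", {
  # no switching: every founder haplotype equals one pool member
  f <- simulate_founders(n_ind = 20, n_snp = 40, n_chr = 1,
                         n_ancestral_haplotypes = 2,
                         founder_switch_rate = 0, seed = 1)
  h <- attr(f, "haplotypes")
  pool_rows <- unique(rbind(h$h1, h$h2))
  expect_lte(nrow(pool_rows), 2L)
  # strong local LD with a 2-haplotype pool
  f2 <- simulate_founders(n_ind = 80, n_snp = 50, n_chr = 1,
                          n_ancestral_haplotypes = 2, seed = 2)
  tab <- ld_r2(f2, max_distance = 1.2e5, maf_min = 0.05)
  expect_gt(mean(tab$r2), 0.5)
  expect_error(simulate_founders(n_ancestral_haplotypes = 1), ">= 2")
})

test_that("founder allele frequencies track the pool in expectation", {
  set.seed(5)
  f <- simulate_founders(n_ind = 300, n_snp = 100, n_chr = 2, seed = 11)
  h <- attr(f, "haplotypes")
  pool_freq <- colMeans(f$dosages) / 2
  # sanity: frequencies are in (0,1) and not degenerate on average
  expect_true(mean(pool_freq > 0.05 & pool_freq < 0.95) > 0.8)
})

test_that("architecture hits target heritabilities and correlations", {
  f <- simulate_founders(n_ind = 1000, n_snp = 300, n_chr = 3, seed = 13)
  arch <- simulate_architecture(f, n_qtl = 60, h2 = c(0.4, 0.3), rg = 0.54,
                                seed = 17)
  bv <- draw_phenotypes(arch, f$dosages)$bv
  # realised founder h2 (phenotypic variance normalised to 1)
  expect_equal(var(bv[, 1]) / (var(bv[, 1]) + arch$ve[1]), 0.4,
               tolerance = 0.02)
  expect_equal(var(bv[, 2]) / (var(bv[, 2]) + arch$ve[2]), 0.3,
               tolerance = 0.02)
  expect_lt(abs(cor(bv[, 1], bv[, 2]) - 0.54), 0.1)
  # rg = 1 makes trait-2 effects proportional to trait-1 effects
  arch1 <- simulate_architecture(f, n_qtl = 20, h2 = c(0.4, 0.4), rg = 1,
                                 seed = 19)
  ratio <- arch1$qtl$effect2 / arch1$qtl$effect1
  expect_lt(diff(range(ratio)), 1e-8)
  # not enough polymorphic SNPs is an error
  mono <- mk_gt(matrix(2, 10, 5))
  expect_error(simulate_architecture(mono, n_qtl = 3, seed = 1),
               "polymorphic")
})

small_design <- function(gens = 2) {
  breeding_design(generations = gens, n_founders = 80,
                  offspring_per_line = 60, n_genotyped_sires_g0 = 20,
                  n_genotyped_sires = 5, g6_males = 30, g6_females = 30)
}

test_that("selection produces divergence; no heritability produces none", {
  f <- simulate_founders(n_ind = 80, n_snp = 120, n_chr = 2, seed = 23)
  des <- small_design(3)
  arch <- simulate_architecture(f, n_qtl = 20, h2 = c(0.45, 0.45),
                                rg = 0.54, large_qtl_var = 0.1, seed = 29)
  exp1 <- run_breeding_experiment(f, arch, des, seed = 31)
  lm <- exp1$truth$line_means
  gap <- function(g) lm[sprintf("G%d_pHu+", g), 1] -
    lm[sprintf("G%d_pHu-", g), 1]
  gaps <- vapply(1:4, gap, numeric(1))
  expect_gt(gaps[4], 0.3) # clear divergence after selection
  expect_gt(gaps[4], gaps[1])
  # the large QTL diverges in frequency between lines
  q1 <- arch$qtl$snp_index[1]
  fq <- exp1$truth$freq
  expect_gt(abs(fq["G3_pHu+", q1] - fq["G3_pHu-", q1]), 0.05)
  # flat trait: drift only
  arch0 <- simulate_architecture(f, n_qtl = 20, h2 = c(0, 0), rg = 0.54,
                                 seed = 37)
  exp0 <- run_breeding_experiment(f, arch0, des, seed = 41)
  lm0 <- exp0$truth$line_means
  expect_lt(abs(lm0["G3_pHu+", 1] - lm0["G3_pHu-", 1]), 0.3)
})

test_that("neutral frequency drift is consistent with the design's Ne", {
  f <- simulate_founders(n_ind = 80, n_snp = 200, n_chr = 2, seed = 43)
  arch0 <- simulate_architecture(f, n_qtl = 10, h2 = c(0, 0), rg = 0,
                                 seed = 47)
  des <- small_design(3)
  exp0 <- run_breeding_experiment(f, arch0, des, seed = 53)
  fq <- exp0$truth$freq
  p0 <- fq["G0", ]
  ok <- p0 > 0.2 & p0 < 0.8
  dvar <- var((fq["G3_pHu-", ok] - p0[ok]) /
                sqrt(p0[ok] * (1 - p0[ok])))
  ne <- 4 * des$n_sires * des$n_dams / (des$n_sires + des$n_dams)
  pred <- inbreeding_from_ne(ne, 3)
  # loose Monte-Carlo band: drift variance within a factor ~2 of the
  # idealised prediction (family structure inflates it slightly)
  expect_gt(dvar, pred * 0.5)
  expect_lt(dvar, pred * 2.5)
})

test_that("the experiment is deterministic and exports round-trip", {
  f <- simulate_founders(n_ind = 60, n_snp = 60, n_chr = 2, seed = 59)
  arch <- simulate_architecture(f, n_qtl = 10, h2 = c(0.4, 0.4), rg = 0.5,
                                seed = 61)
  des <- small_design(2)
  e1 <- run_breeding_experiment(f, arch, des, seed = 67)
  e2 <- run_breeding_experiment(f, arch, des, seed = 67)
  expect_identical(e1$genotypes$G6$dosages, e2$genotypes$G6$dosages)
  expect_identical(e1$phenotypes, e2$phenotypes)
  # layout export and round trip
  dir <- withr::local_tempdir()
  export_study_layout(e1, dir)
  back <- read_genotypes(file.path(dir, "G6"), "plink-text")
  expect_equal(unname(back$dosages), unname(e1$genotypes$G6$dosages))
  ph <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  expect_equal(nrow(ph), 60)
  expect_equal(sum(ph$sex == "M"), 30)
  expect_equal(sum(ph$sex == "F"), 30)
  truth <- read.table(file.path(dir, "truth_qtl.tsv"), header = TRUE)
  expect_true(all(truth$snp %in% e1$snp_map$id))
  # cohorts for the scans exist with the right groups
  co <- scan_cohort(e1, 2)
  expect_setequal(unique(co$individuals$line), c("G0", "pHu-", "pHu+"))
  expect_error(scan_cohort(e1, 5), "not present")
})
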