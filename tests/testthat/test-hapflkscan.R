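# hapFLK statistic, robust normal null, scan and cross-generation merging.

kin2 <- mk_kinship_diag(0.08, 0.08)

test_that("hapflk_statistic sums per-cluster FLK terms", {
  cf <- rbind(A = c(0.4, 0.6), B = c(0.4, 0.6))
  expect_equal(hapflk_statistic(cf, c(0.4, 0.6), kin2), 0)
  # one population, F = 0.08: clusters (0.6 | 0.5) and (0.4 | 0.5) -> 0.5+0.5
  kin1 <- kin2
  kin1$F <- kin1$F[c("G0", "A"), c("G0", "A")]
  kin1$populations <- c("G0", "A")
  cf1 <- rbind(A = c(0.6, 0.4))
  expect_equal(hapflk_statistic(cf1, c(0.5, 0.5), kin1), 1.0)
  # permuting cluster labels leaves the statistic unchanged
  cf2 <- rbind(A = c(0.7, 0.2, 0.1), B = c(0.3, 0.5, 0.2))
  p0 <- c(0.5, 0.3, 0.2)
  perm <- c(3, 1, 2)
  expect_equal(hapflk_statistic(cf2, p0, kin2),
               hapflk_statistic(cf2[, perm], p0[perm], kin2))
  # cluster absent from the outgroup contributes nothing
  expect_equal(hapflk_statistic(cbind(cf2, c(0.0, 0.0)), c(p0, 0), kin2),
               hapflk_statistic(cf2, p0, kin2))
})

test_that("fit_null_normal recovers location/scale robustly", {
  set.seed(43)
  x <- rnorm(10000, mean = 3, sd = 1)
  fit <- fit_null_normal(x)
  expect_equal(fit$location, 3, tolerance = 0.02)
  expect_equal(fit$scale, 1, tolerance = 0.02)
  # 1% contamination far in the upper tail barely moves the fit
  x2 <- x; x2[1:100] <- 50
  fit2 <- fit_null_normal(x2)
  expect_lt(abs(fit2$location - fit$location) / fit$location, 0.01)
  expect_lt(abs(fit2$scale - fit$scale) / fit$scale, 0.015)
  # standard normal sample -> approximately uniform p-values
  z <- rnorm(5000)
  pv <- hapflk_pvalues(fit_null_normal(z), z)
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
  expect_error(fit_null_normal(rep(1, 200)), "degenerate")
  expect_error(fit_null_normal(rnorm(50)), ">= 100")
})

test_that("hapFLK with K = 1 is zero everywhere", {
  set.seed(47)
  gt <- mk_gt(matrix(sample(0:2, 300, TRUE), 15, 20),
              line = rep(c("G0", "A", "B"), each = 5))
  fit <- fit_cluster_model(gt, K = 1, n_em_runs = 1, max_iter = 5, seed = 1)
  cf <- cluster_frequencies(fit)
  stats <- vapply(1:20, function(l) {
    hapflk_statistic(rbind(A = cf["A", l, ], B = cf["B", l, ]),
                     cf["G0", l, ], kin2)
  }, numeric(1))
  expect_equal(stats, rep(0, 20))
})

test_that("merge_generation_regions unions overlapping/contiguous signals", {
  map <- data.frame(id = paste0("s", 1:8), chr = "1",
                    bp = c(1e6, 1.5e6, 2e6, 2.5e6, 3e6, 6e6, 7e6, 8e6))
  r1 <- genomic_regions(chr = "1", start = 1e6, end = 2e6, score = 5,
                        peak_snp = "s1")
  r4 <- genomic_regions(chr = "1", start = 1.5e6, end = 3e6, score = 7,
                        peak_snp = "s5")
  merged <- merge_generation_regions(list(`1` = r1, `4` = r4), map)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 1e6)
  expect_equal(merged$end, 3e6)
  expect_equal(merged$generations, "1/4")
  expect_equal(merged$score, 7)
  # single region unchanged
  single <- merge_generation_regions(list(`2` = r1), map)
  expect_equal(single$start, 1e6)
  expect_equal(single$generations, "2")
  # abutting regions with no genotyped SNP in the gap are merged
  rA <- genomic_regions(chr = "1", start = 1e6, end = 3e6, score = 5)
  rB <- genomic_regions(chr = "1", start = 4e6, end = 6e6, score = 6)
  expect_equal(nrow(merge_generation_regions(list(`1` = rA, `2` = rB), map)),
               1L)
  # disjoint regions separated by a genotyped SNP stay apart
  rC <- genomic_regions(chr = "1", start = 7.5e6, end = 8e6, score = 6)
  expect_equal(nrow(merge_generation_regions(list(`1` = rA, `2` = rC), map)),
               2L)
  # idempotent and associative over generation lists
  m1 <- merge_generation_regions(list(`1` = rA, `2` = rB, `3` = rC), map)
  again <- merge_generation_regions(list(`1/2` = m1), map)
  expect_equal(again$start, m1$start)
  expect_equal(again$end, m1$end)
  expect_equal(nrow(merge_generation_regions(list(), map)), 0L)
})

test_that("region_report produces the reporting schema", {
  map <- data.frame(id = paste0("s", 1:3), chr = "1",
                    bp = c(1e6, 2e6, 3e6))
  reg <- genomic_regions(chr = c("1", "1"), start = c(1e6, 3e6),
                         end = c(2e6, 3e6), score = c(5.2, 3.1),
                         generations = c("1/2", "5"))
  rep <- region_report(reg, map, prefix = "hapFLK")
  expect_equal(rep$name, c("hapFLK-1a", "hapFLK-1b"))
  expect_equal(rep$marker_start, c("s1", "s3"))
  expect_equal(rep$marker_end, c("s2", "s3"))
  expect_equal(rep$length_mb, c(1, 0))
})
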