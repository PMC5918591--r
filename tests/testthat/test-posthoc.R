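# LD summaries, enrichment test and region intersection.

test_that("ld_r2 matches direct correlation and honours filters", {
  set.seed(71)
  x <- sample(0:2, 30, TRUE)
  d <- cbind(x, x, sample(0:2, 30, TRUE))
  gt <- mk_gt(d, bp = c(1e5, 2e5, 3e5))
  tab <- ld_r2(gt, max_distance = 5e5, maf_min = 0)
  dup <- tab[tab$snpA == "s1" & tab$snpB == "s2", ]
  expect_equal(dup$r2, 1)
  # 6-individual hand-computable pair
  a <- c(0, 1, 2, 2, 1, 0); b <- c(0, 0, 2, 2, 2, 0)
  tab2 <- ld_r2(mk_gt(cbind(a, b), bp = c(1e5, 2e5)), maf_min = 0)
  expect_equal(tab2$r2, cor(a, b)^2)
  # distance filter is strict
  far <- ld_r2(mk_gt(cbind(a, b), bp = c(1e5, 6e5)), maf_min = 0)
  expect_equal(nrow(far), 0L)
  # MAF filter is strict (> 0.1)
  rare <- cbind(c(1, rep(0, 9)), c(1, rep(0, 9))) # MAF 0.05
  expect_equal(nrow(ld_r2(mk_gt(rare), maf_min = 0.1)), 0L)
  # zero-variance columns are skipped
  cst <- cbind(rep(1, 10), sample(0:2, 10, TRUE))
  expect_equal(nrow(ld_r2(mk_gt(cst), maf_min = 0)), 0L)
})

test_that("r2 is symmetric in the pair and allele relabeling", {
  set.seed(73)
  a <- sample(0:2, 40, TRUE); b <- sample(0:2, 40, TRUE)
  t1 <- ld_r2(mk_gt(cbind(a, b), bp = c(1e5, 2e5)), maf_min = 0)
  t2 <- ld_r2(mk_gt(cbind(b, a), bp = c(1e5, 2e5)), maf_min = 0)
  t3 <- ld_r2(mk_gt(cbind(2 - a, b), bp = c(1e5, 2e5)), maf_min = 0)
  expect_equal(t1$r2, t2$r2)
  expect_equal(t1$r2, t3$r2)
})

test_that("independent SNPs have near-zero mean r2", {
  set.seed(79)
  n <- 400
  d <- matrix(rbinom(n * 30, 2, 0.5), n, 30)
  tab <- ld_r2(mk_gt(d, bp = seq_len(30) * 1e4), maf_min = 0)
  expect_lt(mean(tab$r2), 0.01)
})

test_that("region_mean_r2 pools pairs per category", {
  pairs <- data.frame(snpA = c("a", "b", "c"), snpB = c("b", "c", "d"),
                      chr = "1", bpA = c(1e6, 2e6, 8e6),
                      bpB = c(2e6, 2.5e6, 8.5e6),
                      distance = c(1e6, 5e5, 5e5), r2 = c(0.2, 0.4, 0.9))
  # one region covering everything equals the global mean
  all_reg <- genomic_regions(chr = "1", start = 1, end = 1e7)
  res <- region_mean_r2(pairs, all_reg)
  expect_equal(res$mean_r2[res$category == "regions"],
               res$mean_r2[res$category == "genome-wide"])
  # two disjoint categories with hand-computed means
  reg2 <- genomic_regions(chr = c("1", "1"), start = c(1, 7e6),
                          end = c(3e6, 9e6))
  reg2$category <- c("left", "right")
  res2 <- region_mean_r2(pairs, reg2)
  expect_equal(res2$mean_r2[res2$category == "left"], 0.3)
  expect_equal(res2$mean_r2[res2$category == "right"], 0.9)
  # genome-wide only when no region is given
  expect_equal(nrow(region_mean_r2(pairs, NULL)), 1L)
  # empty category flagged by zero pairs
  far_reg <- genomic_regions(chr = "2", start = 1, end = 2)
  res3 <- region_mean_r2(pairs, far_reg)
  expect_equal(res3$n_pairs[2], 0L)
  expect_true(is.na(res3$mean_r2[2]))
})

test_that("enrichment_test matches the hand Welch formulas", {
  same <- enrichment_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  et <- enrichment_test(x, y)
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(et$t, t_hand)
  expect_equal(et$df, df_hand)
  expect_equal(et$p_value, 2 * pt(-abs(t_hand), df_hand))
  expect_error(enrichment_test(c(1, 1), c(2, 2)), "degenerate")
})

test_that("enrichment p-values are uniform under label permutation", {
  set.seed(83)
  bf <- rexp(300)
  pv <- replicate(400, {
    lab <- sample(rep(c(TRUE, FALSE), c(30, 270)))
    enrichment_test(bf[lab], bf[!lab])$p_value
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("enrichment has power against a shifted inside group", {
  set.seed(89)
  hits <- 0L
  for (r in 1:20) {
    inside <- rexp(200) + 10
    outside <- rexp(2000)
    if (enrichment_test(inside, outside)$p_value < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("intersect_regions uses closed intervals", {
  qtl <- genomic_regions(chr = c("1", "1", "2"),
                         start = c(24.8e6, 50e6, 1e6),
                         end = c(26.9e6, 51e6, 2e6),
                         name = c("PM-1a", "PM-1b", "PM-2a"))
  sigs <- genomic_regions(chr = c("1", "2"), start = c(18.76e6, 2e6),
                          end = c(29.76e6, 3e6),
                          name = c("hapFLK-1c", "hapFLK-2a"))
  ov <- intersect_regions(qtl, sigs)
  expect_equal(unname(ov["PM-1a"]), "hapFLK-1c")
  expect_equal(unname(ov["PM-1b"]), "-")
  # touching endpoints (closed intervals) count as overlap
  expect_equal(unname(ov["PM-2a"]), "hapFLK-2a")
})
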