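# Haplotype-cluster HMM: EM fitting, posteriors, K selection.

test_that("forward likelihood matches brute-force path enumeration", {
  set.seed(17)
  for (case in 1:4) {
    K <- sample(2:3, 1); L <- sample(2:4, 1); n <- 2
    theta <- matrix(runif(L * K, .1, .9), L, K)
    alpha <- matrix(rexp(L * K), L, K); alpha <- alpha / rowSums(alpha)
    rho <- runif(L, .1, .6)
    chr_start <- c(TRUE, sample(c(TRUE, FALSE), L - 1, TRUE, c(.3, .7)))
    geno <- matrix(sample(c(0:2, -1L), n * L, TRUE), n, L)
    est <- divscan:::.hmm_estep(geno, theta, alpha, rho, chr_start, TRUE)
    expect_equal(est$loglik,
                 brute_hmm_loglik(geno, theta, alpha, rho, chr_start),
                 tolerance = 1e-10)
    # posteriors: expected haplotypes per cluster sum to 2 at every locus
    post <- array(est$post, c(n, L, K))
    expect_equal(apply(post, c(1, 2), sum),
                 matrix(2, n, L), tolerance = 1e-8)
  }
})

test_that("EM log-likelihood is non-decreasing and improves with restarts", {
  set.seed(23)
  gt <- two_hap_fixture(n_ind = 25, n_snp = 12, fA = 0.6)
  fit <- fit_cluster_model(gt, K = 2, n_em_runs = 2, max_iter = 40, seed = 1)
  for (r in seq_along(fit$runs)) {
    expect_true(all(diff(fit$runs[[r]]$loglik_trace) > -1e-6))
  }
  # same seed: the first run of a larger restart set is identical, so the
  # best log-likelihood can only improve
  fit1 <- fit_cluster_model(gt, K = 2, n_em_runs = 1, max_iter = 40, seed = 9)
  fit3 <- fit_cluster_model(gt, K = 2, n_em_runs = 3, max_iter = 40, seed = 9)
  expect_gte(logLik(fit3), logLik(fit1) - 1e-9)
})

test_that("two repeated haplotypes are recovered within 0.02", {
  set.seed(29)
  gt <- two_hap_fixture(n_ind = 40, n_snp = 20, fA = 0.6)
  fit <- fit_cluster_model(gt, K = 2, n_em_runs = 3, max_iter = 80, seed = 2)
  cf <- cluster_frequencies(fit, grouping = rep("P", 40))
  freqs <- cf["P", , ] # loci x 2 clusters
  # one cluster tracks haplotype A (frequency 0.6), the other 0.4
  hi <- pmax(freqs[, 1], freqs[, 2])
  expect_true(all(abs(hi - 0.6) < 0.02))
})

test_that("K = 1 yields a single always-on cluster", {
  set.seed(31)
  gt <- mk_gt(matrix(sample(0:2, 60, TRUE), 6, 10))
  fit <- fit_cluster_model(gt, K = 1, n_em_runs = 1, max_iter = 10, seed = 1)
  cf <- cluster_frequencies(fit, grouping = rep("P", 6))
  expect_equal(unname(cf["P", , 1]), rep(1, 10))
})

test_that("disjoint fixed haplotypes give near-degenerate frequencies", {
  hapA <- rep_len(c(1L, 0L), 16); hapB <- 1L - hapA
  d <- rbind(matrix(hapA * 2, 12, 16, byrow = TRUE),
             matrix(hapB * 2, 12, 16, byrow = TRUE))
  gt <- mk_gt(d)
  fit <- fit_cluster_model(gt, K = 2, n_em_runs = 3, max_iter = 60, seed = 3)
  cf <- cluster_frequencies(fit, grouping = rep(c("P1", "P2"), each = 12))
  expect_true(all(abs(apply(cf["P1", , ], 1, max) - 1) < 0.02))
  expect_true(all(abs(apply(cf["P2", , ], 1, max) - 1) < 0.02))
  # the populations use opposite clusters
  expect_lt(max(abs(cf["P1", , ] + cf["P2", , ] - 1)), 0.04)
  # unknown individual in the grouping is an error
  expect_error(cluster_frequencies(fit, c(zzz = "P1")), "unknown")
})

test_that("select_K picks the truth on a two-haplotype fixture", {
  set.seed(37)
  gt <- two_hap_fixture(n_ind = 40, n_snp = 16, fA = 0.5)
  expect_equal(select_K(gt, c(1, 2), folds = 2, seed = 4), 2L)
  expect_equal(select_K(gt, 4, seed = 1), 4L)
  expect_equal(select_K(gt, c(2, 1), folds = 2, seed = 4),
               select_K(gt, c(1, 2), folds = 2, seed = 4))
})

test_that("degenerate K > #haplotypes still converges (empty clusters)", {
  set.seed(41)
  gt <- two_hap_fixture(n_ind = 15, n_snp = 8, fA = 0.5)
  fit <- fit_cluster_model(gt, K = 4, n_em_runs = 1, max_iter = 40, seed = 5)
  expect_true(is.finite(logLik(fit)))
  cf <- cluster_frequencies(fit, grouping = rep("P", 15))
  expect_equal(unname(rowSums(cf["P", , ])), rep(1, 8), tolerance = 1e-6)
})
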