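# Bayes C-pi machinery: pre-correction, priors, Gibbs sampler, Bayes
# factors, regions. The heavy power/null simulations live in
# test-acceptance.R.

test_that("precorrect_phenotypes removes fixed effects exactly", {
  y <- c(5, 5, 5, 5)
  expect_equal(precorrect_phenotypes(y, data.frame(sex = rep("M", 4))),
               y - mean(y))
  # balanced two-sex design with +1/-1 effects on a constant base
  y2 <- c(6, 4, 6, 4)
  res <- precorrect_phenotypes(y2, data.frame(sex = c("M", "F", "M", "F")))
  expect_equal(res, rep(0, 4))
  # idempotence
  set.seed(53)
  y3 <- rnorm(30)
  cov <- data.frame(sex = rep_len(c("M", "F"), 30),
                    hatch = rep_len(1:3, 30))
  once <- precorrect_phenotypes(y3, cov)
  expect_equal(precorrect_phenotypes(once, cov), once, tolerance = 1e-10)
  # confounded covariates are an error
  expect_error(
    precorrect_phenotypes(y3, data.frame(a = rep_len(c("x", "y"), 30),
                                         b = rep_len(c("u", "v"), 30))),
    "singular")
})

test_that("prior scale follows S2 = sigma2 (nu - 2) / nu", {
  expect_equal(prior_scale(2, 4.2), 2 * 2.2 / 4.2)
  expect_equal(prior_scale(2, 4.2), 1.047619, tolerance = 1e-6)
  expect_error(prior_spec(nu = 2), "nu > 2")
})

test_that("bayes_factor matches the odds-ratio arithmetic", {
  expect_equal(bayes_factor(0.005, 0.005), 1)
  expect_equal(bayes_factor(0.5, 0.005), 199)
  q <- seq(0.01, 0.9, by = 0.01)
  expect_true(all(diff(bayes_factor(q, 0.005)) > 0)) # monotone in q
  expect_equal(as.character(bf_class(c(1, 10, 100, 200))),
               c("none", "suggestive", "strong", "very strong"))
})

test_that("build_qtl_regions merges and flanks", {
  res <- data.frame(snp = c("a", "b", "c"), chr = "1",
                    bp = c(5e6, 5.8e6, 20e6), bf = c(25, 30, 5))
  # single significant SNP at 5 Mb with 1 Mb flanks -> [4, 6] Mb
  one <- build_qtl_regions(res[c(1, 3), ], bf_threshold = 20)
  expect_equal(one$start, 4e6)
  expect_equal(one$end, 6e6)
  # two SNPs 0.8 Mb apart merge, then flank
  two <- build_qtl_regions(res, bf_threshold = 20)
  expect_equal(nrow(two), 1L)
  expect_equal(two$start, 4e6)
  expect_equal(two$end, 6.8e6)
  expect_equal(two$peak_snp, "b")
  # clipping at position 1 and chromosome length
  near0 <- data.frame(snp = "a", chr = "1", bp = 5e5, bf = 50)
  clipped <- build_qtl_regions(near0, chr_lengths = c(`1` = 1e6))
  expect_equal(clipped$start, 1)
  expect_equal(clipped$end, 1e6)
  expect_equal(nrow(build_qtl_regions(res, bf_threshold = 100)), 0L)
})

test_that("conjugate special case matches the closed-form posterior", {
  # pi fixed at 1, one centred predictor, fixed variances: the posterior of
  # the effect is N(x'y / (x'x + s2e/s2a), ...)
  set.seed(59)
  n <- 150
  x <- round(runif(n) * 2)
  y <- 0.6 * (x - mean(x)) + rnorm(n)
  gt <- mk_gt(matrix(x, n, 1))
  fit <- run_bayescpi(y, gt,
                      priors = prior_spec(sigma2_a_prior = 1,
                                          sigma2_e_prior = 1),
                      mcmc = mcmc_spec(6000, 1000, 5, seed = 2),
                      pi_fixed = 1, update_variances = FALSE)
  xc <- x - mean(x)
  closed <- sum(xc * y) / (sum(xc^2) + 1)
  mc_se <- 3 * sqrt(1 / (sum(xc^2) + 1)) / sqrt(fit$pip[1] * 500)
  expect_equal(fit$effect[1], closed, tolerance = 0.05)
  expect_equal(fit$pip[1], 1, tolerance = 1e-3)
})

test_that("chains are reproducible and within their support", {
  set.seed(61)
  n <- 60; M <- 30
  gt <- mk_gt(matrix(sample(0:2, n * M, TRUE), n, M))
  y <- rnorm(n)
  f1 <- run_bayescpi(y, gt, mcmc = mcmc_spec(2000, 400, 4, seed = 77))
  f2 <- run_bayescpi(y, gt, mcmc = mcmc_spec(2000, 400, 4, seed = 77))
  expect_identical(f1$bf, f2$bf)
  ch <- attr(f1, "chains")
  expect_true(all(ch$pi >= 0 & ch$pi <= 1))
  expect_true(all(ch$sigma2_a > 0) && all(ch$sigma2_e > 0))
  expect_true(all(f1$pip >= 0 & f1$pip <= 1))
  expect_true(all(f1$bf >= 0))
})

test_that("missing dosages are mean-imputed, not fatal", {
  set.seed(67)
  d <- matrix(sample(0:2, 40 * 10, TRUE), 40, 10)
  d[sample(length(d), 30)] <- NA
  fit <- run_bayescpi(rnorm(40), mk_gt(d),
                      mcmc = mcmc_spec(1000, 200, 2, seed = 3))
  expect_true(all(is.finite(fit$bf)))
})
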