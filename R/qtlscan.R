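## Bayes C-pi multi-marker association mapping: mixture-prior Gibbs sampling,
## Bayes factors from the prior-to-posterior inclusion odds, and QTL region
## construction with flanking.

#' Prior specification for the Bayes C-pi model
#'
#' The inclusion probability pi gets a Beta(alpha, beta) prior (the default,
#' alpha = 0.5e4 and beta = 99.5e4, pins pi near 0.005); the marker-effect
#' and residual variances get scaled inverse chi-squared priors with `nu`
#' degrees of freedom and scale `S2 = sigma2_hat (nu - 2) / nu` where
#' `sigma2_hat` is the prior point value of the variance.
#'
#' @param pi_alpha,pi_beta Beta prior parameters for pi
#' @param nu degrees of freedom of the variance priors (> 2)
#' @param sigma2_a_prior,sigma2_e_prior prior point values of the marker and
#'   residual variances; `NULL` defers to data-driven defaults at run time
#'   (half the phenotypic variance for the residual, and the remaining half
#'   spread over all markers for the per-effect variance).
#' @return a `prior_spec`.
#' @export
prior_spec <- function(pi_alpha = 0.5e4, pi_beta = 99.5e4, nu = 4.2,
                       sigma2_a_prior = NULL, sigma2_e_prior = NULL) {
  stopifnot(pi_alpha > 0, pi_beta > 0, nu > 2)
  structure(list(pi_alpha = pi_alpha, pi_beta = pi_beta, nu = nu,
                 sigma2_a_prior = sigma2_a_prior,
                 sigma2_e_prior = sigma2_e_prior),
            class = "prior_spec")
}

#' Scale parameter of the scaled inverse chi-squared prior
#'
#' `S2 = sigma2_hat * (nu - 2) / nu`, so that the prior mode/mean matches the
#' supplied point value.
#'
#' @param sigma2_hat prior point value of the variance
#' @param nu degrees of freedom (> 2)
#' @return the prior scale S2.
#' @export
prior_scale <- function(sigma2_hat, nu) {
  stopifnot(nu > 2)
  sigma2_hat * (nu - 2) / nu
}

#' MCMC schedule
#'
#' Default is a 10x scaled-down version of a production schedule
#' (40,000 iterations, 8,000 burn-in, thin 40); scale up for final scans.
#'
#' @param n_iter total Gibbs iterations
#' @param burn_in burn-in iterations (< n_iter)
#' @param thin thinning interval (>= 1)
#' @param seed RNG seed
#' @return an `mcmc_spec`.
#' @export
mcmc_spec <- function(n_iter = 40000, burn_in = 8000, thin = 40,
                      seed = NULL) {
  stopifnot(burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed),
            class = "mcmc_spec")
}

#' Pre-correct phenotypes for fixed effects
#'
#' Residuals of an ordinary least-squares fit of the trait on the categorical
#' covariates (sex, hatch, optionally line), re-centred to mean zero.
#' Constant covariates are dropped; a singular (confounded) design is an
#' error.
#'
#' @param y trait values
#' @param covariates data.frame of categorical covariates (same row count)
#' @return adjusted trait values.
#' @export
precorrect_phenotypes <- function(y, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(y))
  keep <- vapply(covariates, function(v) length(unique(v)) > 1L, logical(1))
  if (!any(keep)) return(y - mean(y))
  covariates <- covariates[, keep, drop = FALSE]
  covariates[] <- lapply(covariates, factor)
  mm <- stats::model.matrix(~ ., data = covariates)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) stop("confounded covariates: singular design")
  res <- stats::lm.fit(mm, y)$residuals
  res - mean(res)
}

#' Run the Bayes C-pi Gibbs sampler
#'
#' Single-site Gibbs updates of (inclusion indicator, effect) per SNP, then
#' the overall mean, the two variances (scaled inverse chi-squared full
#' conditionals) and pi (Beta full conditional). Missing dosages are
#' mean-imputed per SNP and dosage columns are centred before sampling.
#'
#' @param y adjusted trait values (see [precorrect_phenotypes()])
#' @param gt a `genotype_table` for the same individuals, in the same order
#' @param priors a [prior_spec()]
#' @param mcmc an [mcmc_spec()]
#' @param pi_fixed optional: hold pi fixed at this value instead of sampling
#' @param update_variances set `FALSE` to hold the variances at their prior
#'   point values (used for conjugate validation)
#' @return a `qtl_scan_result`: data.frame (snp, chr, bp, pip, bf, effect)
#'   with chains for mu, pi, sigma2_a, sigma2_e and the model size in
#'   attribute `chains`. The posterior inclusion probability is smoothed as
#'   `(count + 0.5) / (S + 1)` over the S retained samples before computing
#'   Bayes factors, so BF is always finite.
#' @export
run_bayescpi <- function(y, gt, priors = prior_spec(), mcmc = mcmc_spec(),
                         pi_fixed = NULL, update_variances = TRUE) {
  stopifnot(inherits(priors, "prior_spec"), inherits(mcmc, "mcmc_spec"))
  X <- gt$dosages
  stopifnot(nrow(X) == length(y))
  # mean-impute missing dosages per SNP, then centre
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  na_idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na_idx)) X[na_idx] <- cm[na_idx[, 2L]]
  X <- sweep(X, 2L, colMeans(X))
  M <- ncol(X)
  pi_mean <- priors$pi_alpha / (priors$pi_alpha + priors$pi_beta)
  vy <- var(y)
  s2e_hat <- if (is.null(priors$sigma2_e_prior)) vy / 2 else
    priors$sigma2_e_prior
  s2a_hat <- if (is.null(priors$sigma2_a_prior)) {
    # half the phenotypic variance treated as genetic and spread over all
    # markers: sigma2_a = Vg / (M * mean 2pq). Dividing by the expected
    # number of *included* markers instead (the pi-scaled convention) makes
    # the spike-and-slab prior so diffuse that chance correlations reach
    # large Bayes factors under a pure-noise trait.
    mean_2pq <- mean(apply(X, 2L, var))
    (vy / 2) / max(M * max(mean_2pq, 1e-8), 1e-8)
  } else priors$sigma2_a_prior
  S2a <- prior_scale(s2a_hat, priors$nu)
  S2e <- prior_scale(s2e_hat, priors$nu)
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  fit <- .bayescpi_gibbs(as.numeric(y), X, priors$pi_alpha, priors$pi_beta,
                         priors$nu, S2a, S2e, mcmc$n_iter, mcmc$burn_in,
                         mcmc$thin,
                         if (is.null(pi_fixed)) -1 else pi_fixed,
                         update_variances, s2a_hat, s2e_hat)
  S <- fit$n_kept
  if (S < 1L) stop("zero retained samples")
  pip <- (fit$incl_count + 0.5) / (S + 1)
  prior_pi <- if (is.null(pi_fixed)) pi_mean else pi_fixed
  # guard the prior odds for degenerate pi (e.g. pi fixed at 1 in validation)
  prior_pi <- min(max(prior_pi, 1e-12), 1 - 1e-12)
  bf <- bayes_factor(pip, prior_pi)
  out <- data.frame(snp = gt$snp_map$id, chr = gt$snp_map$chr,
                    bp = gt$snp_map$bp, pip = pip, bf = bf,
                    effect = fit$a_sum / S, stringsAsFactors = FALSE)
  structure(out, class = c("qtl_scan_result", "data.frame"),
            chains = data.frame(mu = fit$mu, pi = fit$pi,
                                sigma2_a = fit$sigma2_a,
                                sigma2_e = fit$sigma2_e, m_in = fit$m_in),
            prior_pi = prior_pi, n_kept = S)
}

#' @export
print.qtl_scan_result <- function(x, ...) {
  cat("Bayes C-pi scan:", nrow(x), "SNPs;", sum(x$bf >= 20),
      "with BF >= 20 (max BF =", format(max(x$bf), digits = 4), ")\n")
  invisible(x)
}

#' Bayes factor from posterior and prior inclusion probabilities
#'
#' `BF = [q / (1 - q)] / [pi / (1 - pi)]`: the increase from prior to
#' posterior odds of the SNP being in the model. BF in [20, 150] is labelled
#' strong evidence, BF > 150 very strong (see [bf_class()]).
#'
#' @param posterior_inclusion posterior inclusion probability q in [0, 1)
#' @param prior_pi prior inclusion probability in (0, 1)
#' @return the Bayes factor (vectorised).
#' @export
bayes_factor <- function(posterior_inclusion, prior_pi) {
  stopifnot(all(posterior_inclusion >= 0), all(posterior_inclusion <= 1),
            all(prior_pi > 0), all(prior_pi < 1))
  (posterior_inclusion / (1 - posterior_inclusion)) /
    (prior_pi / (1 - prior_pi))
}

#' Evidence class of a Bayes factor
#'
#' @param bf Bayes factor values
#' @return factor with levels none / suggestive / strong / very strong
#'   (cut-offs 3, 20, 150).
#' @export
bf_class <- function(bf) {
  cut(bf, breaks = c(-Inf, 3, 20, 150, Inf),
      labels = c("none", "suggestive", "strong", "very strong"),
      right = FALSE)
}

#' Build QTL regions from a Bayes C-pi scan
#'
#' SNPs with `bf >= bf_threshold` are merged when closer than
#' `merge_distance`; each region is then extended by `flank` on both sides
#' (clipped at position 1 and, when provided, at the chromosome length).
#'
#' @param result a `qtl_scan_result`
#' @param bf_threshold Bayes-factor threshold (default 20, "strong")
#' @param merge_distance merge rule in bp (default 1 Mb, strict `<`)
#' @param flank flanking extension in bp (default 1 Mb)
#' @param chr_lengths optional named vector of chromosome lengths for
#'   clipping
#' @return a `genomic_regions`; `score` is the peak BF.
#' @export
build_qtl_regions <- function(result, bf_threshold = 20, merge_distance = 1e6,
                              flank = 1e6, chr_lengths = NULL) {
  sig <- result$bf >= bf_threshold
  reg <- merge_positions(result$chr[sig], result$bp[sig], result$snp[sig],
                         result$bf[sig], merge_distance)
  if (nrow(reg) == 0L) return(reg)
  reg$start <- pmax(1, reg$start - flank)
  reg$end <- reg$end + flank
  if (!is.null(chr_lengths)) {
    lim <- chr_lengths[reg$chr]
    reg$end <- ifelse(is.na(lim), reg$end, pmin(reg$end, lim))
  }
  reg
}

#' QTL report table
#'
#' One row per significant SNP with its region name, trait, BF from the
#' without-line model and (bracketed in the reference layout) the BF from
#' the with-line model, plus overlapping selection-signature names.
#'
#' @param result `qtl_scan_result` without line effect
#' @param result_line optional `qtl_scan_result` with the line effect
#' @param regions `genomic_regions` from [build_qtl_regions()]
#' @param signatures optional `genomic_regions` of selection signatures
#' @param trait trait label
#' @param bf_threshold report SNPs at or above this BF
#' @return data.frame (region, chr, marker, position, trait, bf, bf_line,
#'   selection_signatures).
#' @export
qtl_report <- function(result, result_line = NULL, regions = NULL,
                       signatures = NULL, trait = "trait",
                       bf_threshold = 20) {
  sig <- which(result$bf >= bf_threshold)
  if (is.null(regions)) regions <- build_qtl_regions(result, bf_threshold)
  region_of <- function(chr, bp) {
    i <- which(regions$chr == chr & regions$start <= bp & regions$end >= bp)
    if (length(i)) regions$name[i[1L]] else NA_character_
  }
  overlap_of <- function(chr, bp) {
    if (is.null(signatures)) return("-")
    i <- which(signatures$chr == chr & signatures$start <= bp &
                 signatures$end >= bp)
    if (length(i)) paste(signatures$name[i], collapse = ",") else "-"
  }
  data.frame(
    region = vapply(sig, function(i) region_of(result$chr[i], result$bp[i]),
                    character(1)),
    chr = result$chr[sig], marker = result$snp[sig],
    position = result$bp[sig], trait = trait,
    bf = round(result$bf[sig], 1),
    bf_line = if (is.null(result_line)) NA_real_ else
      round(result_line$bf[match(result$snp[sig], result_line$snp)], 1),
    selection_signatures = vapply(sig, function(i)
      overlap_of(result$chr[i], result$bp[i]), character(1)),
    stringsAsFactors = FALSE)
}
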