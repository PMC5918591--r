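## Local haplotype-cluster HMM (Scheet-Stephens style) fitted to unphased
## genotypes by EM. Hidden variables are the cluster memberships of the two
## haplotypes of each individual; genotypes are the observations. Used by
## the hapFLK scan through per-population cluster frequencies.

#' Fit the haplotype-cluster HMM by EM
#'
#' Multiple restarts of EM are run from random initialisations (theta uniform
#' in [0.05, 0.95], uniform cluster weights and jump probabilities); each run
#' iterates until the relative log-likelihood change falls below `tol` or
#' `max_iter` iterations. All runs are retained: the hapFLK statistic is
#' averaged over runs, while cluster-frequency displays use the best run.
#'
#' @param gt a `genotype_table` (>= 1 SNP per chromosome); missing dosages
#'   are handled by the emission model.
#' @param K number of haplotype clusters (>= 1); empty clusters are allowed.
#' @param n_em_runs number of EM restarts (default 3; use more, e.g. 50, for
#'   production scans)
#' @param max_iter maximum EM iterations per run
#' @param seed RNG seed
#' @param tol relative log-likelihood convergence tolerance
#' @return a `cluster_model`: list with `K`, `runs` (each with `theta`,
#'   `alpha`, `rho`, `loglik`, `loglik_trace`, `post`), `best` (index of the
#'   best run), `snp_map`, `individuals`, `chr_start`.
#' @export
fit_cluster_model <- function(gt, K, n_em_runs = 3, max_iter = 100,
                              seed = NULL, tol = 1e-6) {
  stopifnot(K >= 1, n_em_runs >= 1, max_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  geno <- gt$dosages
  storage.mode(geno) <- "integer"
  geno[is.na(geno)] <- -1L
  L <- ncol(geno)
  if (L < 1L) stop("no SNPs to fit")
  chr <- gt$snp_map$chr
  chr_start <- c(TRUE, chr[-1L] != chr[-L])
  runs <- vector("list", n_em_runs)
  for (r in seq_len(n_em_runs)) {
    runs[[r]] <- em_one_run(geno, K, chr_start, max_iter, tol)
  }
  best <- which.max(vapply(runs, `[[`, numeric(1), "loglik"))
  structure(list(K = K, runs = runs, best = best, n_runs = n_em_runs,
                 snp_map = gt$snp_map, individuals = gt$individuals,
                 chr_start = chr_start),
            class = "cluster_model")
}

em_one_run <- function(geno, K, chr_start, max_iter, tol) {
  n <- nrow(geno); L <- ncol(geno)
  theta <- matrix(runif(L * K, 0.05, 0.95), L, K)
  alpha <- matrix(1 / K, L, K)
  rho <- rep(0.1, L)
  rho[chr_start] <- 1
  ll_trace <- numeric(0)
  ll_old <- -Inf
  est <- NULL
  for (it in seq_len(max_iter)) {
    est <- .hmm_estep(geno, theta, alpha, rho, chr_start, FALSE)
    ll <- est$loglik
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) break
    ll_old <- ll
    # M-step
    tot <- est$A1 + est$A0
    upd <- tot > 1e-10
    theta[upd] <- pmin(pmax(est$A1[upd] / tot[upd], 1e-4), 1 - 1e-4)
    jd <- est$JD
    for (l in seq_len(L)) {
      denom <- if (chr_start[l]) 2 * n else est$JC[l]
      if (denom > 1e-8) {
        a <- jd[l, ] / denom + 1e-8
        alpha[l, ] <- a / sum(a)
      }
      if (!chr_start[l]) {
        rho[l] <- min(max(est$JC[l] / (2 * n), 1e-5), 0.999)
      }
    }
  }
  final <- .hmm_estep(geno, theta, alpha, rho, chr_start, TRUE)
  list(theta = theta, alpha = alpha, rho = rho, loglik = final$loglik,
       loglik_trace = c(ll_trace, final$loglik),
       post = array(final$post, dim = c(n, L, K)))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model: K =", x$K, ",", x$n_runs, "EM run(s),",
      dim(x$runs[[1]]$post)[1L], "individuals x",
      nrow(x$snp_map), "SNPs\n")
  cat("  best run log-likelihood:", format(x$runs[[x$best]]$loglik), "\n")
  invisible(x)
}

#' Log-likelihood of a cluster model (best run)
#' @param object a `cluster_model`
#' @param ... unused
#' @export
logLik.cluster_model <- function(object, ...) {
  object$runs[[object$best]]$loglik
}

resolve_grouping <- function(individuals, grouping) {
  if (is.null(grouping)) grouping <- setNames(individuals$line, individuals$id)
  if (is.null(names(grouping))) {
    stopifnot(length(grouping) == nrow(individuals))
    grouping <- setNames(as.character(grouping), individuals$id)
  }
  if (!all(names(grouping) %in% individuals$id)) {
    stop("grouping refers to unknown individuals: ",
         paste(setdiff(names(grouping), individuals$id), collapse = ", "))
  }
  grouping[individuals$id]
}

#' Per-population haplotype-cluster frequencies
#'
#' Posterior-expected cluster memberships averaged over the individuals of
#' each population; at every locus the frequencies of the K clusters sum
#' to 1 per population.
#'
#' @param model a `cluster_model`
#' @param grouping individual-to-population mapping (named vector keyed by
#'   individual id, plain vector in table order, or `NULL` to use the `line`
#'   column); every id must exist in the model.
#' @param run which EM run to use: `"best"` (default) or a run index.
#' @return 3-d array `[population, locus, cluster]` with dimnames.
#' @export
cluster_frequencies <- function(model, grouping = NULL, run = "best") {
  r <- if (identical(run, "best")) model$best else as.integer(run)
  post <- model$runs[[r]]$post
  grouping <- resolve_grouping(model$individuals, grouping)
  if (anyNA(grouping)) stop("every individual needs a population label")
  pops <- unique(grouping)
  L <- dim(post)[2L]; K <- dim(post)[3L]
  out <- array(0, dim = c(length(pops), L, K),
               dimnames = list(pops, model$snp_map$id, paste0("C", 1:K)))
  for (p in pops) {
    ii <- which(grouping == p)
    # post sums to 2 haplotypes per locus; /2 gives frequencies
    m <- apply(post[ii, , , drop = FALSE], c(2L, 3L), mean) / 2
    out[p, , ] <- m
  }
  out
}

#' Tidy cluster-frequency trajectory table
#'
#' Plot-ready long-format table (population, SNP, bp, cluster, frequency),
#' the input for haplotype-cluster frequency displays along a region.
#'
#' @inheritParams cluster_frequencies
#' @param path optional TSV output file
#' @return data.frame (invisibly written to `path` when given).
#' @export
cluster_frequency_table <- function(model, grouping = NULL, run = "best",
                                    path = NULL) {
  cf <- cluster_frequencies(model, grouping, run)
  dn <- dimnames(cf)
  out <- expand.grid(population = dn[[1L]], snp = dn[[2L]],
                     cluster = dn[[3L]], KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$bp <- model$snp_map$bp[match(out$snp, model$snp_map$id)]
  out$frequency <- as.vector(cf)
  out <- out[, c("population", "snp", "bp", "cluster", "frequency")]
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}

#' Posterior-expected dosages under a cluster model
#'
#' `E[dosage] = sum_k m[i, l, k] * theta[l, k]` where `m` is the expected
#' number of haplotypes of individual i in cluster k at locus l. Used for
#' imputation-based cross-validation in [select_K()].
#'
#' @param model a `cluster_model`
#' @param run run index or `"best"`
#' @return individuals x SNPs matrix of expected dosages.
#' @export
predict_dosages <- function(model, run = "best") {
  r <- if (identical(run, "best")) model$best else as.integer(run)
  post <- model$runs[[r]]$post
  theta <- model$runs[[r]]$theta
  n <- dim(post)[1L]; L <- dim(post)[2L]; K <- dim(post)[3L]
  out <- matrix(0, n, L)
  for (k in seq_len(K)) out <- out + post[, , k] * rep(theta[, k], each = n)
  dimnames(out) <- list(model$individuals$id, model$snp_map$id)
  out
}

#' Choose the number of clusters by masking cross-validation
#'
#' Randomly masks a fraction of the observed genotypes (split into `folds`
#' folds), refits the model for each candidate K on the masked data, imputes
#' the held-out dosages from the posterior, and returns the K with the
#' smallest held-out mean squared error. Ties go to the smaller K.
#'
#' @param gt a `genotype_table`
#' @param candidate_Ks integer candidates (>= 2 values, or the single
#'   candidate is returned directly)
#' @param folds number of cross-validation folds
#' @param seed RNG seed
#' @param mask_fraction total fraction of entries masked (default 0.1)
#' @param n_em_runs,max_iter passed to [fit_cluster_model()]
#' @return the selected K (integer).
#' @export
select_K <- function(gt, candidate_Ks, folds = 3, seed = NULL,
                     mask_fraction = 0.1, n_em_runs = 1, max_iter = 50) {
  candidate_Ks <- sort(unique(as.integer(candidate_Ks)))
  if (length(candidate_Ks) == 1L) return(candidate_Ks)
  if (!is.null(seed)) set.seed(seed)
  d <- gt$dosages
  obs <- which(!is.na(d))
  masked <- sample(obs, max(folds, round(mask_fraction * length(obs))))
  fold_of <- rep_len(seq_len(folds), length(masked))
  err <- setNames(numeric(length(candidate_Ks)), candidate_Ks)
  for (f in seq_len(folds)) {
    idx <- masked[fold_of == f]
    gt_masked <- gt
    gt_masked$dosages[idx] <- NA
    for (ki in seq_along(candidate_Ks)) {
      fit <- fit_cluster_model(gt_masked, candidate_Ks[ki],
                               n_em_runs = n_em_runs, max_iter = max_iter)
      pred <- predict_dosages(fit)
      err[ki] <- err[ki] + mean((pred[idx] - d[idx])^2)
    }
  }
  candidate_Ks[which.min(err)]
}
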