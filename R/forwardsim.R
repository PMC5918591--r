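## Neutral forward simulations of allele-frequency trajectories and the
## Monte-Carlo trajectory test used to vet FLK outliers.
##
## Two strategies: (1) a standard Wright-Fisher model with N haploid
## individuals; (2) a sex-structured model tracking the number of reproducing
## males Nm(g) and females Nf(g) at each generation.

#' One Wright-Fisher generation
#'
#' Given `x` copies of an allele among `N` haploid individuals, the count in
#' the next generation is Binomial(N, x/N). Vectorised over `x`.
#'
#' @param x copy count(s), each in `[0, N]`
#' @param N haploid population size
#' @return next-generation copy counts (same length as `x`).
#' @export
wf_step <- function(x, N) {
  stopifnot(N >= 1)
  if (any(x < 0 | x > N)) stop("copy count outside [0, N]")
  rbinom(length(x), N, x / N)
}

#' Sex-structured reproduction counts
#'
#' @param nm,nf integer vectors: reproducing males and females per
#'   generation, index 1 = generation 0.
#' @return a `sex_counts` object.
#' @export
sex_counts <- function(nm, nf) {
  stopifnot(length(nm) == length(nf), all(nm >= 1), all(nf >= 1))
  structure(list(nm = as.integer(nm), nf = as.integer(nf)),
            class = "sex_counts")
}

#' One generation of the sex-structured model
#'
#' With `xm` allele copies among the `2*Nm(g)` male alleles and `xf` among
#' the `2*Nf(g)` female alleles, the next generation counts are
#' `xm' = Xmm + Xmf` and `xf' = Xfm + Xff`, where
#' `Xmm ~ Bin(Nm(g+1), xm / (2 Nm(g)))`, `Xmf ~ Bin(Nm(g+1), xf / (2 Nf(g)))`,
#' `Xfm ~ Bin(Nf(g+1), xm / (2 Nm(g)))`, `Xff ~ Bin(Nf(g+1), xf / (2 Nf(g)))`.
#' Vectorised over `xm`, `xf`.
#'
#' @param xm,xf copy counts among male / female alleles at generation g
#' @param nm_g,nf_g reproducing males / females at generation g
#' @param nm_next,nf_next reproducing males / females at generation g + 1
#' @return list with components `xm`, `xf` for generation g + 1.
#' @export
sexed_step <- function(xm, xf, nm_g, nf_g, nm_next, nf_next) {
  if (nm_g < 1 || nf_g < 1 || nm_next < 1 || nf_next < 1) {
    stop("zero reproducers")
  }
  if (any(xm < 0 | xm > 2 * nm_g) || any(xf < 0 | xf > 2 * nf_g)) {
    stop("copy count outside allowed range")
  }
  n <- length(xm)
  pm <- xm / (2 * nm_g)
  pf <- xf / (2 * nf_g)
  xmm <- rbinom(n, nm_next, pm)
  xmf <- rbinom(n, nm_next, pf)
  xfm <- rbinom(n, nf_next, pm)
  xff <- rbinom(n, nf_next, pf)
  list(xm = xmm + xmf, xf = xfm + xff)
}

#' Monte-Carlo trajectory p-value
#'
#' Simulates `n_sims` neutral allele-frequency trajectories of `g`
#' generations starting from `p0`, records the final frequency `pj` of each,
#' and returns the proportion with `(pj - p0)^2 >= (pf - p0)^2`: the
#' probability that drift alone moves the frequency at least as far as
#' observed.
#'
#' @param p0 starting allele frequency
#' @param pf observed final frequency
#' @param g number of generations
#' @param model `"wright-fisher"` (haploid size `N`) or `"sex-structured"`
#'   (per-generation `counts`)
#' @param N haploid population size (strategy 1); when derived from a diploid
#'   Ne estimate use `N = 2 * Ne`
#' @param counts a [sex_counts()] with `g + 1` entries (strategy 2)
#' @param n_sims number of simulated trajectories
#' @param seed optional RNG seed for reproducibility
#' @return list with `p_value`, `se` (binomial standard error), `n_sims`,
#'   and the snapped starting frequency `p0_used`. `p0` is snapped to the
#'   nearest representable copy count with a warning when needed.
#' @export
trajectory_pvalue <- function(p0, pf, g,
                              model = c("wright-fisher", "sex-structured"),
                              N = NULL, counts = NULL, n_sims = 1e5,
                              seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_sims >= 1, p0 >= 0, p0 <= 1, pf >= 0, pf <= 1, g >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (model == "wright-fisher") {
    stopifnot(!is.null(N), N >= 1)
    x0 <- round(p0 * N)
    p0_used <- x0 / N
    if (abs(p0_used - p0) > 1e-12) {
      warning(sprintf("p0 snapped to grid: %.6f -> %.6f", p0, p0_used))
    }
    x <- rep(x0, n_sims)
    for (i in seq_len(g)) x <- wf_step(x, N)
    pj <- x / N
  } else {
    stopifnot(inherits(counts, "sex_counts"))
    if (length(counts$nm) < g + 1L) {
      stop("sex-structured counts must cover generations 0..g")
    }
    nm <- counts$nm; nf <- counts$nf
    xm0 <- round(p0 * 2 * nm[1L]); xf0 <- round(p0 * 2 * nf[1L])
    p0_used <- (xm0 + xf0) / (2 * nm[1L] + 2 * nf[1L])
    if (abs(p0_used - p0) > 1e-12) {
      warning(sprintf("p0 snapped to grid: %.6f -> %.6f", p0, p0_used))
    }
    xm <- rep(xm0, n_sims); xf <- rep(xf0, n_sims)
    for (i in seq_len(g)) {
      st <- sexed_step(xm, xf, nm[i], nf[i], nm[i + 1L], nf[i + 1L])
      xm <- st$xm; xf <- st$xf
    }
    pj <- (xm + xf) / (2 * nm[g + 1L] + 2 * nf[g + 1L])
  }
  hit <- (pj - p0_used)^2 >= (pf - p0_used)^2 - 1e-12
  p_hat <- mean(hit)
  list(p_value = p_hat, se = sqrt(p_hat * (1 - p_hat) / n_sims),
       n_sims = n_sims, p0_used = p0_used)
}

#' Combine per-line trajectory p-values
#'
#' The final p-value at a SNP is the product of the per-line trajectory
#' probabilities of the two divergent lines.
#'
#' @param p_minus,p_plus per-line probabilities in [0, 1]
#' @return their product.
#' @export
two_line_pvalue <- function(p_minus, p_plus) {
  stopifnot(all(p_minus >= 0 & p_minus <= 1), all(p_plus >= 0 & p_plus <= 1))
  p_minus * p_plus
}

#' Batch trajectory tests for a table of SNPs
#'
#' @param table data.frame with columns `snp`, `p0`, `pf_minus`, `pf_plus`
#' @param g generations
#' @param model,N,counts_minus,counts_plus,n_sims,seed see
#'   [trajectory_pvalue()]; `N` may be length 2 (`minus`, `plus`)
#' @return the table with added columns `p_minus`, `p_plus`, `p_combined`.
#' @export
trajectory_test_batch <- function(table, g, model = "wright-fisher",
                                  N = NULL, counts_minus = NULL,
                                  counts_plus = NULL, n_sims = 1e5,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N2 <- if (length(N) == 2L) N else c(N, N)
  res <- lapply(seq_len(nrow(table)), function(i) {
    pm <- trajectory_pvalue(table$p0[i], table$pf_minus[i], g, model,
                            N = N2[1L], counts = counts_minus,
                            n_sims = n_sims)
    pp <- trajectory_pvalue(table$p0[i], table$pf_plus[i], g, model,
                            N = N2[2L], counts = counts_plus,
                            n_sims = n_sims)
    c(pm$p_value, pp$p_value)
  })
  res <- do.call(rbind, res)
  table$p_minus <- res[, 1L]
  table$p_plus <- res[, 2L]
  table$p_combined <- two_line_pvalue(res[, 1L], res[, 2L])
  table
}
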