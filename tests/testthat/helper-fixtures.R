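# Shared fixtures and independent oracles, all built in code.

# quick genotype table around a dosage matrix (one chromosome by default)
mk_gt <- function(dosages, bp = NULL, chr = NULL, line = NULL, sex = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(bp)) bp <- seq_len(m) * 1e5
  if (is.null(chr)) chr <- rep("1", m)
  genotype_table(
    dosages,
    data.frame(id = paste0("s", seq_len(m)), chr = chr, bp = bp,
               allele1 = "A", allele2 = "B", stringsAsFactors = FALSE),
    data.frame(id = paste0("i", seq_len(n)),
               line = if (is.null(line)) "L1" else line,
               generation = 0L,
               sex = if (is.null(sex)) rep_len(c("M", "F"), n) else sex,
               hatch = rep_len(1:2, n), stringsAsFactors = FALSE))
}

# allele_freq_set built directly from frequency / count matrices
mk_afs <- function(freq, counts = NULL, bp = NULL) {
  freq <- as.matrix(freq)
  if (is.null(counts)) {
    counts <- matrix(1e6, nrow(freq), ncol(freq),
                     dimnames = dimnames(freq))
  }
  if (is.null(bp)) bp <- seq_len(nrow(freq)) * 1e5
  structure(list(freq = freq, counts = counts,
                 snp_map = data.frame(id = paste0("s", seq_len(nrow(freq))),
                                      chr = "1", bp = bp,
                                      stringsAsFactors = FALSE)),
            class = "allele_freq_set")
}

# a population_kinship with diagonal F (independent lines) via build_kinship
mk_kinship_diag <- function(FA, FB, outgroup = "G0",
                            lines = c("A", "B")) {
  d <- matrix(0, 3, 3, dimnames = list(c(outgroup, lines),
                                       c(outgroup, lines)))
  d[outgroup, lines[1]] <- d[lines[1], outgroup] <- FA
  d[outgroup, lines[2]] <- d[lines[2], outgroup] <- FB
  d[lines[1], lines[2]] <- d[lines[2], lines[1]] <- FA + FB
  build_kinship(d, outgroup)
}

# exact Wright-Fisher trajectory p-value for g = 1 by binomial enumeration
exact_traj_p_g1 <- function(p0, pf, N) {
  x0 <- round(p0 * N)
  p0g <- x0 / N
  x <- 0:N
  sum(dbinom(x, N, p0g)[(x / N - p0g)^2 >= (pf - p0g)^2 - 1e-12])
}

# brute-force likelihood of the pair-of-haplotypes cluster HMM by full
# enumeration of ordered cluster paths (oracle for .hmm_estep)
brute_hmm_loglik <- function(geno, theta, alpha, rho, chr_start) {
  K <- ncol(theta); L <- nrow(theta)
  emit <- function(g, t1, t2) {
    if (is.na(g) || g < 0) 1
    else if (g == 0) (1 - t1) * (1 - t2)
    else if (g == 2) t1 * t2
    else t1 * (1 - t2) + (1 - t1) * t2
  }
  states <- expand.grid(k1 = 1:K, k2 = 1:K)
  S <- nrow(states)
  ll <- 0
  for (i in seq_len(nrow(geno))) {
    grid <- do.call(expand.grid, rep(list(seq_len(S)), L))
    tot <- 0
    for (r in seq_len(nrow(grid))) {
      pr <- 1
      for (l in seq_len(L)) {
        s <- grid[r, l]
        k1 <- states$k1[s]; k2 <- states$k2[s]
        if (chr_start[l]) {
          pr <- pr * alpha[l, k1] * alpha[l, k2]
        } else {
          sp <- grid[r, l - 1]
          j1 <- states$k1[sp]; j2 <- states$k2[sp]
          pr <- pr * ((1 - rho[l]) * (j1 == k1) + rho[l] * alpha[l, k1]) *
            ((1 - rho[l]) * (j2 == k2) + rho[l] * alpha[l, k2])
        }
        pr <- pr * emit(geno[i, l], theta[l, k1], theta[l, k2])
      }
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  ll
}

# two-haplotype fixture: individuals are draws of two complementary
# haplotypes with frequency fA for haplotype A
two_hap_fixture <- function(n_ind = 30, n_snp = 20, fA = 0.6) {
  hapA <- rep_len(c(1L, 0L), n_snp)
  hapB <- 1L - hapA
  nA <- round(2 * n_ind * fA)
  haps <- c(rep(list(hapA), nA), rep(list(hapB), 2 * n_ind - nA))
  d <- t(vapply(seq_len(n_ind), function(i) {
    haps[[2 * i - 1]] + haps[[2 * i]]
  }, integer(n_snp)))
  mk_gt(d)
}

# pure-drift line frequencies: diploid WF with 2N haploid copies
drift_freq <- function(p0, n_dip, g) {
  x <- rbinom(length(p0), 2 * n_dip, p0)
  if (g > 1) for (i in seq_len(g - 1)) {
    x <- rbinom(length(x), 2 * n_dip, x / (2 * n_dip))
  }
  x / (2 * n_dip)
}

# haplotype-pool population sample: n individuals, pool haplotypes drawn
# with weights w (per segment between breakpoints); returns dosage matrix
sample_pool_pop <- function(n, pool, w, breaks = NULL) {
  L <- ncol(pool)
  segs <- if (is.null(breaks)) list(seq_len(L)) else {
    split(seq_len(L), cut(seq_len(L), breaks = c(0, breaks, L)))
  }
  draw_hap <- function(wloc) {
    h <- integer(L)
    for (sg in segs) {
      h[sg] <- pool[sample.int(nrow(pool), 1, prob = wloc), sg]
    }
    h
  }
  t(vapply(seq_len(n), function(i) draw_hap(w) + draw_hap(w), integer(L)))
}

# Dirichlet draw calibrated so each component has drift variance w(1-w)*F
rdirichlet_drift <- function(w, F) {
  conc <- (1 - F) / F
  g <- rgamma(length(w), shape = w * conc)
  g / sum(g)
}
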