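## Synthetic divergent-selection experiment: founders with blockwise LD,
## correlated polygenic traits, and six generations of two-line divergent
## sib selection with sex-specific reproducer counts. Stands in for the
## (undeposited) real chip data and provides ground truth for every other
## module.
##
## The default design mirrors the reference experiment at reduced SNP count:
## the best 19% of sires and 50% of dams are selected each generation, ~27
## reproducing sires and ~70 dams per line, 51 genotyped G0 sires, ~20
## genotyped sires per line per generation (G1-G5), and a G6 phenotyped
## cohort of 558 birds (253 males, 305 females) measured for two traits with
## heritability ~0.4 and genetic correlation 0.54 (ultimate pH of breast and
## thigh muscle).

#' Breeding design of the divergent-selection experiment
#'
#' @param generations number of selection generations (G1..Gg)
#' @param sire_fraction selected proportion of male candidates
#' @param dam_fraction selected proportion of female candidates
#' @param n_founders G0 population size
#' @param offspring_per_line offspring produced per line per generation
#' @param n_genotyped_sires_g0 genotyped sires at G0
#' @param n_genotyped_sires genotyped (selected) sires per line per
#'   generation
#' @param g6_males,g6_females size of the phenotyped G6 cohort (both lines
#'   pooled)
#' @return a `breeding_design`; the implied per-line reproducer counts
#'   (`n_sires`, `n_dams`) are derived from the fractions.
#' @export
breeding_design <- function(generations = 5, sire_fraction = 0.19,
                            dam_fraction = 0.50, n_founders = 200,
                            offspring_per_line = 280,
                            n_genotyped_sires_g0 = 51,
                            n_genotyped_sires = 20,
                            g6_males = 253, g6_females = 305) {
  stopifnot(sire_fraction > 0, sire_fraction <= 1, dam_fraction > 0,
            dam_fraction <= 1, generations >= 1)
  n_male_cand <- floor(offspring_per_line / 2)
  n_sires <- max(1L, round(sire_fraction * n_male_cand))
  n_dams <- max(1L, round(dam_fraction * (offspring_per_line - n_male_cand)))
  structure(list(generations = generations, sire_fraction = sire_fraction,
                 dam_fraction = dam_fraction, n_founders = n_founders,
                 offspring_per_line = offspring_per_line,
                 n_sires = n_sires, n_dams = n_dams,
                 n_genotyped_sires_g0 = n_genotyped_sires_g0,
                 n_genotyped_sires = n_genotyped_sires,
                 g6_males = g6_males, g6_females = g6_females),
            class = "breeding_design")
}

#' Per-generation reproducer counts of a design
#'
#' @param design a `breeding_design`
#' @return a [sex_counts()] covering generations 0..generations (one line).
#' @export
design_sex_counts <- function(design) {
  g <- design$generations
  sex_counts(rep(design$n_sires, g + 1L), rep(design$n_dams, g + 1L))
}

#' Simulate a founder cohort with blockwise LD
#'
#' Founder haplotypes are recombinant mosaics of a small pool of ancestral
#' haplotypes: walking along each chromosome, a founder haplotype copies one
#' pool member and switches to a random member with probability
#' `founder_switch_rate * gap` between adjacent SNPs. This produces the
#' blockwise LD structure of a real chip panel without coalescent machinery.
#'
#' @param n_ind number of founder individuals
#' @param n_snp total SNPs (split evenly across chromosomes)
#' @param n_chr number of chromosomes
#' @param spacing inter-SNP spacing in bp
#' @param n_ancestral_haplotypes pool size (>= 2)
#' @param founder_switch_rate per-bp mosaic switch probability
#' @param recomb_rate per-bp crossover probability used later for meiosis
#'   (stored with the table)
#' @param seed RNG seed
#' @return a `genotype_table` with attributes `haplotypes` (list of two 0/1
#'   matrices) and `recomb_rate`.
#' @export
simulate_founders <- function(n_ind = 200, n_snp = 2000, n_chr = 5,
                              spacing = 60000, n_ancestral_haplotypes = 10,
                              founder_switch_rate = 5e-7,
                              recomb_rate = 1e-8, seed = NULL) {
  stopifnot(n_ancestral_haplotypes >= 2)
  if (!is.null(seed)) set.seed(seed)
  per_chr <- rep(n_snp %/% n_chr, n_chr)
  per_chr[seq_len(n_snp %% n_chr)] <- per_chr[seq_len(n_snp %% n_chr)] + 1L
  snp_map <- do.call(rbind, lapply(seq_len(n_chr), function(ch) {
    data.frame(id = sprintf("snp-%d-%04d", ch, seq_len(per_chr[ch])),
               chr = as.character(ch), bp = spacing * seq_len(per_chr[ch]),
               stringsAsFactors = FALSE)
  }))
  L <- nrow(snp_map)
  pool_freq <- runif(L, 0.1, 0.9)
  pool <- matrix(rbinom(n_ancestral_haplotypes * L, 1,
                        rep(pool_freq, each = n_ancestral_haplotypes)),
                 n_ancestral_haplotypes, L)
  chr_start <- c(TRUE, snp_map$chr[-1L] != snp_map$chr[-L])
  gap <- c(0, diff(snp_map$bp))
  gap[chr_start] <- 0
  switch_p <- pmin(0.5, founder_switch_rate * gap)
  draw_hap <- function() {
    sw <- chr_start | (runif(L) < switch_p)
    src <- sample.int(n_ancestral_haplotypes, sum(sw), replace = TRUE)
    idx <- cumsum(sw)
    pool[cbind(src[idx], seq_len(L))]
  }
  h1 <- t(vapply(seq_len(n_ind), function(i) draw_hap(), integer(L)))
  h2 <- t(vapply(seq_len(n_ind), function(i) draw_hap(), integer(L)))
  ind <- data.frame(id = sprintf("G0-%04d", seq_len(n_ind)), line = "G0",
                    generation = 0L,
                    sex = rep_len(c("M", "F"), n_ind),
                    hatch = rep_len(1:2, n_ind), stringsAsFactors = FALSE)
  gt <- genotype_table(h1 + h2, snp_map, ind)
  attr(gt, "haplotypes") <- list(h1 = h1, h2 = h2)
  attr(gt, "recomb_rate") <- recomb_rate
  gt
}

#' Simulate a correlated two-trait polygenic architecture
#'
#' QTL effects are drawn from a bivariate normal with correlation `rg` and
#' scaled so the realised founder-population heritabilities match `h2`
#' (phenotypic variances are normalised to 1, so genetic variance = h2).
#' Optionally the first QTL is given a fixed large effect on trait 1.
#'
#' @param gt founder `genotype_table`
#' @param n_qtl number of QTL (sampled among polymorphic SNPs)
#' @param h2 length-2 heritabilities (0 allowed: a flat trait)
#' @param rg genetic correlation between the trait effects
#' @param residual_cor residual correlation (default 0.2)
#' @param large_qtl_var fraction of trait-1 phenotypic variance assigned to
#'   the first QTL (0 = none)
#' @param mu trait means (default pH-like values 5.9 and 6.35)
#' @param seed RNG seed
#' @return a `trait_architecture`: list with `qtl` (data.frame snp_index,
#'   snp, effect1, effect2), `h2`, `rg`, `residual_cor`, `ve`, `mu`.
#' @export
simulate_architecture <- function(gt, n_qtl = 100, h2 = c(0.4, 0.4),
                                  rg = 0.54, residual_cor = 0.2,
                                  large_qtl_var = 0,
                                  mu = c(5.9, 6.35), seed = NULL) {
  stopifnot(length(h2) == 2, all(h2 >= 0), all(h2 < 1), abs(rg) <= 1,
            n_qtl <= n_snps(gt))
  if (!is.null(seed)) set.seed(seed)
  X <- gt$dosages
  v <- apply(X, 2L, var)
  poly <- which(v > 0)
  if (length(poly) < n_qtl) stop("insufficient polymorphic SNPs for ", n_qtl,
                                 " QTL")
  idx <- sort(sample(poly, n_qtl))
  z1 <- rnorm(n_qtl)
  z2 <- rg * z1 + sqrt(max(0, 1 - rg^2)) * rnorm(n_qtl)
  eff <- cbind(z1, z2)
  if (large_qtl_var > 0) {
    eff[1L, 1L] <- sqrt(large_qtl_var / v[idx[1L]])
  }
  Xq <- X[, idx, drop = FALSE]
  for (t in 1:2) {
    target <- h2[t]
    if (target == 0) {
      eff[, t] <- 0
      next
    }
    if (large_qtl_var > 0 && t == 1L) {
      # fix the large QTL, rescale the polygenic background to the remainder
      bg <- seq_len(n_qtl)[-1L]
      vbg <- var(as.vector(Xq[, bg, drop = FALSE] %*% eff[bg, t]))
      rem <- max(target - large_qtl_var, 0)
      eff[bg, t] <- eff[bg, t] * if (vbg > 0) sqrt(rem / vbg) else 0
    } else {
      vg <- var(as.vector(Xq %*% eff[, t]))
      if (vg <= 0) stop("degenerate genetic variance for trait ", t)
      eff[, t] <- eff[, t] * sqrt(target / vg)
    }
  }
  ve <- 1 - h2
  structure(list(qtl = data.frame(snp_index = idx, snp = gt$snp_map$id[idx],
                                  effect1 = eff[, 1L], effect2 = eff[, 2L],
                                  stringsAsFactors = FALSE),
                 h2 = h2, rg = rg, residual_cor = residual_cor, ve = ve,
                 mu = mu),
            class = "trait_architecture")
}

#' Breeding values and phenotypes under an architecture
#'
#' @param arch a `trait_architecture`
#' @param dosages dosage matrix (individuals x all SNPs)
#' @return list with `bv` (n x 2 breeding values) and `pheno` (n x 2
#'   phenotypes with correlated residuals).
#' @export
draw_phenotypes <- function(arch, dosages) {
  Xq <- dosages[, arch$qtl$snp_index, drop = FALSE]
  bv <- Xq %*% cbind(arch$qtl$effect1, arch$qtl$effect2)
  n <- nrow(bv)
  e1 <- rnorm(n)
  e2 <- arch$residual_cor * e1 +
    sqrt(max(0, 1 - arch$residual_cor^2)) * rnorm(n)
  err <- cbind(e1 * sqrt(arch$ve[1L]), e2 * sqrt(arch$ve[2L]))
  pheno <- sweep(bv + err, 2L, arch$mu, `+`)
  colnames(bv) <- colnames(pheno) <- c("trait1", "trait2")
  list(bv = bv, pheno = pheno)
}

## vectorised meiosis: one recombinant gamete from a parent's two haplotypes
one_gamete <- function(h1, h2, switch_p, chr_start) {
  L <- length(switch_p)
  sw <- runif(L) < switch_p
  sw[chr_start] <- runif(sum(chr_start)) < 0.5
  start_flip <- runif(1) < 0.5 # phase before first locus
  phase <- cumsum(sw) %% 2L
  if (start_flip) phase <- 1L - phase
  ifelse(phase == 0L, h1, h2)
}

#' Run the divergent-selection breeding experiment
#'
#' Two lines are founded from the same G0 cohort and selected divergently
#' (high / low) on trait 1 for `design$generations` generations, using a
#' sib index: each candidate is ranked by the mean trait-1 phenotype of its
#' full sibs (excluding itself - the measured sibs are slaughtered), the
#' best `sire_fraction` of males and `dam_fraction` of females becoming the
#' reproducers. Matings are nested (each dam assigned to one sire), gametes
#' recombine at the founder table's `recomb_rate`. A final G6 cohort is
#' produced and phenotyped for both traits.
#'
#' @param founders founder table from [simulate_founders()]
#' @param arch a [simulate_architecture()] result
#' @param design a [breeding_design()]
#' @param seed RNG seed
#' @return a `breeding_experiment`: list with `genotypes` (named list of
#'   `genotype_table`s: `G0` genotyped sires, `G<g>_pHu-` / `G<g>_pHu+`
#'   genotyped sires per generation, `G6` cohort), `phenotypes` (G6 trait
#'   table), and `truth` (QTL table, per-generation true line allele
#'   frequencies, per-generation line trait means, selected parent ids).
#' @export
run_breeding_experiment <- function(founders, arch, design, seed = NULL) {
  stopifnot(inherits(design, "breeding_design"),
            inherits(arch, "trait_architecture"))
  if (!is.null(seed)) set.seed(seed)
  haps <- attr(founders, "haplotypes")
  if (is.null(haps)) stop("founders must carry haplotypes (simulate_founders)")
  recomb <- attr(founders, "recomb_rate")
  map <- founders$snp_map
  L <- nrow(map)
  chr_start <- c(TRUE, map$chr[-1L] != map$chr[-L])
  gap <- c(0, diff(map$bp)); gap[chr_start] <- 0
  switch_p <- pmin(0.5, recomb * gap)
  lines <- c("pHu-", "pHu+")
  n_gen <- design$generations

  founder_ph <- draw_phenotypes(arch, founders$dosages)
  g0 <- list(h1 = haps$h1, h2 = haps$h2, sex = founders$individuals$sex,
             pheno = founder_ph$pheno, bv = founder_ph$bv,
             family = seq_len(nrow(haps$h1)), # founders: no sib structure
             id = founders$individuals$id)

  freq_truth <- list()
  line_means <- list()
  selected_parents <- list()
  genotypes <- list()

  # G0 genotyped sires
  g0_males <- which(g0$sex == "M")
  g0_sires <- sort(sample(g0_males,
                          min(design$n_genotyped_sires_g0, length(g0_males))))
  genotypes[["G0"]] <- make_table(g0, g0_sires, map, "G0", 0L)
  freq_truth[["G0"]] <- colMeans(g0$h1 + g0$h2) / 2

  # found the two lines from G0 on own phenotype (no sib records yet)
  cur <- list()
  for (ln in lines) {
    dir <- if (ln == "pHu+") 1 else -1
    idx_m <- order(dir * g0$pheno[g0_males, 1L], decreasing = TRUE)
    sires <- g0_males[head(idx_m, design$n_sires)]
    g0_females <- which(g0$sex == "F")
    idx_f <- order(dir * g0$pheno[g0_females, 1L], decreasing = TRUE)
    dams <- g0_females[head(idx_f, design$n_dams)]
    cur[[ln]] <- list(pop = g0, sires = sires, dams = dams)
    selected_parents[[paste0("G0_", ln)]] <-
      list(sires = g0$id[sires], dams = g0$id[dams])
  }

  for (g in seq_len(n_gen)) {
    for (ln in lines) {
      off <- breed_generation(cur[[ln]]$pop, cur[[ln]]$sires,
                              cur[[ln]]$dams, design$offspring_per_line,
                              switch_p, chr_start, arch,
                              sprintf("G%d-%s", g, ln))
      dir <- if (ln == "pHu+") 1 else -1
      sel <- select_on_sib_index(off, dir, design)
      cur[[ln]] <- list(pop = off, sires = sel$sires, dams = sel$dams)
      selected_parents[[sprintf("G%d_%s", g, ln)]] <-
        list(sires = off$id[sel$sires], dams = off$id[sel$dams])
      freq_truth[[sprintf("G%d_%s", g, ln)]] <-
        colMeans(off$h1 + off$h2) / 2
      line_means[[sprintf("G%d_%s", g, ln)]] <- colMeans(off$pheno)
      gsires <- sort(sel$sires[seq_len(min(design$n_genotyped_sires,
                                           length(sel$sires)))])
      genotypes[[sprintf("G%d_%s", g, ln)]] <-
        make_table(off, gsires, map, ln, g)
    }
  }

  # G6 phenotyped cohort: half of the target from each line
  n6 <- design$g6_males + design$g6_females
  per_line <- c(floor(n6 / 2), ceiling(n6 / 2))
  sexes6 <- sample(rep(c("M", "F"), c(design$g6_males, design$g6_females)))
  g6_parts <- list()
  at <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    off <- breed_generation(cur[[ln]]$pop, cur[[ln]]$sires, cur[[ln]]$dams,
                            per_line[i], switch_p, chr_start, arch,
                            sprintf("G%d-%s", n_gen + 1L, ln),
                            sexes = sexes6[(at + 1L):(at + per_line[i])])
    at <- at + per_line[i]
    off$line <- ln
    g6_parts[[ln]] <- off
    freq_truth[[sprintf("G%d_%s", n_gen + 1L, ln)]] <-
      colMeans(off$h1 + off$h2) / 2
    line_means[[sprintf("G%d_%s", n_gen + 1L, ln)]] <- colMeans(off$pheno)
  }
  g6_dos <- rbind(g6_parts[[1L]]$h1 + g6_parts[[1L]]$h2,
                  g6_parts[[2L]]$h1 + g6_parts[[2L]]$h2)
  g6_ind <- data.frame(
    id = c(g6_parts[[1L]]$id, g6_parts[[2L]]$id),
    line = rep(lines, per_line),
    generation = n_gen + 1L,
    sex = c(g6_parts[[1L]]$sex, g6_parts[[2L]]$sex),
    hatch = rep_len(1:2, sum(per_line)), stringsAsFactors = FALSE)
  genotypes[["G6"]] <- genotype_table(g6_dos, map, g6_ind)
  phenotypes <- data.frame(g6_ind,
                           PM_pHu = c(g6_parts[[1L]]$pheno[, 1L],
                                      g6_parts[[2L]]$pheno[, 1L]),
                           SART_pHu = c(g6_parts[[1L]]$pheno[, 2L],
                                        g6_parts[[2L]]$pheno[, 2L]),
                           stringsAsFactors = FALSE)

  truth <- list(qtl = arch$qtl,
                freq = do.call(rbind, freq_truth),
                line_means = do.call(rbind, line_means),
                selected = selected_parents)
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 truth = truth, design = design, arch = arch,
                 snp_map = map),
            class = "breeding_experiment")
}

## produce one generation of offspring from selected parents
breed_generation <- function(pop, sires, dams, n_off, switch_p, chr_start,
                             arch, id_prefix, sexes = NULL) {
  if (length(sires) == 0L || length(dams) == 0L) {
    stop("extinction: no selected parents")
  }
  # nested mating: each dam assigned to one sire; offspring spread over dams
  dam_sire <- sires[rep_len(seq_along(sires), length(dams))]
  off_dam <- rep_len(seq_along(dams), n_off)
  h1 <- matrix(0L, n_off, length(switch_p))
  h2 <- matrix(0L, n_off, length(switch_p))
  for (o in seq_len(n_off)) {
    di <- dams[off_dam[o]]
    si <- dam_sire[off_dam[o]]
    h1[o, ] <- one_gamete(pop$h1[si, ], pop$h2[si, ], switch_p, chr_start)
    h2[o, ] <- one_gamete(pop$h1[di, ], pop$h2[di, ], switch_p, chr_start)
  }
  ph <- draw_phenotypes(arch, h1 + h2)
  sex <- if (is.null(sexes)) sample(rep_len(c("M", "F"), n_off)) else sexes
  list(h1 = h1, h2 = h2, sex = sex, pheno = ph$pheno, bv = ph$bv,
       family = off_dam, id = sprintf("%s-%04d", id_prefix, seq_len(n_off)))
}

## sib index: mean trait-1 phenotype of full sibs excluding self
select_on_sib_index <- function(off, dir, design) {
  fam <- off$family
  y <- off$pheno[, 1L]
  fam_sum <- tapply(y, fam, sum)[as.character(fam)]
  fam_n <- tapply(y, fam, length)[as.character(fam)]
  index <- ifelse(fam_n > 1, (fam_sum - y) / (fam_n - 1), y)
  males <- which(off$sex == "M")
  females <- which(off$sex == "F")
  n_s <- min(design$n_sires, length(males))
  n_d <- min(design$n_dams, length(females))
  sires <- males[order(dir * index[males], decreasing = TRUE)][seq_len(n_s)]
  dams <- females[order(dir * index[females],
                        decreasing = TRUE)][seq_len(n_d)]
  list(sires = sires, dams = dams)
}

make_table <- function(pop, idx, map, line, generation) {
  ind <- data.frame(id = pop$id[idx], line = line,
                    generation = as.integer(generation),
                    sex = pop$sex[idx], hatch = rep_len(1:2, length(idx)),
                    stringsAsFactors = FALSE)
  genotype_table(pop$h1[idx, , drop = FALSE] + pop$h2[idx, , drop = FALSE],
                 map, ind)
}

#' Combined scan cohort at one generation
#'
#' Genotyped G0 sires plus the genotyped sires of both lines at generation
#' `g`, as one `genotype_table` whose `line` labels are the population
#' grouping used by the FLK/hapFLK scans.
#'
#' @param exp a `breeding_experiment`
#' @param g generation (1..design$generations)
#' @return a `genotype_table`.
#' @export
scan_cohort <- function(exp, g) {
  parts <- list(exp$genotypes[["G0"]],
                exp$genotypes[[sprintf("G%d_pHu-", g)]],
                exp$genotypes[[sprintf("G%d_pHu+", g)]])
  if (any(vapply(parts, is.null, logical(1)))) {
    stop("generation ", g, " not present in the experiment")
  }
  genotype_table(do.call(rbind, lapply(parts, `[[`, "dosages")),
                 exp$snp_map,
                 do.call(rbind, lapply(parts, `[[`, "individuals")))
}

#' Export the simulated study to files
#'
#' PLINK-style genotype files per cohort, a G6 phenotype TSV and truth TSVs
#' (QTL effects and per-generation line allele frequencies).
#'
#' @param exp a `breeding_experiment`
#' @param dir output directory (created if needed)
#' @param format genotype format for [write_genotypes()]
#' @return `dir`, invisibly.
#' @export
export_study_layout <- function(exp, dir, format = "plink-text") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(exp$genotypes)) {
    write_genotypes(exp$genotypes[[nm]],
                    file.path(dir, gsub("[^A-Za-z0-9_+-]", "_", nm)), format)
  }
  write.table(exp$phenotypes, file.path(dir, "phenotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(exp$truth$qtl, file.path(dir, "truth_qtl.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  freq <- data.frame(cohort = rownames(exp$truth$freq), exp$truth$freq,
                     check.names = FALSE)
  write.table(freq, file.path(dir, "truth_freq.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
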