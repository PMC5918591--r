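## Post-hoc summaries: pairwise LD (r2), region-category LD averages, the
## QTL-inside-selection-signature enrichment test, and region intersection.

#' Pairwise linkage disequilibrium (r2)
#'
#' Squared dosage correlation (composite LD, the standard chip-data
#' estimator) for all same-chromosome SNP pairs closer than `max_distance`
#' with minor allele frequency strictly greater than `maf_min`. Pairs
#' involving a zero-variance SNP are skipped.
#'
#' @param gt a `genotype_table`
#' @param max_distance maximum pair distance in bp (strict `<`, default
#'   500 kb)
#' @param maf_min MAF threshold (strict `>`, default 0.1)
#' @return an `ld_pair_table` data.frame: snpA, snpB, chr, bpA, bpB,
#'   distance, r2.
#' @export
ld_r2 <- function(gt, max_distance = 5e5, maf_min = 0.1) {
  f <- colMeans(gt$dosages, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  maf_ok <- pmin(f, 1 - f) > maf_min
  v <- apply(gt$dosages, 2L, var, na.rm = TRUE)
  keep <- maf_ok & !is.na(v) & v > 0
  d <- gt$dosages[, keep, drop = FALSE]
  map <- gt$snp_map[keep, , drop = FALSE]
  out <- list()
  for (ch in unique(map$chr)) {
    jj <- which(map$chr == ch)
    bp <- map$bp[jj]
    for (ai in seq_along(jj)) {
      bi <- ai + 1L
      while (bi <= length(jj) && bp[bi] - bp[ai] < max_distance) {
        r <- suppressWarnings(
          cor(d[, jj[ai]], d[, jj[bi]], use = "pairwise.complete.obs"))
        if (is.finite(r)) {
          out[[length(out) + 1L]] <-
            data.frame(snpA = map$id[jj[ai]], snpB = map$id[jj[bi]],
                       chr = ch, bpA = bp[ai], bpB = bp[bi],
                       distance = bp[bi] - bp[ai], r2 = r * r,
                       stringsAsFactors = FALSE)
        }
        bi <- bi + 1L
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(snpA = character(), snpB = character(), chr = character(),
               bpA = numeric(), bpB = numeric(), distance = numeric(),
               r2 = numeric(), stringsAsFactors = FALSE)
  class(res) <- c("ld_pair_table", "data.frame")
  res
}

#' Mean r2 per region category
#'
#' A pair belongs to a category when both of its SNPs fall inside a region
#' of that category. The genome-wide category (all pairs) is always
#' reported. The spread is reported two ways: across qualifying pairs
#' (`sd_pairs`) and across per-region means (`sd_regions`).
#'
#' @param pairs an `ld_pair_table`
#' @param regions a `genomic_regions` table, optionally with a `category`
#'   column (defaults to a single category named `"regions"`); `NULL` for
#'   genome-wide only
#' @return data.frame: category, n_pairs, mean_r2, sd_pairs, sd_regions
#'   (`NA` when a category holds no pair, flagged by n_pairs = 0).
#' @export
region_mean_r2 <- function(pairs, regions = NULL) {
  res <- data.frame(category = "genome-wide", n_pairs = nrow(pairs),
                    mean_r2 = if (nrow(pairs)) mean(pairs$r2) else NA_real_,
                    sd_pairs = if (nrow(pairs) > 1) sd(pairs$r2) else NA_real_,
                    sd_regions = NA_real_, stringsAsFactors = FALSE)
  if (is.null(regions) || nrow(regions) == 0L) return(res)
  if (is.null(regions$category)) regions$category <- "regions"
  for (cat in unique(regions$category)) {
    rr <- regions[regions$category == cat, , drop = FALSE]
    per_region <- numeric(0)
    inside <- rep(FALSE, nrow(pairs))
    for (i in seq_len(nrow(rr))) {
      hit <- pairs$chr == rr$chr[i] &
        pairs$bpA >= rr$start[i] & pairs$bpA <= rr$end[i] &
        pairs$bpB >= rr$start[i] & pairs$bpB <= rr$end[i]
      inside <- inside | hit
      if (any(hit)) per_region <- c(per_region, mean(pairs$r2[hit]))
    }
    res <- rbind(res, data.frame(
      category = cat, n_pairs = sum(inside),
      mean_r2 = if (any(inside)) mean(pairs$r2[inside]) else NA_real_,
      sd_pairs = if (sum(inside) > 1) sd(pairs$r2[inside]) else NA_real_,
      sd_regions = if (length(per_region) > 1) sd(per_region) else NA_real_,
      stringsAsFactors = FALSE))
  }
  res
}

#' Enrichment of Bayes factors inside selected regions
#'
#' Two-sided two-sample Welch t-test comparing the Bayes factors of SNPs
#' inside candidate selection regions with those of the rest of the genome.
#'
#' @param bf_inside,bf_outside BF values for the two groups (each >= 2)
#' @return list with `t`, `p_value`, `df`, `mean_inside`, `mean_outside`.
#' @export
enrichment_test <- function(bf_inside, bf_outside) {
  stopifnot(length(bf_inside) >= 2, length(bf_outside) >= 2)
  if (var(bf_inside) == 0 && var(bf_outside) == 0) {
    if (identical(mean(bf_inside), mean(bf_outside))) {
      return(list(t = 0, p_value = 1, df = NA_real_,
                  mean_inside = mean(bf_inside),
                  mean_outside = mean(bf_outside)))
    }
    stop("degenerate variance in both groups")
  }
  tt <- t.test(bf_inside, bf_outside, var.equal = FALSE,
               alternative = "two.sided")
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_inside = mean(bf_inside),
       mean_outside = mean(bf_outside))
}

#' Intersect QTL regions with selection signatures
#'
#' Closed-interval overlap (touching endpoints count). Every overlapping
#' signature is reported; regions with none get `"-"`.
#'
#' @param qtl,signatures `genomic_regions` tables
#' @return character vector (one entry per QTL region, comma-separated
#'   signature names), named by QTL region name.
#' @export
intersect_regions <- function(qtl, signatures) {
  out <- setNames(rep("-", nrow(qtl)), qtl$name)
  if (nrow(qtl) == 0L || is.null(signatures) || nrow(signatures) == 0L) {
    return(out)
  }
  for (i in seq_len(nrow(qtl))) {
    hit <- signatures$chr == qtl$chr[i] &
      signatures$start <= qtl$end[i] & signatures$end >= qtl$start[i]
    if (any(hit)) out[i] <- paste(signatures$name[hit], collapse = ",")
  }
  out
}
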