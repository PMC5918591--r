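## hapFLK scan: the FLK quadratic form extended to local haplotype-cluster
## frequencies, with an empirical normal null fitted robustly to genome-wide
## values and region construction within and across generations.

#' hapFLK statistic at one locus
#'
#' Sum over haplotype clusters of the single-frequency FLK quadratic form,
#' each cluster's frequency vector playing the role of an allele frequency
#' and the outgroup cluster frequency the role of the ancestral frequency.
#' Clusters whose outgroup frequency is (numerically) 0 or 1, or that are
#' absent everywhere, contribute nothing.
#'
#' @param cluster_freqs matrix populations x clusters at one locus (selected
#'   lines only, rownames = population names)
#' @param p0_clusters outgroup cluster frequencies (length = clusters)
#' @param kinship a `population_kinship`
#' @return the statistic value.
#' @export
hapflk_statistic <- function(cluster_freqs, p0_clusters, kinship) {
  stopifnot(ncol(cluster_freqs) == length(p0_clusters))
  pops <- rownames(cluster_freqs)
  Fm <- kinship$F[pops, pops, drop = FALSE]
  Fi <- safe_inverse(Fm)
  tot <- 0
  for (k in seq_along(p0_clusters)) {
    p0 <- p0_clusters[k]
    if (is.na(p0) || p0 < P0_EPS || p0 > 1 - P0_EPS) next
    d <- cluster_freqs[, k] - p0
    tot <- tot + drop(t(d) %*% Fi %*% d) / (p0 * (1 - p0))
  }
  tot
}

#' Fit the normal null of a hapFLK scan
#'
#' Assumes the statistic is normally distributed under neutral drift and
#' estimates location and scale by regressing the order statistics of the
#' lower body of the distribution (5th to 65th percentile ranks) on standard
#' normal quantiles. Excluding the whole upper tail - not just the extreme
#' 5% - keeps the fit essentially unchanged when a few percent of loci carry
#' genuine selection signal.
#'
#' @param stats genome-wide hapFLK values (>= 100)
#' @return a `hapflk_null`: list with `location`, `scale`.
#' @export
fit_null_normal <- function(stats) {
  stats <- stats[is.finite(stats)]
  n <- length(stats)
  if (n < 100L) stop("need >= 100 hapFLK values to fit the null")
  s <- sort(stats)
  z <- qnorm(ppoints(n))
  keep <- seq_len(n) >= ceiling(0.05 * n) & seq_len(n) <= floor(0.65 * n)
  fit <- lm(s[keep] ~ z[keep])
  location <- unname(coef(fit)[1L])
  scale <- unname(coef(fit)[2L])
  if (!is.finite(scale) || scale < 1e-10) {
    stop("degenerate scale: hapFLK values are (near-)constant")
  }
  structure(list(location = location, scale = scale), class = "hapflk_null")
}

#' Upper-tail p-values under a fitted hapFLK null
#' @param null a `hapflk_null`
#' @param x statistic values
#' @return p-values.
#' @export
hapflk_pvalues <- function(null, x) {
  pnorm(x, mean = null$location, sd = null$scale, lower.tail = FALSE)
}

#' Genome-wide hapFLK scan
#'
#' Computes the per-locus statistic for every EM run of the cluster model,
#' averages across runs (one null fit per scan), assigns p-values from the
#' robust normal null and q-values, and groups contiguous significant loci
#' into regions.
#'
#' @param model a `cluster_model` fitted on all individuals of the
#'   comparison (outgroup + selected lines)
#' @param kinship a `population_kinship`
#' @param grouping individual-to-population mapping (see
#'   [cluster_frequencies()])
#' @param q_threshold q-value threshold for regions (default 0.05)
#' @param merge_distance bp merge rule for significant loci (default 1 Mb)
#' @param runs `"all"` (average the statistic across EM runs, default) or
#'   `"best"`
#' @return list with `scan` (a `scan_result`) and `regions`
#'   (a `genomic_regions`).
#' @export
hapflk_scan <- function(model, kinship, grouping = NULL, q_threshold = 0.05,
                        merge_distance = 1e6, runs = "all") {
  run_idx <- if (identical(runs, "best")) model$best else seq_len(model$n_runs)
  lines <- setdiff(kinship$populations, kinship$outgroup)
  L <- nrow(model$snp_map)
  stat <- rep(0, L)
  for (r in run_idx) {
    cf <- cluster_frequencies(model, grouping, run = r)
    if (!all(c(lines, kinship$outgroup) %in% dimnames(cf)[[1L]])) {
      stop("cluster frequencies do not cover the kinship populations")
    }
    K <- dim(cf)[3L]
    for (l in seq_len(L)) {
      cfl <- cf[lines, l, , drop = FALSE]
      dim(cfl) <- c(length(lines), K)
      rownames(cfl) <- lines
      stat[l] <- stat[l] +
        hapflk_statistic(cfl, cf[kinship$outgroup, l, ], kinship)
    }
  }
  stat <- stat / length(run_idx)
  null <- fit_null_normal(stat)
  pv <- hapflk_pvalues(null, stat)
  qv <- compute_qvalues(pv)
  scan <- data.frame(snp = model$snp_map$id, chr = model$snp_map$chr,
                     bp = model$snp_map$bp, stat = stat, p_value = pv,
                     q_value = qv, stringsAsFactors = FALSE)
  scan <- structure(scan, class = c("scan_result", "data.frame"),
                    method = "hapFLK", populations = lines,
                    outgroup = kinship$outgroup, null = null)
  sig <- qv <= q_threshold
  regions <- merge_positions(scan$chr[sig], scan$bp[sig], scan$snp[sig],
                             -log10(pmax(pv[sig], 1e-300)), merge_distance)
  list(scan = scan, regions = regions)
}

#' Merge per-generation regions
#'
#' Regions detected at different generations that overlap or abut are
#' unioned; "abut" means the gap between them spans no genotyped SNP
#' (i.e. at most one inter-SNP interval). The output carries the sorted list
#' of generations of detection and the best (largest) score.
#'
#' @param per_generation_regions named list of `genomic_regions`, one per
#'   generation; names (or indices) are the generation labels.
#' @param snp_map SNP map data.frame (`chr`, `bp`) used to decide whether a
#'   gap contains a genotyped SNP.
#' @return a merged `genomic_regions` table with a `generations` column like
#'   `"1/4"`.
#' @export
merge_generation_regions <- function(per_generation_regions, snp_map) {
  gens <- names(per_generation_regions)
  if (is.null(gens)) gens <- as.character(seq_along(per_generation_regions))
  all <- do.call(rbind, lapply(seq_along(per_generation_regions), function(i) {
    r <- as.data.frame(per_generation_regions[[i]])
    if (nrow(r) == 0L) return(NULL)
    r$generation <- gens[i]
    r
  }))
  if (is.null(all) || nrow(all) == 0L) return(empty_regions())
  all <- all[order(all$chr, all$start, all$end), , drop = FALSE]
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    gsorted <- sort(unique(unlist(cur$gens)))
    data.frame(chr = cur$chr, start = cur$start, end = cur$end,
               peak_snp = cur$peak_snp, score = cur$score,
               generations = paste(gsorted, collapse = "/"),
               n_snp = cur$n_snp, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(all))) {
    r <- all[i, ]
    joinable <- !is.null(cur) && cur$chr == r$chr &&
      (r$start <= cur$end ||
         !any(snp_map$chr == r$chr & snp_map$bp > cur$end &
                snp_map$bp < r$start))
    if (joinable) {
      cur$end <- max(cur$end, r$end)
      cur$gens <- c(cur$gens, r$generation)
      cur$n_snp <- cur$n_snp + r$n_snp
      if (r$score > cur$score) {
        cur$score <- r$score
        cur$peak_snp <- r$peak_snp
      }
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- flush(cur)
      cur <- list(chr = r$chr, start = r$start, end = r$end,
                  peak_snp = r$peak_snp, score = r$score,
                  gens = r$generation, n_snp = r$n_snp)
    }
  }
  out[[length(out) + 1L]] <- flush(cur)
  out <- do.call(rbind, out)
  genomic_regions(chr = out$chr, start = out$start, end = out$end,
                  peak_snp = out$peak_snp, score = out$score,
                  generations = out$generations, n_snp = out$n_snp)
}

#' Region table in the reporting schema
#'
#' Adds length (Mb) and flanking marker ids to a region table, the layout
#' used for the selection-signature report.
#'
#' @param regions a `genomic_regions`
#' @param snp_map SNP map (`id`, `chr`, `bp`)
#' @param prefix name prefix, e.g. `"hapFLK"`
#' @return data.frame with columns name, chr, start, end, length_mb,
#'   marker_start, marker_end, minus_log10_p, generations.
#' @export
region_report <- function(regions, snp_map, prefix = "region") {
  if (nrow(regions) == 0L) {
    return(data.frame(name = character(), chr = character(),
                      start = numeric(), end = numeric(),
                      length_mb = numeric(), marker_start = character(),
                      marker_end = character(), minus_log10_p = numeric(),
                      generations = character(), stringsAsFactors = FALSE))
  }
  marker_at <- function(chr, bp) {
    i <- which(snp_map$chr == chr & snp_map$bp == bp)
    if (length(i)) snp_map$id[i[1L]] else NA_character_
  }
  regions <- regions[order(regions$chr, regions$start), , drop = FALSE]
  idx_in_chr <- unlist(lapply(split(seq_len(nrow(regions)), regions$chr),
                              seq_along), use.names = FALSE)
  idx_in_chr <- idx_in_chr[order(unlist(split(seq_len(nrow(regions)),
                                              regions$chr),
                                        use.names = FALSE))]
  nm <- paste0(prefix, "-", regions$chr,
               letters[pmin(idx_in_chr, length(letters))])
  data.frame(name = nm, chr = regions$chr,
             start = regions$start, end = regions$end,
             length_mb = round((regions$end - regions$start) / 1e6, 2),
             marker_start = mapply(marker_at, regions$chr, regions$start),
             marker_end = mapply(marker_at, regions$chr, regions$end),
             minus_log10_p = round(regions$score, 1),
             generations = regions$generations,
             stringsAsFactors = FALSE)
}
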