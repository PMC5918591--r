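## Single-SNP FLK scan: quadratic-form differentiation statistic against the
## drift kinship null, chi-squared p-values, q-value FDR and significant
## region construction.

P0_EPS <- 1e-6

#' FLK statistic at one SNP
#'
#' `(p - p0)' V^{-1} (p - p0)` with `V = p0 (1 - p0) F` restricted to the
#' selected lines, where `p0` is the ancestral (outgroup) frequency. Relies
#' only on the kinship matrix; populations with shared drift are handled by
#' the off-diagonal entries of `F`. A pseudo-inverse is used when `V` is
#' near-singular; the statistic is undefined (`NA`) when `p0` is within
#' `1e-6` of 0 or 1.
#'
#' @param p named vector of population frequencies (selected lines)
#' @param p0 ancestral / outgroup frequency
#' @param kinship a `population_kinship` covering all populations in `p`
#' @return the statistic value (`NA` when undefined).
#' @export
flk_statistic <- function(p, p0, kinship) {
  if (is.na(p0) || p0 < P0_EPS || p0 > 1 - P0_EPS) return(NA_real_)
  pops <- names(p)
  if (is.null(pops)) {
    pops <- setdiff(kinship$populations, kinship$outgroup)
    stopifnot(length(p) == length(pops))
  }
  if (!all(pops %in% kinship$populations)) {
    stop("kinship does not cover populations: ",
         paste(setdiff(pops, kinship$populations), collapse = ", "))
  }
  Fm <- kinship$F[pops, pops, drop = FALSE]
  V <- p0 * (1 - p0) * Fm
  d <- p - p0
  Vi <- safe_inverse(V)
  drop(t(d) %*% Vi %*% d)
}

safe_inverse <- function(V) {
  s <- svd(V)
  tol <- max(dim(V)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) stop("kinship covariance is identically zero")
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Genome-wide FLK scan
#'
#' @param freqs an `allele_freq_set` including the outgroup population
#' @param kinship a `population_kinship`
#' @param df chi-squared degrees of freedom for p-values; default = number of
#'   selected (non-outgroup) lines, i.e. 2 in a two-line design with the
#'   ancestral frequency fixed from the outgroup.
#' @param qvalue_method passed to [compute_qvalues()]
#' @return a `scan_result` data.frame (snp, chr, bp, stat, p_value, q_value)
#'   with metadata attributes; SNPs with undefined statistic (ancestral
#'   frequency at 0/1 or missing in a population) carry `NA` and are excluded
#'   from the FDR computation.
#' @export
flk_scan <- function(freqs, kinship, df = NULL, qvalue_method = "storey") {
  lines <- setdiff(kinship$populations, kinship$outgroup)
  if (!all(c(lines, kinship$outgroup) %in% colnames(freqs$freq))) {
    stop("frequency set does not cover the kinship populations")
  }
  if (is.null(df)) df <- length(lines)
  stopifnot(df >= 1)
  p0 <- freqs$freq[, kinship$outgroup]
  P <- freqs$freq[, lines, drop = FALSE]
  Fm <- kinship$F[lines, lines, drop = FALSE]
  Fi <- safe_inverse(Fm)
  D <- P - p0
  stat <- rowSums((D %*% Fi) * D) / (p0 * (1 - p0))
  bad <- is.na(p0) | p0 < P0_EPS | p0 > 1 - P0_EPS |
    rowSums(is.na(P)) > 0
  stat[bad] <- NA_real_
  pv <- pchisq(stat, df = df, lower.tail = FALSE)
  qv <- rep(NA_real_, length(pv))
  qv[!is.na(pv)] <- compute_qvalues(pv[!is.na(pv)], method = qvalue_method)
  out <- data.frame(snp = freqs$snp_map$id, chr = freqs$snp_map$chr,
                    bp = freqs$snp_map$bp, stat = stat, p_value = pv,
                    q_value = qv, stringsAsFactors = FALSE)
  structure(out, class = c("scan_result", "data.frame"),
            method = "FLK", populations = lines,
            outgroup = kinship$outgroup, df = df)
}

#' @export
print.scan_result <- function(x, ...) {
  cat(attr(x, "method"), "scan:", nrow(x), "SNPs;",
      sum(x$q_value <= 0.05, na.rm = TRUE), "with q <= 0.05\n")
  invisible(x)
}

#' Write a scan result as TSV
#' @param scan a `scan_result`
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' q-values for FDR control
#'
#' Storey q-values with a point estimate of the null proportion
#' `pi0 = #\{p > lambda\} / ((1 - lambda) m)` at `lambda = 0.5`; when the
#' estimate is unstable (0, > 1 or based on fewer than 20 p-values) the
#' procedure falls back to Benjamini-Hochberg (`pi0 = 1`). Output is monotone
#' non-decreasing in the p-value ranks.
#'
#' @param p_values vector of p-values in [0, 1]
#' @param method `"storey"` (with BH fallback) or `"bh"`
#' @return q-values in input order.
#' @export
compute_qvalues <- function(p_values, method = c("storey", "bh")) {
  method <- match.arg(method)
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  pi0 <- 1
  if (method == "storey" && m >= 20L) {
    lambda <- 0.5
    est <- mean(p_values > lambda) / (1 - lambda)
    if (is.finite(est) && est > 0 && est <= 1) pi0 <- est
  }
  o <- order(p_values)
  q <- pi0 * p_values[o] * m / seq_len(m)
  q <- rev(cummin(rev(pmin(q, 1))))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Build significant regions from an FLK scan
#'
#' SNPs with `q_value <= q_threshold` that do not fall inside any `exclude`
#' region (e.g. regions already detected by hapFLK) are merged into regions
#' when consecutive significant SNPs are closer than `merge_distance`;
#' isolated SNPs form single-SNP regions.
#'
#' @param scan a `scan_result` (sorted by position within chromosome)
#' @param q_threshold q-value significance threshold (default 0.05)
#' @param merge_distance merge rule in bp (default 1 Mb, strict `<`)
#' @param exclude optional `genomic_regions` to mask
#' @return a `genomic_regions` table; `score` is the peak `-log10(p)`.
#' @export
build_flk_regions <- function(scan, q_threshold = 0.05, merge_distance = 1e6,
                              exclude = NULL) {
  sig <- !is.na(scan$q_value) & scan$q_value <= q_threshold
  sig[sig] <- !in_any_region(scan$chr[sig], scan$bp[sig], exclude)
  merge_positions(scan$chr[sig], scan$bp[sig], scan$snp[sig],
                  -log10(pmax(scan$p_value[sig], 1e-300)), merge_distance)
}
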