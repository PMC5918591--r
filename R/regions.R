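## Genomic regions: the output unit of every scan. A plain data.frame with
## class "genomic_regions" and columns (name, chr, start, end, peak_snp,
## score, generations, n_snp). Coordinates are 1-based, intervals closed.

#' Construct a genomic-regions table
#'
#' @param chr chromosome labels
#' @param start,end 1-based closed interval bounds (bp)
#' @param name region names (auto-generated when `NULL`)
#' @param peak_snp id of the most significant SNP in each region
#' @param score region score (e.g. -log10 p or max BF)
#' @param generations character vector, e.g. `"1/2/5"` (generations of
#'   detection), or `NA`
#' @param n_snp number of significant SNPs in the region
#' @return a `genomic_regions` data.frame sorted by (chr, start).
#' @export
genomic_regions <- function(chr = character(), start = numeric(),
                            end = numeric(), name = NULL, peak_snp = NA,
                            score = NA, generations = NA, n_snp = NA) {
  n <- length(chr)
  stopifnot(length(start) == n, length(end) == n)
  if (n > 0 && any(end < start)) stop("region end < start")
  if (is.null(name)) {
    name <- if (n) paste0("region-", seq_len(n)) else character(0)
  }
  out <- data.frame(name = as.character(name), chr = as.character(chr),
                    start = as.numeric(start), end = as.numeric(end),
                    peak_snp = rep_len(as.character(peak_snp), n),
                    score = rep_len(as.numeric(score), n),
                    generations = rep_len(as.character(generations), n),
                    n_snp = rep_len(as.integer(n_snp), n),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chr, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genomic_regions", "data.frame")
  out
}

#' @export
print.genomic_regions <- function(x, ...) {
  cat("genomic_regions:", nrow(x), "region(s)\n")
  print.data.frame(x, ...)
  invisible(x)
}

empty_regions <- function() genomic_regions()

#' Merge significant positions into regions
#'
#' Shared region-building rule: positions on the same chromosome closer than
#' `merge_distance` (strictly) are merged into one region; isolated positions
#' form single-SNP regions.
#'
#' @param chr,bp,snp_id position and id of each significant SNP
#' @param score per-SNP score (larger = more significant)
#' @param merge_distance merge threshold in bp (strict `<`)
#' @return a `genomic_regions` table.
#' @keywords internal
merge_positions <- function(chr, bp, snp_id, score, merge_distance) {
  if (length(bp) == 0L) return(empty_regions())
  o <- order(chr, bp)
  chr <- chr[o]; bp <- bp[o]; snp_id <- snp_id[o]; score <- score[o]
  newgrp <- c(TRUE, chr[-1L] != chr[-length(chr)] |
                diff(bp) >= merge_distance)
  grp <- cumsum(newgrp)
  res <- lapply(split(seq_along(grp), grp), function(ii) {
    k <- ii[which.max(score[ii])]
    data.frame(chr = chr[ii[1L]], start = bp[ii[1L]], end = bp[ii[length(ii)]],
               peak_snp = snp_id[k], score = score[k],
               n_snp = length(ii), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  genomic_regions(chr = res$chr, start = res$start, end = res$end,
                  peak_snp = res$peak_snp, score = res$score,
                  n_snp = res$n_snp)
}

in_any_region <- function(chr, bp, regions) {
  if (is.null(regions) || nrow(regions) == 0L) {
    return(rep(FALSE, length(bp)))
  }
  out <- rep(FALSE, length(bp))
  for (i in seq_len(nrow(regions))) {
    out <- out | (chr == regions$chr[i] & bp >= regions$start[i] &
                    bp <= regions$end[i])
  }
  out
}

#' Write regions as TSV (1-based closed) or BED (0-based half-open)
#'
#' @param regions a `genomic_regions` table
#' @param path output file
#' @param format `"tsv"` keeps the package's 1-based closed convention;
#'   `"bed"` converts to BED (start - 1, end).
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bed <- data.frame(chrom = regions$chr, chromStart = regions$start - 1,
                      chromEnd = regions$end, name = regions$name,
                      score = regions$score)
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
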