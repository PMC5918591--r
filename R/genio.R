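## Genotype / phenotype I/O, QC filters and per-population allele frequencies.
##
## The exchange object for the whole package is the `genotype_table`: an
## individuals x SNPs dosage matrix (0/1/2/NA counts of the "counted" allele)
## plus a SNP map (id, chromosome, bp, allele labels) and individual metadata
## (id, line, generation, sex, hatch).

#' Construct a genotype table
#'
#' @param dosages integer/numeric matrix, individuals in rows, SNPs in
#'   columns; entries must be 0, 1, 2 or `NA`.
#' @param snp_map data.frame with columns `id`, `chr`, `bp` and optionally
#'   `allele1`, `allele2` (labels of the uncounted / counted allele).
#' @param individuals data.frame with column `id` and optionally `line`,
#'   `generation`, `sex`, `hatch`.
#' @return An object of class `genotype_table`.
#' @details Invariants enforced: dosages in \{0,1,2,NA\}; bp positions
#'   strictly increasing within each chromosome; individual and SNP ids
#'   unique. Positions are 1-based; intervals elsewhere in the package are
#'   closed.
#' @export
genotype_table <- function(dosages, snp_map, individuals) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  snp_map <- as.data.frame(snp_map, stringsAsFactors = FALSE)
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chr", "bp") %in% names(snp_map)),
            "id" %in% names(individuals))
  if (is.null(snp_map$allele1)) snp_map$allele1 <- rep("A", nrow(snp_map))
  if (is.null(snp_map$allele2)) snp_map$allele2 <- rep("B", nrow(snp_map))
  for (col in c("line", "sex")) {
    if (is.null(individuals[[col]])) individuals[[col]] <- NA_character_
  }
  for (col in c("generation", "hatch")) {
    if (is.null(individuals[[col]])) individuals[[col]] <- NA_integer_
  }
  if (nrow(dosages) != nrow(individuals)) {
    stop("structural error: ", nrow(dosages), " dosage rows but ",
         nrow(individuals), " individuals")
  }
  if (ncol(dosages) != nrow(snp_map)) {
    stop("structural error: ", ncol(dosages), " dosage columns but ",
         nrow(snp_map), " SNP map rows")
  }
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("invalid dosage values (must be 0, 1, 2 or NA)")
  if (anyDuplicated(snp_map$id)) stop("duplicated SNP ids")
  if (anyDuplicated(individuals$id)) stop("duplicated individual ids")
  for (ch in unique(snp_map$chr)) {
    bp <- snp_map$bp[snp_map$chr == ch]
    if (length(bp) > 1L && any(diff(bp) <= 0)) {
      stop("bp positions not strictly increasing on chromosome ", ch)
    }
  }
  rownames(dosages) <- individuals$id
  colnames(dosages) <- snp_map$id
  structure(list(dosages = dosages, snp_map = snp_map,
                 individuals = individuals),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "SNPs on", length(unique(x$snp_map$chr)),
      "chromosome(s)\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing rate: %.3f\n", miss))
  invisible(x)
}

#' Number of individuals / SNPs
#' @param gt a `genotype_table`
#' @return integer count.
#' @export
n_individuals <- function(gt) nrow(gt$dosages)

#' @rdname n_individuals
#' @export
n_snps <- function(gt) ncol(gt$dosages)

#' Subset a genotype table
#'
#' @param gt a `genotype_table`
#' @param individuals logical/integer/character index of individuals to keep
#' @param snps logical/integer/character index of SNPs to keep
#' @return the subsetted `genotype_table` (order preserved as given).
#' @export
subset_genotypes <- function(gt, individuals = NULL, snps = NULL) {
  ii <- if (is.null(individuals)) seq_len(nrow(gt$dosages)) else individuals
  if (is.character(ii)) ii <- match(ii, gt$individuals$id)
  jj <- if (is.null(snps)) seq_len(ncol(gt$dosages)) else snps
  if (is.character(jj)) jj <- match(jj, gt$snp_map$id)
  genotype_table(gt$dosages[ii, jj, drop = FALSE],
                 gt$snp_map[jj, , drop = FALSE],
                 gt$individuals[ii, , drop = FALSE])
}

## ---------------------------------------------------------------- readers

#' Read genotypes from PLINK-style or TSV files
#'
#' @param path file prefix: `<path>.ped`/`<path>.map` for `plink-text`,
#'   `<path>.bed`/`.bim`/`.fam` for `plink-binary`, and
#'   `<path>.geno.tsv`/`.snps.tsv`/`.inds.tsv` for `tsv`.
#' @param format one of `"plink-text"`, `"plink-binary"`, `"tsv"`.
#' @return a `genotype_table`.
#' @details For `plink-text` the counted allele at each SNP is the
#'   alphabetically larger of the two observed alleles ("B" when the file was
#'   written by [write_genotypes()]); `0` is the missing code. For
#'   `plink-binary` the counted allele is A1 (5th column of the .bim), as in
#'   PLINK's additive recoding.
#' @export
read_genotypes <- function(path,
                           format = c("plink-text", "plink-binary", "tsv")) {
  format <- match.arg(format)
  switch(format,
         "plink-text"   = read_plink_text(path),
         "plink-binary" = read_plink_binary(path),
         "tsv"          = read_geno_tsv(path))
}

file_or_stop <- function(f) {
  if (!file.exists(f)) stop("file not found: ", f)
  f
}

parse_fam_like <- function(tab) {
  data.frame(id = as.character(tab[[2L]]),
             line = as.character(tab[[1L]]),
             generation = NA_integer_,
             sex = c("M", "F", NA)[match(as.integer(tab[[5L]]), c(1L, 2L),
                                         nomatch = 3L)],
             hatch = NA_integer_,
             stringsAsFactors = FALSE)
}

read_map_file <- function(f) {
  map <- read.table(file_or_stop(f), header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(map) < 4L) stop("malformed map file (", f, "): need 4 columns")
  data.frame(id = as.character(map[[2L]]), chr = as.character(map[[1L]]),
             bp = as.numeric(map[[4L]]), stringsAsFactors = FALSE)
}

read_plink_text <- function(path) {
  ped_f <- file_or_stop(paste0(path, ".ped"))
  map <- read_map_file(paste0(path, ".map"))
  lines <- readLines(ped_f)
  lines <- lines[nzchar(trimws(lines))]
  n_snp <- nrow(map)
  n_ind <- length(lines)
  a1 <- matrix(NA_character_, n_ind, n_snp)
  a2 <- matrix(NA_character_, n_ind, n_snp)
  fam <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    tok <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1L]]
    if (length(tok) != 6L + 2L * n_snp) {
      stop("malformed .ped at line ", i, ": expected ", 6L + 2L * n_snp,
           " fields, found ", length(tok))
    }
    fam[[i]] <- tok[1:6]
    g <- tok[-(1:6)]
    a1[i, ] <- g[seq(1L, by = 2L, length.out = n_snp)]
    a2[i, ] <- g[seq(2L, by = 2L, length.out = n_snp)]
  }
  fam <- as.data.frame(do.call(rbind, fam), stringsAsFactors = FALSE)
  ind <- parse_fam_like(fam)
  dos <- matrix(NA_real_, n_ind, n_snp)
  allele1 <- allele2 <- character(n_snp)
  for (j in seq_len(n_snp)) {
    al <- c(a1[, j], a2[, j])
    al[al == "0"] <- NA
    obs <- sort(unique(al[!is.na(al)]))
    if (length(obs) > 2L) stop("SNP ", map$id[j], " has >2 alleles")
    # counted allele: alphabetically larger of the observed pair
    allele1[j] <- if (length(obs) >= 1L) obs[1L] else "A"
    allele2[j] <- if (length(obs) == 2L) obs[2L] else "B"
    cnt <- (a1[, j] == allele2[j]) + (a2[, j] == allele2[j])
    cnt[a1[, j] == "0" | a2[, j] == "0"] <- NA
    dos[, j] <- cnt
  }
  map$allele1 <- allele1
  map$allele2 <- allele2
  genotype_table(dos, map, ind)
}

read_plink_binary <- function(path) {
  bed_f <- file_or_stop(paste0(path, ".bed"))
  bim <- read.table(file_or_stop(paste0(path, ".bim")), header = FALSE,
                    stringsAsFactors = FALSE)
  fam <- read.table(file_or_stop(paste0(path, ".fam")), header = FALSE,
                    stringsAsFactors = FALSE)
  map <- data.frame(id = as.character(bim[[2L]]), chr = as.character(bim[[1L]]),
                    bp = as.numeric(bim[[4L]]),
                    allele1 = as.character(bim[[6L]]),
                    allele2 = as.character(bim[[5L]]),
                    stringsAsFactors = FALSE)
  ind <- parse_fam_like(fam)
  n_ind <- nrow(fam); n_snp <- nrow(bim)
  raw <- readBin(bed_f, "raw", n = file.size(bed_f))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    stop("malformed .bed file (bad magic number): ", bed_f)
  }
  if (raw[3L] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  bpl <- ceiling(n_ind / 4)
  if (length(raw) != 3L + bpl * n_snp) {
    stop("structural error: .bed size inconsistent with .bim/.fam dimensions")
  }
  body <- raw[-(1:3)]
  # decode 2-bit genotypes; PLINK codes: 00 hom A1, 01 missing, 10 het, 11 hom A2
  lut <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0) # dosage of A1
  dos <- matrix(NA_real_, n_ind, n_snp)
  idx <- as.integer(body)
  two_bits <- cbind(idx %% 4L, (idx %/% 4L) %% 4L,
                    (idx %/% 16L) %% 4L, (idx %/% 64L) %% 4L)
  for (j in seq_len(n_snp)) {
    block <- two_bits[((j - 1L) * bpl + 1L):(j * bpl), , drop = FALSE]
    codes <- as.vector(t(block))[seq_len(n_ind)]
    dos[, j] <- lut[codes + 1L]
  }
  genotype_table(dos, map, ind)
}

read_geno_tsv <- function(path) {
  g <- read.table(file_or_stop(paste0(path, ".geno.tsv")), header = TRUE,
                  sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  snps <- read.table(file_or_stop(paste0(path, ".snps.tsv")), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  inds <- read.table(file_or_stop(paste0(path, ".inds.tsv")), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  ids <- as.character(g[[1L]])
  dos <- as.matrix(g[, -1L, drop = FALSE])
  if (!identical(colnames(dos), as.character(snps$id))) {
    stop("structural error: SNP ids in .geno.tsv and .snps.tsv disagree")
  }
  inds <- inds[match(ids, inds$id), , drop = FALSE]
  if (anyNA(inds$id)) stop("structural error: individuals missing from .inds.tsv")
  genotype_table(dos, snps, inds)
}

#' Write a genotype table
#'
#' @param gt a `genotype_table`
#' @param path file prefix (see [read_genotypes()] for the files produced).
#' @param format output format.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path,
                            format = c("plink-text", "plink-binary", "tsv")) {
  format <- match.arg(format)
  switch(format,
         "plink-text" = write_plink_text(gt, path),
         "plink-binary" = write_plink_binary(gt, path),
         "tsv" = write_geno_tsv(gt, path))
  invisible(path)
}

fam_frame <- function(gt) {
  ind <- gt$individuals
  data.frame(fid = ifelse(is.na(ind$line), "0", ind$line), iid = ind$id,
             pat = 0, mat = 0,
             sex = ifelse(is.na(ind$sex), 0L, ifelse(ind$sex == "M", 1L, 2L)),
             pheno = -9)
}

write_plink_text <- function(gt, path) {
  map <- gt$snp_map
  write.table(data.frame(map$chr, map$id, 0, map$bp),
              paste0(path, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n_snp <- ncol(gt$dosages)
  fam <- fam_frame(gt)
  con <- file(paste0(path, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(gt$dosages))) {
    d <- gt$dosages[i, ]
    a <- ifelse(is.na(d), "0", ifelse(d >= 1, map$allele2, map$allele1))
    b <- ifelse(is.na(d), "0", ifelse(d == 2, map$allele2, map$allele1))
    writeLines(paste(c(unlist(fam[i, ]), as.vector(rbind(a, b))),
                     collapse = " "), con)
  }
}

write_plink_binary <- function(gt, path) {
  map <- gt$snp_map
  write.table(data.frame(map$chr, map$id, 0, map$bp, map$allele2, map$allele1),
              paste0(path, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(fam_frame(gt), paste0(path, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n_ind <- nrow(gt$dosages)
  bpl <- ceiling(n_ind / 4)
  con <- file(paste0(path, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  code_of <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  for (j in seq_len(ncol(gt$dosages))) {
    codes <- code_of(gt$dosages[, j])
    codes <- c(codes, rep(0L, bpl * 4L - n_ind))
    m <- matrix(codes, nrow = 4L)
    bytes <- m[1L, ] + 4L * m[2L, ] + 16L * m[3L, ] + 64L * m[4L, ]
    writeBin(as.raw(bytes), con)
  }
}

write_geno_tsv <- function(gt, path) {
  g <- data.frame(id = gt$individuals$id, gt$dosages, check.names = FALSE)
  write.table(g, paste0(path, ".geno.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(gt$snp_map, paste0(path, ".snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gt$individuals, paste0(path, ".inds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Read a phenotype table
#'
#' Tab-separated file with a header; expected columns include `id`, `line`,
#' `generation`, `sex`, `hatch` and one column per trait.
#'
#' @param path file path
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  read.table(file_or_stop(path), header = TRUE, sep = "\t",
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------- QC

#' Apply chip-style QC filters
#'
#' Individuals with call rate strictly greater than `ind_callrate_min` are
#' retained first; SNP-level MAF and call rate are then computed on the
#' retained individuals, and SNPs with MAF strictly greater than `maf_min`
#' and call rate strictly greater than `snp_callrate_min` are retained.
#' Thresholds are strict inequalities ("higher than"), so boundary SNPs are
#' removed. Order of individuals and SNPs is preserved.
#'
#' @param gt a `genotype_table`
#' @param maf_min minor-allele-frequency threshold (default 0.05)
#' @param snp_callrate_min per-SNP call-rate threshold (default 0.95)
#' @param ind_callrate_min per-individual call-rate threshold (default 0.95)
#' @return the filtered `genotype_table`.
#' @export
filter_genotypes <- function(gt, maf_min = 0.05, snp_callrate_min = 0.95,
                             ind_callrate_min = 0.95) {
  stopifnot(maf_min >= 0, maf_min <= 1, snp_callrate_min >= 0,
            snp_callrate_min <= 1, ind_callrate_min >= 0,
            ind_callrate_min <= 1)
  d <- gt$dosages
  keep_ind <- rowMeans(!is.na(d)) > ind_callrate_min
  d <- d[keep_ind, , drop = FALSE]
  call <- colMeans(!is.na(d))
  f <- colMeans(d, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  maf <- pmin(f, 1 - f)
  keep_snp <- maf > maf_min & call > snp_callrate_min
  if (!any(keep_snp)) {
    warning("all SNPs removed by QC filters: empty panel")
  }
  subset_genotypes(gt, individuals = which(keep_ind), snps = which(keep_snp))
}

## ------------------------------------------------------- allele frequencies

#' Per-population allele frequencies
#'
#' @param gt a `genotype_table`
#' @param grouping population label per individual: either a vector of length
#'   `n_individuals(gt)` (in table order), a named vector keyed by individual
#'   id, or `NULL` to use the `line` metadata column.
#' @return an `allele_freq_set`: list with `freq` (SNP x population matrix of
#'   counted-allele frequencies, `NA` when a population has no call at a SNP),
#'   `counts` (non-missing allele counts) and the `snp_map`.
#' @export
allele_frequencies <- function(gt, grouping = NULL) {
  if (is.null(grouping)) grouping <- gt$individuals$line
  if (!is.null(names(grouping))) {
    grouping <- grouping[gt$individuals$id]
    if (anyNA(names(grouping))) stop("grouping misses some individuals")
  }
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(gt$dosages) || anyNA(grouping)) {
    stop("every individual must be assigned to exactly one population")
  }
  pops <- unique(grouping)
  d <- gt$dosages
  freq <- matrix(NA_real_, ncol(d), length(pops),
                 dimnames = list(gt$snp_map$id, pops))
  counts <- matrix(0, ncol(d), length(pops),
                   dimnames = list(gt$snp_map$id, pops))
  for (p in pops) {
    dp <- d[grouping == p, , drop = FALSE]
    n_alleles <- 2 * colSums(!is.na(dp))
    s <- colSums(dp, na.rm = TRUE)
    fr <- ifelse(n_alleles > 0, s / n_alleles, NA_real_)
    freq[, p] <- fr
    counts[, p] <- n_alleles
  }
  structure(list(freq = freq, counts = counts, snp_map = gt$snp_map),
            class = "allele_freq_set")
}

#' @export
print.allele_freq_set <- function(x, ...) {
  cat("allele_freq_set:", nrow(x$freq), "SNPs x", ncol(x$freq),
      "populations (", paste(colnames(x$freq), collapse = ", "), ")\n")
  invisible(x)
}
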