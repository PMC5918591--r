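## Population kinship from genome-wide Reynolds distances.
##
## The drift null model behind FLK/hapFLK: a rooted population tree estimated
## by neighbour joining on pairwise Reynolds distances, with the founder
## cohort (G0) as outgroup, summarised by a kinship matrix F where F[i,j] is
## the drift shared by populations i and j since the root and F[i,i] the
## per-population inbreeding coefficient.

#' Pairwise Reynolds distances between populations
#'
#' Coancestry-based distances appropriate for pure-drift divergence,
#' computed with a bias-corrected ratio-of-sums estimator across loci.
#' The estimator is calibrated on the drift scale: under pure drift from a
#' common ancestor, `d(i, j)` estimates `F_i + F_j`, the summed per-branch
#' inbreeding coefficients, so neighbour-joining branch lengths can be read
#' directly in drift units.
#'
#' Per locus, with counted-allele frequencies `p_i`, `p_j` and allele counts
#' `c_i`, `c_j`:
#' `num = (p_i - p_j)^2 - p_i(1-p_i)/(c_i-1) - p_j(1-p_j)/(c_j-1)` and
#' `den = pbar(1-pbar) + num/4` with `pbar = (p_i+p_j)/2`; the distance is
#' `sum(num) / sum(den)` over loci, clamped at 0.
#'
#' @param freqs an `allele_freq_set` (>= 2 populations); SNPs monomorphic in
#'   every population are skipped.
#' @return a symmetric distance matrix with zero diagonal, class `dist`-like
#'   plain matrix.
#' @export
reynolds_distances <- function(freqs) {
  f <- freqs$freq
  cnt <- freqs$counts
  if (ncol(f) < 2L) stop("need at least 2 populations")
  poly <- apply(f, 1L, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && any(x > 0) && any(x < 1)
  })
  f <- f[poly, , drop = FALSE]
  cnt <- cnt[poly, , drop = FALSE]
  pops <- colnames(f)
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in (i + 1L):length(pops)) {
      pi <- f[, i]; pj <- f[, j]
      ci <- cnt[, i]; cj <- cnt[, j]
      ok <- !is.na(pi) & !is.na(pj) & ci > 1 & cj > 1
      vi <- pi[ok] * (1 - pi[ok]) / (ci[ok] - 1)
      vj <- pj[ok] * (1 - pj[ok]) / (cj[ok] - 1)
      num <- (pi[ok] - pj[ok])^2 - vi - vj
      pbar <- (pi[ok] + pj[ok]) / 2
      den <- pbar * (1 - pbar) + num / 4
      d[i, j] <- d[j, i] <- max(0, sum(num) / sum(den))
    }
  }
  d
}

#' Build the population kinship from a distance matrix
#'
#' Estimates a neighbour-joining tree from `dist`, roots it at the midpoint
#' of the outgroup terminal branch (the outgroup is the ancestral reference,
#' its drift is set to 0), and converts branch lengths into the kinship
#' matrix: `F[i, j]` is the summed length of branches shared by the
#' root-to-i and root-to-j paths, in drift units.
#'
#' @param dist symmetric distance matrix with population names
#' @param outgroup name of the outgroup population (e.g. `"G0"`)
#' @return a `population_kinship`: list with `populations` (outgroup first),
#'   `F` (kinship matrix), `inbreeding` (diagonal), `tree` (rooted
#'   `ape::phylo`).
#' @export
build_kinship <- function(dist, outgroup) {
  pops <- colnames(dist)
  if (is.null(pops)) pops <- rownames(dist)
  if (!outgroup %in% pops) stop("outgroup ", outgroup, " not in distance matrix")
  if (nrow(dist) == 2L) {
    # degenerate NJ: single branch split at midpoint is not meaningful with
    # an outgroup; assign the full distance to the non-outgroup branch
    other <- setdiff(pops, outgroup)
    Fm <- matrix(0, 2, 2, dimnames = list(c(outgroup, other),
                                          c(outgroup, other)))
    Fm[other, other] <- dist[outgroup, other]
    tree <- ape::read.tree(text = sprintf("(%s:0,%s:%f);", outgroup, other,
                                          dist[outgroup, other]))
    return(new_population_kinship(Fm, tree, outgroup))
  }
  tree <- ape::nj(as.dist(dist))
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  # patristic distances on the NJ tree
  pd <- ape::cophenetic.phylo(tree)
  lo <- tree$edge.length[tree$edge[, 2L] ==
                           which(tree$tip.label == outgroup)]
  sel <- setdiff(pops, outgroup)
  k <- length(sel)
  Fm <- matrix(0, k + 1L, k + 1L,
               dimnames = list(c(outgroup, sel), c(outgroup, sel)))
  for (a in sel) {
    Fm[a, a] <- max(0, pd[a, outgroup] - lo / 2)
    for (b in sel) {
      if (a == b) next
      sh <- (pd[a, outgroup] + pd[b, outgroup] - pd[a, b]) / 2 - lo / 2
      Fm[a, b] <- max(0, sh)
    }
  }
  # enforce the tree-metric property F[i,j] <= min(F[i,i], F[j,j])
  for (a in sel) for (b in sel) {
    if (a != b) Fm[a, b] <- min(Fm[a, b], Fm[a, a], Fm[b, b])
  }
  rtree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  new_population_kinship(Fm, rtree, outgroup)
}

new_population_kinship <- function(Fm, tree, outgroup) {
  structure(list(populations = colnames(Fm), F = Fm,
                 inbreeding = diag(Fm), tree = tree, outgroup = outgroup),
            class = "population_kinship")
}

#' @export
print.population_kinship <- function(x, ...) {
  cat("population_kinship (outgroup:", x$outgroup, ")\n")
  print(round(x$F, 4))
  invisible(x)
}

#' Estimate population kinship from allele frequencies
#'
#' Convenience wrapper: [reynolds_distances()] then [build_kinship()].
#'
#' @param freqs an `allele_freq_set`
#' @param outgroup outgroup population name
#' @return a `population_kinship`.
#' @export
estimate_kinship <- function(freqs, outgroup) {
  build_kinship(reynolds_distances(freqs), outgroup)
}

#' Export the population tree as Newick / the kinship matrix as TSV
#'
#' @param kin a `population_kinship`
#' @param tree_path,f_path output files (either may be `NULL` to skip)
#' @return invisibly, `kin`.
#' @export
export_kinship <- function(kin, tree_path = NULL, f_path = NULL) {
  if (!is.null(tree_path)) ape::write.tree(kin$tree, file = tree_path)
  if (!is.null(f_path)) {
    write.table(data.frame(population = rownames(kin$F), kin$F,
                           check.names = FALSE),
                f_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(kin)
}

#' Convert between inbreeding coefficient and effective population size
#'
#' In a Wright-Fisher population of `N` diploid individuals,
#' `F = 1 - (1 - 1/(2N))^g` after `g` generations. `ne_from_inbreeding`
#' solves this for `N`; `inbreeding_from_ne` evaluates it forward.
#'
#' @param F inbreeding coefficient in (0, 1); `F <= 0` returns `Inf`
#'   (no detectable drift), `F >= 1` is an error.
#' @param g number of generations (>= 1)
#' @return effective size as a (non-integer) diploid count.
#' @examples
#' ne_from_inbreeding(0.08, 5)   # ~30 diploid reproducers
#' @export
ne_from_inbreeding <- function(F, g) {
  stopifnot(g >= 1)
  if (F >= 1) stop("F must be < 1")
  if (F <= 0) return(Inf)
  1 / (2 * (1 - (1 - F)^(1 / g)))
}

#' @rdname ne_from_inbreeding
#' @param N diploid effective population size (> 0)
#' @export
inbreeding_from_ne <- function(N, g) {
  stopifnot(N > 0, g >= 1)
  1 - (1 - 1 / (2 * N))^g
}
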