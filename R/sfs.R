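#' Which loci enter the allele frequency spectrum
#'
#' The SFS needs one focal allele and a uniform sample size per bin, so a
#' locus is included only if (a) all its calls fall on the first two allele
#' indices (monomorphic and biallelic loci; tri-/tetra-allelic loci are
#' excluded) and (b) every requested population is completely genotyped there
#' (no missing calls). Exclusion tallies are returned so runs can report them.
#'
#' @param table an [build_allele_counts()] table
#' @param pops population labels or indices the spectrum will span
#' @return list with `loci` (integer indices included), `n_excluded_missing`,
#'   `n_excluded_multiallelic`, and `n_k` (full chromosome sample size per
#'   requested population).
#' @export
sfs_locus_set <- function(table, pops) {
  ks <- vapply(pops, function(p) pop_index(table, p), integer(1))
  n_full <- table$n_ind_pop[ks] * table$ploidy
  multi <- rowSums(table$counts[, , 3:4, drop = FALSE]) > 0
  complete <- rep(TRUE, nrow(table$n_called))
  for (i in seq_along(ks)) {
    complete <- complete & table$n_called[, ks[i]] == n_full[i]
  }
  list(loci = which(!multi & complete),
       n_excluded_missing = sum(!complete),
       n_excluded_multiallelic = sum(multi & complete),
       n_k = n_full)
}

#' Single-population allele frequency spectrum
#'
#' Histogram over loci of the focal-allele count among the population's `n`
#' chromosomes. Folded mode (default) uses the minor allele (a tie at `n/2`
#' falls in bin `n/2`); unfolded mode uses the designated allele — allele
#' index 2, i.e. the first ALT for VCF input, the second-seen symbol for arp.
#' Only the loci selected by [sfs_locus_set()] contribute.
#'
#' @param table an [build_allele_counts()] table
#' @param pop population label or index
#' @param folded logical, default `TRUE`
#' @return list of class `sfs`: `spectrum` (integer vector, bins `0..n`),
#'   `n` (chromosomes), `folded`, `n_loci` (mass), plus the exclusion tallies
#'   of [sfs_locus_set()].
#' @export
single_sfs <- function(table, pop, folded = TRUE) {
  sel <- sfs_locus_set(table, pop)
  k <- pop_index(table, pop)
  n <- sel$n_k[1]
  counts2 <- table$counts[sel$loci, k, 2L]
  if (length(sel$loci) == 0L) {
    warning("no biallelic loci with complete data; empty spectrum")
  }
  focal <- if (folded) pmin(counts2, n - counts2) else counts2
  spectrum <- tabulate(focal + 1L, nbins = n + 1L)
  structure(list(spectrum = spectrum, n = n, folded = folded,
                 n_loci = length(sel$loci),
                 n_excluded_missing = sel$n_excluded_missing,
                 n_excluded_multiallelic = sel$n_excluded_multiallelic,
                 pop = table$populations[k]),
            class = "sfs")
}

#' Joint (multi-population) allele frequency spectrum
#'
#' Array of dimension `s` with shape `(n_1+1) x ... x (n_s+1)`; each included
#' locus increments the cell indexed by its per-population focal-allele
#' counts. The locus set is the intersection of complete-data biallelic loci
#' across the requested populations. Folded mode folds on the *pooled* minor
#' allele: a locus whose designated-allele total exceeds half the pooled
#' chromosomes is complemented; an exact tie keeps whichever of the cell and
#' its complement is lexicographically smaller, so folding the unfolded
#' spectrum reproduces the folded one cell for cell.
#'
#' @param table an [build_allele_counts()] table
#' @param pops ordered population labels or indices, length >= 2
#' @param folded logical, default `TRUE`
#' @return list of class `joint_sfs`: `spectrum` (integer array), `n_k`,
#'   `pops`, `folded`, `n_loci`, exclusion tallies.
#' @export
joint_sfs <- function(table, pops = table$populations, folded = TRUE) {
  if (length(pops) < 2L) stop("joint SFS needs at least 2 populations")
  sel <- sfs_locus_set(table, pops)
  ks <- vapply(pops, function(p) pop_index(table, p), integer(1))
  n_k <- sel$n_k
  cmat <- table$counts[sel$loci, ks, 2L, drop = FALSE][, , 1L]
  cmat <- matrix(cmat, nrow = length(sel$loci), ncol = length(ks))
  if (folded) cmat <- fold_cells(cmat, n_k)
  # linear index into the row-major-agnostic R array (first axis fastest)
  dims <- n_k + 1L
  idx <- cmat[, 1L]
  mult <- 1L
  for (j in seq_along(ks)[-1L]) {
    mult <- mult * dims[j - 1L]
    idx <- idx + cmat[, j] * mult
  }
  spectrum <- array(tabulate(idx + 1L, nbins = prod(dims)), dim = dims)
  structure(list(spectrum = spectrum, n_k = n_k,
                 pops = table$populations[ks], folded = folded,
                 n_loci = length(sel$loci),
                 n_excluded_missing = sel$n_excluded_missing,
                 n_excluded_multiallelic = sel$n_excluded_multiallelic),
            class = "joint_sfs")
}

# Fold per-locus count vectors on the pooled minor allele; ties keep the
# lexicographically smaller of (c, n - c).
fold_cells <- function(cmat, n_k) {
  tot <- rowSums(cmat); half <- sum(n_k) / 2
  comp <- sweep(-cmat, 2L, n_k, "+")
  flip <- tot > half
  undecided <- which(tot == half)     # tie: first differing axis decides
  for (j in seq_along(n_k)) {
    if (length(undecided) == 0L) break
    gt <- cmat[undecided, j] > comp[undecided, j]
    lt <- cmat[undecided, j] < comp[undecided, j]
    flip[undecided[gt]] <- TRUE
    undecided <- undecided[!gt & !lt]
  }
  cmat[flip, ] <- comp[flip, ]
  cmat
}

#' Fold an unfolded joint spectrum
#'
#' Sums each cell `c` with its complement `n - c`, using the same pooled-minor
#' and lexicographic tie rule as [joint_sfs()], so the result equals the
#' directly folded spectrum exactly.
#'
#' @param jsfs an unfolded `joint_sfs`
#' @return a folded `joint_sfs`.
#' @export
fold_joint_sfs <- function(jsfs) {
  stopifnot(inherits(jsfs, "joint_sfs"), !jsfs$folded)
  dims <- jsfs$n_k + 1L
  cells <- as.matrix(expand.grid(lapply(dims, function(d) 0:(d - 1L))))
  folded_cells <- fold_cells(cells, jsfs$n_k)
  idx <- folded_cells[, 1L]
  mult <- 1L
  for (j in seq_along(dims)[-1L]) {
    mult <- mult * dims[j - 1L]
    idx <- idx + folded_cells[, j] * mult
  }
  out <- array(0L, dim = dims)
  for (cell in seq_len(nrow(cells))) {
    out[idx[cell] + 1L] <- out[idx[cell] + 1L] + jsfs$spectrum[cell]
  }
  jsfs$spectrum <- out
  jsfs$folded <- TRUE
  jsfs
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("<sfs> pop %s, n = %d chromosomes, %s, mass %d loci\n",
              x$pop, x$n, if (x$folded) "folded" else "unfolded", x$n_loci))
  print(stats::setNames(x$spectrum, 0:x$n))
  invisible(x)
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf("<joint_sfs> pops %s, %s, mass %d loci\n",
              paste(x$pops, collapse = " x "),
              if (x$folded) "folded" else "unfolded", x$n_loci))
  invisible(x)
}
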