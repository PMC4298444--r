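#' Tally allele calls per locus, population and allele
#'
#' The allele-count table is the single substrate every statistic is computed
#' from. Counting follows the complete-genotype rule: a diploid individual
#' with any missing allele at a locus contributes nothing to that locus (so
#' `n_called = 2 * n_ind_called` always holds, which the heterozygosity
#' estimators rely on).
#'
#' @param panel a [genotype_panel()]
#' @param assignment a [pop_assignment()] covering all individuals
#' @param chunk_cols internal: loci are tallied in column blocks of this size
#'   to bound temporary memory on very wide panels.
#' @return object of class `allele_count_table`: list with
#'   \describe{
#'     \item{counts}{integer array `[locus, pop, allele 1..4]` of called
#'       chromosomes}
#'     \item{het_obs}{integer `[locus, pop]`, heterozygous individuals
#'       (all zero for haploid panels)}
#'     \item{het_by_allele}{integer `[locus, pop, allele]`, individuals
#'       heterozygous *for* that allele (carrying exactly one copy); needed by
#'       the Weir-Cockerham components}
#'     \item{n_called}{integer `[locus, pop]` called chromosomes}
#'     \item{n_ind_called}{integer `[locus, pop]` individuals with a complete
#'       genotype}
#'     \item{populations, ploidy, n_ind_pop, locus_id}{bookkeeping}
#'   }
#' @export
build_allele_counts <- function(panel, assignment, chunk_cols = 200000L) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(assignment, "pop_assignment"))
  n_ind <- n_individuals(panel)
  if (length(assignment$pop_of) != n_ind) {
    stop("assignment covers ", length(assignment$pop_of),
         " individuals but panel has ", n_ind)
  }
  pops <- assignment$populations
  sizes <- table(assignment$pop_of)
  if (any(sizes == 0)) {
    stop("population(s) with zero individuals: ",
         paste(names(sizes)[sizes == 0], collapse = ", "))
  }
  M <- n_loci(panel); K <- length(pops); P <- panel$ploidy
  counts <- array(0L, dim = c(M, K, 4L))
  het_obs <- matrix(0L, M, K)
  het_by_allele <- array(0L, dim = c(M, K, 4L))
  n_ind_called <- matrix(0L, M, K)

  ind_of_pop <- split(seq_len(n_ind), assignment$pop_of)
  blocks <- split(seq_len(M), ceiling(seq_len(M) / max(1L, chunk_cols)))
  for (cols in blocks) {
    for (k in seq_len(K)) {
      ind <- ind_of_pop[[k]]
      if (P == 2L) {
        a1 <- panel$matrix[2L * ind - 1L, cols, drop = FALSE]
        a2 <- panel$matrix[2L * ind, cols, drop = FALSE]
        called <- !is.na(a1) & !is.na(a2)
        n_ind_called[cols, k] <- colSums(called)
        het <- called & (a1 != a2)
        het_obs[cols, k] <- colSums(het, na.rm = TRUE)
        for (a in 1:4) {
          counts[cols, k, a] <- colSums(called & (a1 == a), na.rm = TRUE) +
            colSums(called & (a2 == a), na.rm = TRUE)
          het_by_allele[cols, k, a] <-
            colSums(het & (a1 == a | a2 == a), na.rm = TRUE)
        }
      } else {
        a1 <- panel$matrix[ind, cols, drop = FALSE]
        called <- !is.na(a1)
        n_ind_called[cols, k] <- colSums(called)
        for (a in 1:4) {
          counts[cols, k, a] <- colSums(a1 == a, na.rm = TRUE)
        }
      }
    }
  }
  structure(list(counts = counts, het_obs = het_obs,
                 het_by_allele = het_by_allele,
                 n_called = n_ind_called * P, n_ind_called = n_ind_called,
                 populations = pops, ploidy = P,
                 n_ind_pop = as.integer(sizes),
                 locus_id = rep("", 0)),
            class = "allele_count_table")
}

#' @export
print.allele_count_table <- function(x, ...) {
  cat(sprintf("<allele_count_table> %d loci x %d populations (ploidy %d)\n",
              nrow(x$n_called), length(x$populations), x$ploidy))
  invisible(x)
}

#' Pool an allele-count table across populations
#'
#' Sums counts over populations into a single "total" population. Used where
#' total counts (not mean frequencies) are needed.
#'
#' @param table an `allele_count_table`
#' @return an `allele_count_table` with one population `"total"`.
#' @export
pool_counts <- function(table) {
  M <- nrow(table$n_called)
  counts <- array(0L, dim = c(M, 1L, 4L))
  hba <- array(0L, dim = c(M, 1L, 4L))
  for (a in 1:4) {
    counts[, 1L, a] <- rowSums(table$counts[, , a, drop = FALSE])
    hba[, 1L, a] <- rowSums(table$het_by_allele[, , a, drop = FALSE])
  }
  structure(list(counts = counts,
                 het_obs = matrix(rowSums(table$het_obs), M, 1L),
                 het_by_allele = hba,
                 n_called = matrix(rowSums(table$n_called), M, 1L),
                 n_ind_called = matrix(rowSums(table$n_ind_called), M, 1L),
                 populations = "total", ploidy = table$ploidy,
                 n_ind_pop = sum(table$n_ind_pop),
                 locus_id = table$locus_id),
            class = "allele_count_table")
}

#' Subset an allele-count table to a block of loci
#'
#' @param table an `allele_count_table`
#' @param loci integer indices of loci to keep
#' @return an `allele_count_table` over the selected loci (order preserved).
#' @export
subset_counts <- function(table, loci) {
  structure(list(counts = table$counts[loci, , , drop = FALSE],
                 het_obs = table$het_obs[loci, , drop = FALSE],
                 het_by_allele = table$het_by_allele[loci, , , drop = FALSE],
                 n_called = table$n_called[loci, , drop = FALSE],
                 n_ind_called = table$n_ind_called[loci, , drop = FALSE],
                 populations = table$populations, ploidy = table$ploidy,
                 n_ind_pop = table$n_ind_pop, locus_id = table$locus_id),
            class = "allele_count_table")
}
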