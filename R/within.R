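#' Per-locus allele frequencies for one population
#'
#' `p_i = counts_i / n_called`. Loci with no called chromosomes in the
#' population are undefined: the row is all `NA` (a flag, not an error).
#'
#' @param table an [build_allele_counts()] table
#' @param pop population label or index
#' @param loci optional integer locus indices (default: all)
#' @return numeric matrix `[locus, allele 1..4]`; rows sum to 1 where defined.
#' @export
allele_frequencies <- function(table, pop, loci = NULL) {
  k <- pop_index(table, pop)
  if (is.null(loci)) loci <- seq_len(nrow(table$n_called))
  n <- table$n_called[loci, k]
  p <- table$counts[loci, k, , drop = FALSE][, 1L, ] / n
  p <- matrix(p, nrow = length(loci), ncol = 4L)
  p[n == 0L, ] <- NA_real_
  colnames(p) <- paste0("allele", 1:4)
  p
}

#' Observed heterozygosity per locus for one population
#'
#' `Ho = het_obs / n_ind_called`, the fraction of completely genotyped
#' individuals whose two allele indices differ. Undefined (all-`NA`) for
#' haploid panels and for loci with no called individual in the population.
#'
#' @inheritParams allele_frequencies
#' @return numeric vector over `loci`.
#' @export
observed_heterozygosity <- function(table, pop, loci = NULL) {
  k <- pop_index(table, pop)
  if (is.null(loci)) loci <- seq_len(nrow(table$n_called))
  if (table$ploidy != 2L) return(rep(NA_real_, length(loci)))
  n <- table$n_ind_called[loci, k]
  ho <- table$het_obs[loci, k] / n
  ho[n == 0L] <- NA_real_
  ho
}

#' Expected heterozygosity (gene diversity) per locus for one population
#'
#' Raw form: `He = 1 - sum_i p_i^2`. Unbiased form (default): the small-sample
#' correction `He = n/(n-1) * (1 - sum p_i^2)` with `n` the number of called
#' chromosomes. The unbiased form needs `n >= 2` and is `NA` below that.
#'
#' @inheritParams allele_frequencies
#' @param unbiased logical; apply the `n/(n-1)` correction (default `TRUE`).
#' @return numeric vector over `loci`.
#' @export
expected_heterozygosity <- function(table, pop, loci = NULL, unbiased = TRUE) {
  k <- pop_index(table, pop)
  if (is.null(loci)) loci <- seq_len(nrow(table$n_called))
  n <- table$n_called[loci, k]
  p <- allele_frequencies(table, pop, loci)
  he <- 1 - rowSums(p^2)
  if (unbiased) {
    he <- he * n / (n - 1)
    he[n < 2L] <- NA_real_
  } else {
    he[n == 0L] <- NA_real_
  }
  he
}

pop_index <- function(table, pop) {
  if (is.character(pop)) {
    k <- match(pop, table$populations)
    if (is.na(k)) stop("unknown population: ", pop)
    return(k)
  }
  as.integer(pop)
}

#' Mean and variance of a per-locus statistic across defined loci
#'
#' `NA` marks loci where the statistic is not defined; those are excluded.
#' The variance is the population variance (denominator `count`) by default,
#' matching across-locus summaries of a fixed panel; `sample = TRUE` switches
#' to the `count - 1` denominator.
#'
#' @param values per-locus numeric vector with `NA` for undefined loci
#' @param sample logical; use the sample (n-1) variance denominator
#' @return list with `mean`, `variance`, `count`; mean and variance are `NA`
#'   when `count == 0` (and variance additionally when `count == 1` under
#'   `sample = TRUE`).
#' @export
summarize_stat <- function(values, sample = FALSE) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n == 0L) return(list(mean = NA_real_, variance = NA_real_, count = 0L))
  m <- sum(v) / n
  ss <- sum((v - m)^2)
  var <- if (sample) {
    if (n > 1L) ss / (n - 1) else NA_real_
  } else {
    ss / n
  }
  list(mean = m, variance = var, count = n)
}
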