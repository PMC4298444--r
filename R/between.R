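#' Per-locus differentiation components
#'
#' Computes, for a block of loci, every quantity the differentiation
#' estimators are built from, vectorised over loci. A population with zero
#' called chromosomes at a locus is dropped from that locus's `s`; loci with
#' fewer than two remaining populations are undefined (`NA`) for all
#' between-population statistics.
#'
#' Definitions per locus (populations `k = 1..s` after dropping empties,
#' alleles `i`):
#' \describe{
#'   \item{Nei 1973}{`Hs = mean_k (1 - sum_i p_ki^2)`;
#'     `Ht = 1 - sum_i pbar_i^2` with `pbar_i` the *unweighted* mean of
#'     `p_ki`; `Gst = (Ht - Hs) / Ht`.}
#'   \item{Nei-Chesser 1983}{with `n~` the harmonic mean number of genotyped
#'     individuals and `Ho_bar` the mean observed heterozygosity:
#'     `Hs^ = n~/(n~-1) * (1 - mean_k sum_i p_ki^2 - Ho_bar/(2 n~))`,
#'     `Ht^ = 1 - sum_i pbar_i^2 + Hs^/(n~ s) - Ho_bar/(2 n~ s)`,
#'     `Gst^ = (Ht^ - Hs^)/Ht^`. For haploid panels the `Ho_bar` terms drop
#'     and `n~` counts chromosomes.}
#'   \item{Hedrick 2005}{`G'st = Gst^ * (s - 1 + Hs^) / ((s-1) * (1 - Hs^))`.}
#'   \item{Jost 2008}{`D = (s/(s-1)) * (Ht^ - Hs^) / (1 - Hs^)` (the
#'     estimator form; a raw variant uses `Hs`, `Ht`).}
#'   \item{Weir-Cockerham 1984}{variance components `a` (among populations),
#'     `b` (among individuals within populations), `c` (within individuals),
#'     summed over alleles; `theta = a/(a+b+c)`.}
#' }
#'
#' @param table an [build_allele_counts()] table
#' @param loci optional integer locus indices (default all)
#' @return data.frame, one row per requested locus, columns `s`, `Hs`, `Ht`,
#'   `Gst73`, `n_harm`, `Ho_bar`, `Hs_hat`, `Ht_hat`, `GstNC`, `GstHedrick`,
#'   `JostD`, `JostD_raw`, `WC_a`, `WC_b`, `WC_c`, `WC_theta`.
#' @export
diff_components <- function(table, loci = NULL) {
  out <- diff_components_list(table, loci)
  attr(out, "row.names") <- .set_row_names(length(out$s))
  class(out) <- "data.frame"
  out
}

# same computation, returned as a bare list (hot path: called once per chunk)
diff_components_list <- function(table, loci = NULL) {
  if (is.null(loci)) loci <- seq_len(nrow(table$n_called))
  m <- length(loci); K <- length(table$populations)
  n <- table$n_called[loci, , drop = FALSE]
  nind <- table$n_ind_called[loci, , drop = FALSE]
  incl <- n > 0L
  s <- rowSums(incl)
  defined <- s >= 2L

  # p[, k, a] with 0 where the population is dropped at the locus
  p <- array(0, dim = c(m, K, 4L))
  for (a in 1:4) {
    pa <- table$counts[loci, , a, drop = FALSE][, , 1L] / n
    pa <- matrix(pa, m, K)
    pa[!incl] <- 0
    p[, , a] <- pa
  }
  sumsq <- matrix(0, m, K)
  for (a in 1:4) sumsq <- sumsq + p[, , a]^2

  Hs <- rowSums(incl * (1 - sumsq)) / s
  # accumulate sum(pbar^2) first: addition of the nonzero terms is
  # commutative, so Ht is bit-identical under allele relabeling (for <= 2
  # observed alleles), which the cross-format contract relies on
  sumsq_bar <- rep(0, m)
  for (a in 1:4) sumsq_bar <- sumsq_bar + (rowSums(incl * p[, , a]) / s)^2
  Ht <- 1 - sumsq_bar
  Gst73 <- (Ht - Hs) / Ht
  Gst73[!defined | Ht == 0] <- NA_real_
  Hs[!defined] <- NA_real_; Ht[!defined] <- NA_real_

  diploid <- table$ploidy == 2L
  nk_nc <- if (diploid) nind else n       # sample-size unit for Nei-Chesser
  inv <- matrix(0, m, K); inv[incl] <- 1 / nk_nc[incl]
  n_harm <- s / rowSums(inv)
  if (diploid) {
    ho <- table$het_obs[loci, , drop = FALSE] / nind
    ho[!incl] <- 0
    Ho_bar <- rowSums(incl * ho) / s
  } else {
    Ho_bar <- rep(0, m)
  }
  Hs_hat <- n_harm / (n_harm - 1) * ((1 - rowSums(incl * sumsq) / s) -
                                       Ho_bar / (2 * n_harm))
  Ht_raw <- 1 - sumsq_bar   # NA-free (Ht above gets masked)
  Ht_hat <- Ht_raw + Hs_hat / (n_harm * s) - Ho_bar / (2 * n_harm * s)
  bad_nc <- !defined | n_harm <= 1
  Hs_hat[bad_nc] <- NA_real_; Ht_hat[bad_nc] <- NA_real_
  GstNC <- (Ht_hat - Hs_hat) / Ht_hat
  GstNC[is.na(Ht_hat) | Ht_hat == 0] <- NA_real_
  GstHedrick <- GstNC * (s - 1 + Hs_hat) / ((s - 1) * (1 - Hs_hat))
  GstHedrick[is.na(GstNC) | Hs_hat == 1] <- NA_real_
  JostD <- (s / (s - 1)) * (Ht_hat - Hs_hat) / (1 - Hs_hat)
  JostD[is.na(Hs_hat) | Hs_hat == 1] <- NA_real_
  Hs_r <- rowSums(incl * (1 - sumsq)) / s
  JostD_raw <- (s / (s - 1)) * (Ht_raw - Hs_r) / (1 - Hs_r)
  JostD_raw[!defined | Hs_r == 1] <- NA_real_

  # Weir-Cockerham variance components
  nk <- if (diploid) nind else n
  nk <- nk * incl
  nbar <- rowSums(nk) / s
  nc <- (s * nbar - rowSums(nk^2) / (s * nbar)) / (s - 1)
  A <- B <- C <- rep(0, m)
  snbar <- s * nbar
  for (a in 1:4) {
    pa <- p[, , a]
    pbar <- rowSums(nk * pa) / snbar
    s2 <- rowSums(nk * (pa - pbar)^2) / ((s - 1) * nbar)
    if (diploid) {
      hka <- table$het_by_allele[loci, , a, drop = FALSE][, , 1L] / nind
      hka <- matrix(hka, m, K); hka[!incl] <- 0
      hbar <- rowSums(nk * hka) / snbar
    } else {
      hbar <- rep(0, m)
    }
    inner <- pbar * (1 - pbar) - ((s - 1) / s) * s2
    A <- A + (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1))
    B <- B + (nbar / (nbar - 1)) * (inner - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    C <- C + hbar / 2
  }
  bad_wc <- !defined | nbar <= 1 | nc <= 0
  A[bad_wc] <- NA_real_; B[bad_wc] <- NA_real_; C[bad_wc] <- NA_real_
  theta <- A / (A + B + C)
  theta[is.na(A) | (A + B + C) == 0] <- NA_real_

  n_harm[bad_nc] <- NA_real_
  ho_out <- Ho_bar; ho_out[!defined] <- NA_real_
  list(s = s, Hs = Hs, Ht = Ht, Gst73 = Gst73,
       n_harm = n_harm, Ho_bar = ho_out,
       Hs_hat = Hs_hat, Ht_hat = Ht_hat, GstNC = GstNC,
       GstHedrick = GstHedrick, JostD = JostD, JostD_raw = JostD_raw,
       WC_a = A, WC_b = B, WC_c = C, WC_theta = theta)
}

#' Nei (1973) Gst per locus
#' @inheritParams diff_components
#' @return list with per-locus vectors `Hs`, `Ht`, `Gst`.
#' @export
gst_nei73 <- function(table, loci = NULL) {
  d <- diff_components(table, loci)
  list(Hs = d$Hs, Ht = d$Ht, Gst = d$Gst73)
}

#' Nei & Chesser (1983) sample-size-corrected Gst per locus
#' @inheritParams diff_components
#' @return list with per-locus vectors `Hs_hat`, `Ht_hat`, `Gst`.
#' @export
gst_nei_chesser <- function(table, loci = NULL) {
  d <- diff_components(table, loci)
  list(Hs_hat = d$Hs_hat, Ht_hat = d$Ht_hat, Gst = d$GstNC)
}

#' Hedrick (2005) G'st per locus
#' @inheritParams diff_components
#' @return per-locus numeric vector.
#' @export
gst_hedrick <- function(table, loci = NULL) diff_components(table, loci)$GstHedrick

#' Jost (2008) D per locus
#' @inheritParams diff_components
#' @param raw logical; use the raw `Hs`/`Ht` instead of the Nei-Chesser
#'   estimators (default `FALSE`, i.e. the "est D" form).
#' @return per-locus numeric vector.
#' @export
jost_d <- function(table, loci = NULL, raw = FALSE) {
  d <- diff_components(table, loci)
  if (raw) d$JostD_raw else d$JostD
}

#' Weir & Cockerham (1984) theta
#'
#' Per-locus variance components and theta, plus the multilocus ratio of sums
#' `sum(a) / sum(a + b + c)` over defined loci (Weir & Cockerham's
#' recommended multilocus weighting; in general it differs from the mean of
#' per-locus thetas). Negative estimates are reported as computed.
#'
#' @inheritParams diff_components
#' @return list with vectors `a`, `b`, `c`, `theta` and scalar
#'   `theta_multilocus`.
#' @export
wc_theta <- function(table, loci = NULL) {
  d <- diff_components(table, loci)
  ok <- !is.na(d$WC_a)
  denom <- sum(d$WC_a[ok] + d$WC_b[ok] + d$WC_c[ok])
  list(a = d$WC_a, b = d$WC_b, c = d$WC_c, theta = d$WC_theta,
       theta_multilocus = if (any(ok) && denom != 0) sum(d$WC_a[ok]) / denom
                          else NA_real_)
}

# Partial sums for the pairwise shared-allele matrix over a block of loci:
# returns S (sum of per-locus shares) and N (usable-locus counts), both
# n_ind x n_ind, exact to sum across blocks (shares are multiples of 0.5).
shared_partial <- function(panel, loci) {
  n_ind <- n_individuals(panel)
  if (panel$ploidy == 2L) {
    a1 <- panel$matrix[seq(1L, 2L * n_ind, by = 2L), loci, drop = FALSE]
    a2 <- panel$matrix[seq(2L, 2L * n_ind, by = 2L), loci, drop = FALSE]
    g1 <- pmin(a1, a2); g2 <- pmax(a1, a2)
    called <- !is.na(g1)
    S <- matrix(0, n_ind, n_ind); N <- matrix(0L, n_ind, n_ind)
    for (i in seq_len(n_ind)) {
      ci <- called[i, ]
      for (j in i:n_ind) {
        ok <- ci & called[j, ]
        if (i == j) { N[i, i] <- sum(ok); S[i, i] <- sum(ok); next }
        m1 <- (g1[i, ok] == g1[j, ok]) + (g2[i, ok] == g2[j, ok])
        m2 <- (g1[i, ok] == g2[j, ok]) + (g2[i, ok] == g1[j, ok])
        S[i, j] <- S[j, i] <- sum(pmax(m1, m2)) / 2
        N[i, j] <- N[j, i] <- sum(ok)
      }
    }
  } else {
    g <- panel$matrix[, loci, drop = FALSE]
    called <- !is.na(g)
    S <- matrix(0, n_ind, n_ind); N <- matrix(0L, n_ind, n_ind)
    for (i in seq_len(n_ind)) {
      for (j in i:n_ind) {
        ok <- called[i, ] & called[j, ]
        S[i, j] <- S[j, i] <- sum(g[i, ok] == g[j, ok])
        N[i, j] <- N[j, i] <- sum(ok)
      }
    }
  }
  list(S = S, N = N)
}

#' Pairwise proportion of shared alleles between individuals
#'
#' For each pair of individuals and each locus where both genotypes are fully
#' called, the per-locus share is the multiset intersection of the two
#' genotypes divided by the ploidy (0, 0.5 or 1 for diploids; 0 or 1 for
#' haploids). The matrix entry is the mean over usable loci; pairs with no
#' usable locus are `NA`.
#'
#' @param panel a [genotype_panel()]
#' @param assignment a [pop_assignment()] (used only to label the output)
#' @param loci optional integer locus indices (default all)
#' @return list of class `pair_share`: `share` (symmetric matrix, diagonal 1
#'   where the individual has any fully called locus), `n_loci_used`
#'   (integer matrix), `individual_ids`, `pop_of`.
#' @export
shared_alleles <- function(panel, assignment, loci = NULL) {
  if (is.null(loci)) loci <- seq_len(n_loci(panel))
  part <- shared_partial(panel, loci)
  share <- part$S / part$N
  share[part$N == 0L] <- NA_real_
  ids <- panel$individual_ids
  dimnames(share) <- list(ids, ids)
  structure(list(share = share, n_loci_used = part$N,
                 individual_ids = ids,
                 pop_of = as.character(assignment$pop_of)),
            class = "pair_share")
}
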