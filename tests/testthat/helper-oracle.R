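# Independent naive-oracle implementations, written as explicit double loops
# straight from the estimator definitions. They share no code with the
# package internals and are deliberately slow and literal.

# random small test panel: <=5 pops, <=10 diploids each, <=50 loci, 1..4
# alleles per locus, ~10% missing
random_panel <- function(seed, max_pops = 5, max_ind = 10, max_loci = 50,
                         miss = 0.1, ploidy = 2) {
  set.seed(seed)
  K <- sample.int(max_pops - 1L, 1L) + 1L   # 2..max_pops
  n_ind_k <- sample(2:max_ind, K, replace = TRUE)
  M <- sample(5:max_loci, 1)
  n_ind <- sum(n_ind_k)
  H <- n_ind * ploidy
  mat <- matrix(NA_integer_, H, M)
  labels <- vector("list", M)
  nucs <- c("A", "C", "G", "T")
  for (j in seq_len(M)) {
    na <- sample(1:4, 1, prob = c(0.15, 0.6, 0.15, 0.1))
    labels[[j]] <- sample(nucs, na)
    w <- stats::runif(na) + 0.1
    mat[, j] <- sample(seq_len(na), H, replace = TRUE, prob = w / sum(w))
  }
  mat[stats::runif(length(mat)) < miss] <- NA_integer_
  ids <- sprintf("ind%03d", seq_len(n_ind))
  panel <- panelpop::genotype_panel(mat, ploidy, ids)
  loci <- panelpop::locus_table(sprintf("L%03d", seq_len(M)), "1",
                                seq_len(M), labels)
  asg <- panelpop::pop_assignment(rep(sprintf("P%d", seq_len(K)), n_ind_k))
  panelpop::panel_bundle(panel, loci, asg)
}

# per-entry tally by explicit loops; complete-genotype rule
oracle_counts <- function(panel, assignment) {
  P <- panel$ploidy
  n_ind <- length(panel$individual_ids)
  M <- ncol(panel$matrix)
  pops <- assignment$populations
  K <- length(pops)
  counts <- array(0L, c(M, K, 4))
  het <- matrix(0L, M, K)
  hba <- array(0L, c(M, K, 4))
  nic <- matrix(0L, M, K)
  for (i in seq_len(n_ind)) {
    k <- match(as.character(assignment$pop_of[i]), pops)
    for (j in seq_len(M)) {
      if (P == 2) {
        g <- c(panel$matrix[2 * i - 1, j], panel$matrix[2 * i, j])
        if (any(is.na(g))) next
        nic[j, k] <- nic[j, k] + 1L
        for (a in g) counts[j, k, a] <- counts[j, k, a] + 1L
        if (g[1] != g[2]) {
          het[j, k] <- het[j, k] + 1L
          hba[j, k, g[1]] <- hba[j, k, g[1]] + 1L
          hba[j, k, g[2]] <- hba[j, k, g[2]] + 1L
        }
      } else {
        g <- panel$matrix[i, j]
        if (is.na(g)) next
        nic[j, k] <- nic[j, k] + 1L
        counts[j, k, g] <- counts[j, k, g] + 1L
      }
    }
  }
  list(counts = counts, het_obs = het, het_by_allele = hba,
       n_called = nic * P, n_ind_called = nic)
}

oracle_freq <- function(cnt, j, k) {
  n <- cnt$n_called[j, k]
  if (n == 0) return(rep(NA_real_, 4))
  cnt$counts[j, k, ] / n
}

oracle_ho <- function(cnt, j, k) {
  n <- cnt$n_ind_called[j, k]
  if (n == 0) return(NA_real_)
  cnt$het_obs[j, k] / n
}

oracle_he <- function(cnt, j, k, unbiased) {
  n <- cnt$n_called[j, k]
  if (n == 0 || (unbiased && n < 2)) return(NA_real_)
  p <- cnt$counts[j, k, ] / n
  he <- 1 - sum(p^2)
  if (unbiased) he * n / (n - 1) else he
}

# populations with data at locus j
oracle_pops_in <- function(cnt, j) which(cnt$n_called[j, ] > 0)

oracle_gst73 <- function(cnt, j) {
  ks <- oracle_pops_in(cnt, j)
  if (length(ks) < 2) return(list(Hs = NA_real_, Ht = NA_real_, Gst = NA_real_))
  s <- length(ks)
  hs <- 0
  pbar <- rep(0, 4)
  for (k in ks) {
    p <- cnt$counts[j, k, ] / cnt$n_called[j, k]
    hs <- hs + (1 - sum(p^2)) / s
    pbar <- pbar + p / s
  }
  ht <- 1 - sum(pbar^2)
  list(Hs = hs, Ht = ht,
       Gst = if (ht == 0) NA_real_ else (ht - hs) / ht)
}

oracle_gstnc <- function(cnt, j, ploidy) {
  ks <- oracle_pops_in(cnt, j)
  if (length(ks) < 2) return(list(Hs = NA_real_, Ht = NA_real_, Gst = NA_real_,
                                  s = length(ks)))
  s <- length(ks)
  nk <- if (ploidy == 2) cnt$n_ind_called[j, ks] else cnt$n_called[j, ks]
  ntil <- s / sum(1 / nk)
  if (ntil <= 1) return(list(Hs = NA_real_, Ht = NA_real_, Gst = NA_real_, s = s))
  hobar <- 0; msq <- 0; pbar <- rep(0, 4)
  for (k in ks) {
    p <- cnt$counts[j, k, ] / cnt$n_called[j, k]
    msq <- msq + sum(p^2) / s
    pbar <- pbar + p / s
    if (ploidy == 2) hobar <- hobar + (cnt$het_obs[j, k] / cnt$n_ind_called[j, k]) / s
  }
  hs <- ntil / (ntil - 1) * (1 - msq - hobar / (2 * ntil))
  ht <- 1 - sum(pbar^2) + hs / (ntil * s) - hobar / (2 * ntil * s)
  list(Hs = hs, Ht = ht, Gst = if (ht == 0) NA_real_ else (ht - hs) / ht, s = s)
}

oracle_hedrick <- function(cnt, j, ploidy) {
  nc <- oracle_gstnc(cnt, j, ploidy)
  if (is.na(nc$Gst) || nc$Hs == 1) return(NA_real_)
  nc$Gst * (nc$s - 1 + nc$Hs) / ((nc$s - 1) * (1 - nc$Hs))
}

oracle_jostd <- function(cnt, j, ploidy, raw = FALSE) {
  if (raw) {
    g <- oracle_gst73(cnt, j)
    ks <- oracle_pops_in(cnt, j); s <- length(ks)
    if (s < 2 || is.na(g$Hs) || g$Hs == 1) return(NA_real_)
    return((s / (s - 1)) * (g$Ht - g$Hs) / (1 - g$Hs))
  }
  nc <- oracle_gstnc(cnt, j, ploidy)
  if (is.na(nc$Hs) || nc$Hs == 1) return(NA_real_)
  (nc$s / (nc$s - 1)) * (nc$Ht - nc$Hs) / (1 - nc$Hs)
}

oracle_wc <- function(cnt, j, ploidy) {
  ks <- oracle_pops_in(cnt, j)
  und <- list(a = NA_real_, b = NA_real_, c = NA_real_, theta = NA_real_)
  if (length(ks) < 2) return(und)
  s <- length(ks)
  nk <- if (ploidy == 2) cnt$n_ind_called[j, ks] else cnt$n_called[j, ks]
  nbar <- mean(nk)
  if (nbar <= 1) return(und)
  ncoef <- (s * nbar - sum(nk^2) / (s * nbar)) / (s - 1)
  if (ncoef <= 0) return(und)
  A <- B <- C <- 0
  for (a in 1:4) {
    p <- cnt$counts[j, ks, a] / cnt$n_called[j, ks]
    pbar <- sum(nk * p) / (s * nbar)
    s2 <- sum(nk * (p - pbar)^2) / ((s - 1) * nbar)
    hbar <- if (ploidy == 2) {
      sum(nk * cnt$het_by_allele[j, ks, a] / cnt$n_ind_called[j, ks]) / (s * nbar)
    } else 0
    A <- A + (nbar / ncoef) *
      (s2 - (pbar * (1 - pbar) - ((s - 1) / s) * s2 - hbar / 4) / (nbar - 1))
    B <- B + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((s - 1) / s) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    C <- C + hbar / 2
  }
  list(a = A, b = B, c = C,
       theta = if (A + B + C == 0) NA_real_ else A / (A + B + C))
}

oracle_shared <- function(panel) {
  P <- panel$ploidy
  n_ind <- length(panel$individual_ids)
  M <- ncol(panel$matrix)
  S <- matrix(NA_real_, n_ind, n_ind)
  for (i in seq_len(n_ind)) for (jj in seq_len(n_ind)) {
    tot <- 0; used <- 0
    for (l in seq_len(M)) {
      if (P == 2) {
        gi <- c(panel$matrix[2 * i - 1, l], panel$matrix[2 * i, l])
        gj <- c(panel$matrix[2 * jj - 1, l], panel$matrix[2 * jj, l])
        if (any(is.na(gi)) || any(is.na(gj))) next
        sh <- 0
        for (a in 1:4) sh <- sh + min(sum(gi == a), sum(gj == a))
        tot <- tot + sh / 2; used <- used + 1
      } else {
        gi <- panel$matrix[i, l]; gj <- panel$matrix[jj, l]
        if (is.na(gi) || is.na(gj)) next
        tot <- tot + (gi == gj); used <- used + 1
      }
    }
    S[i, jj] <- if (used == 0) NA_real_ else tot / used
  }
  S
}

# brute-force spectra: per-locus tally by an independent loop; returns NULL
# entries for excluded loci. designated allele = index 2.
oracle_sfs_loci <- function(cnt, ks, n_full) {
  M <- dim(cnt$counts)[1]
  keep <- logical(M)
  for (j in seq_len(M)) {
    multi <- sum(cnt$counts[j, , 3:4]) > 0
    comp <- all(cnt$n_called[j, ks] == n_full)
    keep[j] <- !multi && comp
  }
  which(keep)
}

oracle_single_sfs <- function(cnt, k, n_full, folded) {
  loci <- oracle_sfs_loci(cnt, k, n_full)
  spec <- rep(0L, n_full + 1)
  for (j in loci) {
    c2 <- cnt$counts[j, k, 2]
    b <- if (folded) min(c2, n_full - c2) else c2
    spec[b + 1] <- spec[b + 1] + 1L
  }
  spec
}

oracle_joint_sfs <- function(cnt, ks, n_full, folded) {
  loci <- oracle_sfs_loci(cnt, ks, n_full)
  arr <- array(0L, n_full + 1)
  for (j in loci) {
    cc <- sapply(seq_along(ks), function(i) cnt$counts[j, ks[i], 2])
    if (folded) {
      comp <- n_full - cc
      if (sum(cc) > sum(n_full) / 2) cc <- comp
      else if (sum(cc) == sum(n_full) / 2) {
        for (i in seq_along(cc)) {
          if (cc[i] > comp[i]) { cc <- comp; break }
          if (cc[i] < comp[i]) break
        }
      }
    }
    idx <- matrix(cc + 1L, nrow = 1)
    arr[idx] <- arr[idx] + 1L
  }
  arr
}

# small literal panels used across tests
tiny_bundle <- function(geno_by_pop, labels = NULL) {
  # geno_by_pop: named list pop -> matrix n_ind x (2*M) of allele indices
  mats <- lapply(geno_by_pop, function(g) {
    n <- nrow(g); M <- ncol(g) / 2
    out <- matrix(NA_integer_, 2 * n, M)
    for (i in seq_len(n)) {
      out[2 * i - 1, ] <- as.integer(g[i, seq(1, 2 * M, by = 2)])
      out[2 * i, ] <- as.integer(g[i, seq(2, 2 * M, by = 2)])
    }
    out
  })
  mat <- do.call(rbind, mats)
  M <- ncol(mat)
  n_k <- vapply(geno_by_pop, nrow, 0L)
  if (is.null(labels)) labels <- rep(list(c("A", "C", "G", "T")), M)
  ids <- sprintf("i%02d", seq_len(sum(n_k)))
  panelpop::panel_bundle(
    panelpop::genotype_panel(mat, 2L, ids),
    panelpop::locus_table(sprintf("L%d", seq_len(M)), "1", seq_len(M), labels),
    panelpop::pop_assignment(rep(names(geno_by_pop), n_k)))
}
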