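# counts table built directly, bypassing a panel: lets tests set huge n or
# exact heterozygote counts
make_table <- function(counts, het_obs = NULL, het_by_allele = NULL,
                       ploidy = 2L) {
  M <- dim(counts)[1]; K <- dim(counts)[2]
  n_called <- matrix(0L, M, K)
  for (a in 1:4) n_called <- n_called + counts[, , a]
  n_ind <- n_called / ploidy
  if (is.null(het_obs)) het_obs <- matrix(0L, M, K)
  if (is.null(het_by_allele)) het_by_allele <- array(0L, c(M, K, 4))
  structure(list(counts = counts, het_obs = het_obs,
                 het_by_allele = het_by_allele, n_called = n_called,
                 n_ind_called = n_ind, populations = paste0("P", seq_len(K)),
                 ploidy = as.integer(ploidy),
                 n_ind_pop = rep(0L, K), locus_id = character(0)),
            class = "allele_count_table")
}

biallelic_counts <- function(p1, p2, n) {
  cc <- array(0L, c(1, 2, 4))
  cc[1, 1, 1:2] <- as.integer(round(c(p1, 1 - p1) * n))
  cc[1, 2, 1:2] <- as.integer(round(c(p2, 1 - p2) * n))
  cc
}

test_that("Nei 1973 Gst closed forms", {
  # p = 0.2 vs 0.8: Hs = 0.32, Ht = 0.5, Gst = 0.36
  ct <- make_table(biallelic_counts(0.2, 0.8, 10))
  g <- gst_nei73(ct)
  expect_equal(g$Hs, 0.32)
  expect_equal(g$Ht, 0.5)
  expect_equal(g$Gst, 0.36)
  # identical populations -> 0
  g0 <- gst_nei73(make_table(biallelic_counts(0.3, 0.3, 10)))
  expect_equal(g0$Gst, 0)
  # fixed difference -> Hs 0, Ht 0.5, Gst 1
  g1 <- gst_nei73(make_table(biallelic_counts(1, 0, 10)))
  expect_equal(g1$Hs, 0)
  expect_equal(g1$Ht, 0.5)
  expect_equal(g1$Gst, 1)
  # monomorphic overall -> Ht = 0 -> undefined
  gm <- gst_nei73(make_table(biallelic_counts(1, 1, 10)))
  expect_true(is.na(gm$Gst))
})

test_that("Nei-Chesser estimators approach the raw values as n grows", {
  # Ho matching 2p(1-p) exactly, huge equal n: Hs_hat -> Hs within 1e-5
  n <- 2e6   # chromosomes; 1e6 individuals
  for (p in c(0.2, 0.5)) {
    cc <- biallelic_counts(p, 1 - p, n)
    ho <- matrix(as.integer(round(2 * p * (1 - p) * n / 2)), 1, 2)
    ct <- make_table(cc, het_obs = ho)
    nc <- gst_nei_chesser(ct)
    expect_equal(nc$Hs_hat, 2 * p * (1 - p), tolerance = 1e-5)
  }
  # identical populations, equal n, Ho equal -> Gst_hat ~ 0; the finite-n
  # correction to Ht_hat leaves an O(1/(n~ s)) residue, so the bound is 2/n~
  cc <- biallelic_counts(0.4, 0.4, 1000)
  ho <- matrix(as.integer(round(2 * 0.4 * 0.6 * 500)), 1, 2)
  ncs <- gst_nei_chesser(make_table(cc, het_obs = ho))
  expect_lt(abs(ncs$Gst), 2 / 500)
})

test_that("Hedrick G'st closed forms", {
  # fixed difference, no heterozygotes: Hs_hat = 0 -> G'st = GstNC = 1
  ct <- make_table(biallelic_counts(1, 0, 10))
  expect_equal(gst_hedrick(ct), 1)
  expect_equal(gst_nei_chesser(ct)$Gst, 1)
  # identical populations -> ~0 (O(1/n~) estimator residue)
  cc <- biallelic_counts(0.4, 0.4, 1000)
  ho <- matrix(240L, 1, 2)
  expect_lt(abs(gst_hedrick(make_table(cc, het_obs = ho))), 2 / 500)
})

test_that("Jost's D closed forms and large-n limit", {
  # fixed difference, large equal n -> D -> 1
  ct <- make_table(biallelic_counts(1, 0, 2e6))
  expect_equal(jost_d(ct), 1, tolerance = 1e-5)
  # identical populations -> ~0 (O(1/n~) estimator residue)
  cc <- biallelic_counts(0.4, 0.4, 1000)
  ho <- matrix(240L, 1, 2)
  expect_lt(abs(jost_d(make_table(cc, het_obs = ho))), 2 / 500)
  # p = 0.2 / 0.8 large-n limit: D -> 2 * 0.18 / 0.68
  n <- 2e6
  cc <- biallelic_counts(0.2, 0.8, n)
  ho <- matrix(as.integer(round(2 * 0.2 * 0.8 * n / 2)), 1, 2)
  expect_equal(jost_d(make_table(cc, het_obs = ho)),
               2 * 0.18 / 0.68, tolerance = 1e-4)
  # raw switch uses raw Hs / Ht exactly
  expect_equal(jost_d(make_table(biallelic_counts(0.2, 0.8, 10)), raw = TRUE),
               2 * 0.18 / 0.68)
})

test_that("Weir-Cockerham theta closed forms", {
  # fixed difference, equal n, no heterozygotes -> theta = 1 (b = c = 0)
  w <- wc_theta(make_table(biallelic_counts(1, 0, 10)))
  expect_equal(w$theta, 1)
  expect_equal(w$b, 0)
  expect_equal(w$c, 0)
  # identical populations -> s2 = 0 -> a <= 0 -> theta <= 0, not truncated
  cc <- biallelic_counts(0.4, 0.4, 20)
  ho <- matrix(5L, 1, 2)
  hba <- array(0L, c(1, 2, 4)); hba[1, , 1] <- 5L; hba[1, , 2] <- 5L
  w0 <- wc_theta(make_table(cc, het_obs = ho, het_by_allele = hba))
  expect_lte(w0$a, 0)
  expect_lte(w0$theta, 0)
})

test_that("all differentiation statistics match the naive oracle", {
  for (seed in 1:25) {
    b <- random_panel(seed)
    ct <- build_allele_counts(b$panel, b$assignment)
    oc <- oracle_counts(b$panel, b$assignment)
    d <- diff_components(ct)
    for (j in seq_len(n_loci(b$panel))) {
      g73 <- oracle_gst73(oc, j)
      expect_equal(d$Hs[j], g73$Hs, tolerance = 1e-12)
      expect_equal(d$Gst73[j], g73$Gst, tolerance = 1e-12)
      nc <- oracle_gstnc(oc, j, 2L)
      expect_equal(d$GstNC[j], nc$Gst, tolerance = 1e-12)
      expect_equal(d$GstHedrick[j], oracle_hedrick(oc, j, 2L), tolerance = 1e-12)
      expect_equal(d$JostD[j], oracle_jostd(oc, j, 2L), tolerance = 1e-12)
      expect_equal(d$JostD_raw[j], oracle_jostd(oc, j, 2L, raw = TRUE),
                   tolerance = 1e-12)
      w <- oracle_wc(oc, j, 2L)
      expect_equal(d$WC_a[j], w$a, tolerance = 1e-12)
      expect_equal(d$WC_b[j], w$b, tolerance = 1e-12)
      expect_equal(d$WC_c[j], w$c, tolerance = 1e-12)
      expect_equal(d$WC_theta[j], w$theta, tolerance = 1e-12)
    }
  }
})

test_that("multilocus theta is the ratio of sums, not the mean of thetas", {
  b <- random_panel(99, max_loci = 50)
  ct <- build_allele_counts(b$panel, b$assignment)
  w <- wc_theta(ct)
  ok <- !is.na(w$a)
  expect_equal(w$theta_multilocus,
               sum(w$a[ok]) / sum(w$a[ok] + w$b[ok] + w$c[ok]),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(w$theta_multilocus, mean(w$theta, na.rm = TRUE))))
})

test_that("statistics are invariant under population reordering and relabeling", {
  b <- random_panel(5)
  ct <- build_allele_counts(b$panel, b$assignment)
  d <- diff_components(ct)
  # reorder populations
  pops <- b$assignment$populations
  a2 <- pop_assignment(as.character(b$assignment$pop_of), populations = rev(pops))
  d2 <- diff_components(build_allele_counts(b$panel, a2))
  expect_equal(d2$Gst73, d$Gst73)
  expect_equal(d2$JostD, d$JostD)
  expect_equal(d2$WC_theta, d$WC_theta)
  # relabel alleles
  set.seed(3); perm <- sample(4)
  p2 <- genotype_panel(matrix(perm[b$panel$matrix], nrow(b$panel$matrix)),
                       2L, b$panel$individual_ids)
  d3 <- diff_components(build_allele_counts(p2, b$assignment))
  expect_equal(d3$Gst73, d$Gst73, tolerance = 1e-12)
  expect_equal(d3$GstNC, d$GstNC, tolerance = 1e-12)
  expect_equal(d3$WC_theta, d$WC_theta, tolerance = 1e-12)
})

test_that("doubling sample sizes fixes Gst73 and moves estimators with n", {
  cc1 <- biallelic_counts(0.2, 0.8, 10)
  cc2 <- biallelic_counts(0.2, 0.8, 20)
  ho1 <- matrix(2L, 1, 2); ho2 <- matrix(4L, 1, 2)
  g1 <- gst_nei73(make_table(cc1, het_obs = ho1))
  g2 <- gst_nei73(make_table(cc2, het_obs = ho2))
  expect_equal(g1$Gst, g2$Gst)
  nc1 <- gst_nei_chesser(make_table(cc1, het_obs = ho1))$Gst
  nc2 <- gst_nei_chesser(make_table(cc2, het_obs = ho2))$Gst
  limit <- 0.36   # infinite-n Gst for these frequencies
  expect_lt(abs(nc2 - limit), abs(nc1 - limit))
})

test_that("shared-allele proportions follow the min-count rule", {
  # i1 AA, i2 AG, i3 GG over locus 1; locus 2: i1 AA, i2 AA, i3 AG
  b <- tiny_bundle(list(P1 = rbind(c(1, 1, 1, 1),
                                   c(1, 2, 1, 1),
                                   c(2, 2, 1, 2))))
  ps <- shared_alleles(b$panel, b$assignment)
  expect_equal(ps$share["i01", "i02"], mean(c(0.5, 1)))   # AA|AG then AA|AA
  expect_equal(ps$share["i01", "i03"], mean(c(0, 0.5)))   # AA|GG then AA|AG
  expect_true(isSymmetric(ps$share))
  expect_equal(diag(ps$share), c(i01 = 1, i02 = 1, i03 = 1))
  # order within genotype is irrelevant: AG vs GA
  b2 <- tiny_bundle(list(P1 = rbind(c(1, 2), c(2, 1))))
  expect_equal(shared_alleles(b2$panel, b2$assignment)$share[1, 2], 1)
})

test_that("shared-allele matrix matches the naive oracle", {
  for (seed in c(3, 14)) {
    b <- random_panel(seed, max_ind = 6, max_loci = 20)
    ps <- shared_alleles(b$panel, b$assignment)
    expect_equal(unname(ps$share), oracle_shared(b$panel), tolerance = 1e-12)
  }
})
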