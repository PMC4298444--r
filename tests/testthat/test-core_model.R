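test_that("allele counting follows the complete-genotype rule", {
  # one pop: AA, AG, GG, plus an individual with a half-call
  b <- tiny_bundle(list(P1 = rbind(c(1, 1), c(1, 2), c(2, 2), c(1, NA))))
  ct <- build_allele_counts(b$panel, b$assignment)
  expect_equal(ct$counts[1, 1, ], c(3L, 3L, 0L, 0L))
  expect_equal(ct$het_obs[1, 1], 1L)
  expect_equal(ct$n_ind_called[1, 1], 3L)   # half-called individual dropped
  expect_equal(ct$n_called[1, 1], 6L)
})

test_that("haploid counting tallies chromosomes directly", {
  m <- matrix(c(1L, 1L, 1L, 2L), 4, 1)
  p <- genotype_panel(m, 1L, sprintf("h%d", 1:4))
  ct <- build_allele_counts(p, pop_assignment(rep("P1", 4)))
  expect_equal(ct$counts[1, 1, ], c(3L, 1L, 0L, 0L))
  expect_equal(ct$n_called[1, 1], 4L)
  expect_equal(ct$het_obs[1, 1], 0L)
})

test_that("counting matches an independent per-entry tally on random panels", {
  for (seed in 1:10) {
    b <- random_panel(seed)
    ct <- build_allele_counts(b$panel, b$assignment)
    oc <- oracle_counts(b$panel, b$assignment)
    expect_equal(unname(ct$counts), oc$counts)
    expect_equal(unname(ct$het_obs), oc$het_obs, ignore_attr = TRUE)
    expect_equal(unname(ct$het_by_allele), oc$het_by_allele)
    expect_equal(unname(ct$n_called), oc$n_called, ignore_attr = TRUE)
    expect_equal(unname(ct$n_ind_called), oc$n_ind_called, ignore_attr = TRUE)
  }
})

test_that("pool_counts sums across populations and conserves n_called", {
  b <- tiny_bundle(list(P1 = rbind(c(1, 1), c(1, 2)),
                        P2 = rbind(c(2, 2), c(1, 2))))
  ct <- build_allele_counts(b$panel, b$assignment)
  pooled <- pool_counts(ct)
  expect_equal(pooled$counts[1, 1, ], c(4L, 4L, 0L, 0L))
  expect_equal(pooled$n_called[1, 1], sum(ct$n_called[1, ]))
  expect_equal(pooled$populations, "total")
  # one population: pooling is the identity on the numbers
  b1 <- tiny_bundle(list(P1 = rbind(c(1, 1), c(1, 2))))
  ct1 <- build_allele_counts(b1$panel, b1$assignment)
  p1 <- pool_counts(ct1)
  expect_equal(unname(p1$counts), unname(ct1$counts))
  # pooled table equals counting on a single-population panel directly
  all_one <- pop_assignment(rep("all", n_individuals(b$panel)))
  direct <- build_allele_counts(b$panel, all_one)
  expect_equal(unname(pooled$counts), unname(direct$counts))
  expect_equal(unname(pooled$het_obs), unname(direct$het_obs))
})

test_that("permuting individuals leaves counts unchanged", {
  b <- random_panel(42)
  n <- n_individuals(b$panel)
  set.seed(1); perm <- sample(n)
  rows <- as.vector(rbind(2 * perm - 1, 2 * perm))
  p2 <- genotype_panel(b$panel$matrix[rows, ], 2L,
                       b$panel$individual_ids[perm])
  a2 <- pop_assignment(as.character(b$assignment$pop_of)[perm],
                       populations = b$assignment$populations)
  expect_equal(unname(build_allele_counts(p2, a2)$counts),
               unname(build_allele_counts(b$panel, b$assignment)$counts))
})

test_that("validate_panel flags degenerate columns and never mutates", {
  m <- cbind(c(NA, NA, NA, NA), c(1L, 1L, 1L, 1L), c(1L, 2L, 1L, 2L))
  p <- genotype_panel(m, 2L, c("i1", "i2"))
  loci <- locus_table(c("L1", "L2", "L3"), "1", 1:3,
                      list("A", c("A", "C"), c("A", "C")))
  before <- p$matrix
  rep_df <- validate_panel(p, loci)
  expect_identical(p$matrix, before)
  expect_setequal(rep_df$flag[rep_df$locus == "L1"], "no data")
  expect_setequal(rep_df$flag[rep_df$locus == "L2"], "monomorphic")
  expect_false("L3" %in% rep_df$locus)
  expect_error(validate_panel(p, loci[1:2, ]), "mismatch")
  # clean panel -> empty report
  clean <- genotype_panel(cbind(c(1L, 2L, 1L, 2L)), 2L, c("i1", "i2"))
  expect_equal(nrow(validate_panel(clean, loci[3, ])), 0L)
})

test_that("removing a monomorphic locus leaves other loci's counts unchanged", {
  b0 <- random_panel(7)
  # splice a known monomorphic column into the middle
  j <- 3L
  m <- cbind(b0$panel$matrix[, 1:2], 1L,
             b0$panel$matrix[, 3:ncol(b0$panel$matrix)])
  b <- list(panel = genotype_panel(m, 2L, b0$panel$individual_ids),
            assignment = b0$assignment)
  ct <- build_allele_counts(b$panel, b$assignment)
  keep <- setdiff(seq_len(ncol(m)), j)
  p2 <- genotype_panel(b$panel$matrix[, keep, drop = FALSE], 2L,
                       b$panel$individual_ids)
  ct2 <- build_allele_counts(p2, b$assignment)
  expect_equal(unname(ct2$counts), unname(ct$counts[keep, , , drop = FALSE]))
})

test_that("constructor invariants are enforced", {
  expect_error(genotype_panel(matrix(5L, 2, 1), 2L, "i1"), "1..4")
  expect_error(genotype_panel(matrix(1L, 3, 1), 2L, "i1"), "ploidy")
  expect_error(pop_assignment(c("a", NA)), "exactly one")
  expect_error(build_allele_counts(
    genotype_panel(matrix(1L, 2, 1), 2L, "i1"),
    pop_assignment(c("a", "b"))), "individuals")
  asg <- pop_assignment(c("a"), populations = c("a", "b"))
  expect_error(build_allele_counts(
    genotype_panel(matrix(1L, 2, 1), 2L, "i1"), asg), "zero individuals")
})
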