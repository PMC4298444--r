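#' Configuration for the panel simulator
#'
#' The simulator emulates a clean multi-population split: each locus draws an
#' ancestral frequency `p0` (uniform on `[0.05, 0.95]` by default, so loci
#' are polymorphic in the ancestor), each population then draws its
#' present-day frequency from the Balding-Nichols beta approximation to
#' drift, `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` with `F = 1 - exp(-tau)` and
#' `tau = t / 2N` the divergence in coalescent units, and genotypes are drawn
#' by binomial sampling under Hardy-Weinberg. Missing calls are masked
#' i.i.d. per allele call. The default sizes mirror a scaled-down version of
#' a two-population split design (the full-size regime being 2 x 500
#' diploids separated by 1000 generations).
#'
#' @param n_pops number of populations (default 2)
#' @param n_ind diploid individuals per population (scalar or vector,
#'   default 50)
#' @param n_loci number of loci (default 1000)
#' @param tau divergence `t/2N` per population (scalar or vector, default 0.1)
#' @param p0_range range of the uniform ancestral-frequency draw
#' @param missing_rate i.i.d. missing-call probability in `[0, 1)`
#' @param ploidy 1 or 2 (default 2)
#' @param seed RNG seed; identical configs give identical panels
#' @param pop_labels population labels (default pop1..popK)
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 2L, n_ind = 50L, n_loci = 1000L, tau = 0.1,
                       p0_range = c(0.05, 0.95), missing_rate = 0,
                       ploidy = 2L, seed = 1L,
                       pop_labels = paste0("pop", seq_len(n_pops))) {
  stopifnot(n_pops >= 1L, all(tau >= 0), missing_rate >= 0, missing_rate < 1)
  structure(list(n_pops = as.integer(n_pops),
                 n_ind = rep_len(as.integer(n_ind), n_pops),
                 n_loci = as.integer(n_loci),
                 tau = rep_len(tau, n_pops),
                 p0_range = p0_range, missing_rate = missing_rate,
                 ploidy = as.integer(ploidy), seed = as.integer(seed),
                 pop_labels = pop_labels),
            class = "sim_config")
}

#' Simulate a SNP panel with known population structure
#'
#' See [sim_config()] for the generating model. Every locus is biallelic at
#' the frequency level (two nucleotide labels drawn per locus); sampling can
#' of course fix one allele in the realized panel.
#'
#' @param config a [sim_config()]
#' @return a [panel_bundle()]; attribute `pop_freqs` holds the latent
#'   per-population allele-2 frequencies (n_loci x n_pops), useful in tests.
#' @export
simulate_panel <- function(config) {
  set.seed(config$seed)
  M <- config$n_loci; K <- config$n_pops; P <- config$ploidy
  p0 <- stats::runif(M, config$p0_range[1], config$p0_range[2])
  Fk <- pmin(pmax(1 - exp(-config$tau), 1e-9), 1 - 1e-9)
  freqs <- matrix(0, M, K)
  for (k in seq_len(K)) {
    freqs[, k] <- stats::rbeta(M, p0 * (1 - Fk[k]) / Fk[k],
                               (1 - p0) * (1 - Fk[k]) / Fk[k])
  }
  n_ind_tot <- sum(config$n_ind)
  H <- n_ind_tot * P
  mat <- matrix(NA_integer_, H, M)
  row0 <- 0L
  for (k in seq_len(K)) {
    hk <- config$n_ind[k] * P
    # one Bernoulli(freq) draw per haplotype: allele 2 with prob freqs[, k]
    draws <- matrix(stats::rbinom(hk * M, 1L,
                                  rep(freqs[, k], each = hk)), hk, M)
    mat[row0 + seq_len(hk), ] <- 1L + draws
    row0 <- row0 + hk
  }
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(mat)) < config$missing_rate
    mat[mask] <- NA_integer_
  }
  nucs <- c("A", "C", "G", "T")
  labels <- lapply(seq_len(M), function(j) sample(nucs, 2L))
  ids <- unlist(lapply(seq_len(K), function(k) {
    sprintf("%s_i%03d", config$pop_labels[k], seq_len(config$n_ind[k]))
  }))
  panel <- genotype_panel(mat, P, ids)
  loci <- locus_table(sprintf("snp%06d", seq_len(M)), "1", seq_len(M), labels)
  assignment <- pop_assignment(rep(config$pop_labels, config$n_ind),
                               populations = config$pop_labels)
  bundle <- panel_bundle(panel, loci, assignment)
  attr(bundle, "pop_freqs") <- freqs
  bundle
}

#' Write a panel bundle in one of the three supported input dialects
#'
#' Each writer emits a file the corresponding reader parses back to an
#' equivalent bundle (allele indices may be permuted: ped orders codes
#' lexicographically, VCF puts REF first). For `"vcf"` a popmap sidecar is
#' written next to the file (`<path>.popmap`) so the population structure
#' survives the round trip; for `"ped"` `path` is the stem and `<path>.ped` /
#' `<path>.map` are written. The arp writer emits `GenotypicData=1` blocks
#' (two rows per individual) for diploid bundles and haplotype blocks
#' (`GenotypicData=0`) for haploid ones, so ploidy round-trips.
#'
#' @param bundle a [panel_bundle()]
#' @param format `"vcf"`, `"ped"` or `"arp"`
#' @param path output path (stem for `"ped"`)
#' @return invisibly, the path(s) written.
#' @export
write_panel <- function(bundle, format = c("vcf", "ped", "arp"), path) {
  format <- match.arg(format)
  switch(format,
         vcf = write_vcf_panel(bundle, path),
         ped = write_ped_panel(bundle, path),
         arp = write_arp_panel(bundle, path))
}

miss_tok <- function(x, miss) ifelse(is.na(x), miss, x)

write_vcf_panel <- function(bundle, path) {
  panel <- bundle$panel; loci <- bundle$loci
  stopifnot(panel$ploidy == 2L)
  n_ind <- n_individuals(panel)
  hdr <- c("##fileformat=VCFv4.1",
           "##source=panelpop",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$individual_ids), collapse = "\t"))
  a1 <- panel$matrix[seq(1L, 2L * n_ind, by = 2L), , drop = FALSE] - 1L
  a2 <- panel$matrix[seq(2L, 2L * n_ind, by = 2L), , drop = FALSE] - 1L
  body <- vapply(seq_len(n_loci(panel)), function(j) {
    lab <- loci$allele_labels[[j]]
    alt <- if (length(lab) > 1L) paste(lab[-1L], collapse = ",") else "."
    gt <- paste0(miss_tok(a1[, j], "."), "/", miss_tok(a2[, j], "."))
    paste(c(loci$chrom[j], loci$position[j], loci$locus_id[j], lab[1L], alt,
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  pm <- paste0(path, ".popmap")
  writeLines(paste(panel$individual_ids, as.character(bundle$assignment$pop_of),
                   sep = "\t"), pm)
  invisible(c(path, pm))
}

write_ped_panel <- function(bundle, stem) {
  panel <- bundle$panel; loci <- bundle$loci
  stopifnot(panel$ploidy == 2L)
  n_ind <- n_individuals(panel); M <- n_loci(panel)
  a1 <- panel$matrix[seq(1L, 2L * n_ind, by = 2L), , drop = FALSE]
  a2 <- panel$matrix[seq(2L, 2L * n_ind, by = 2L), , drop = FALSE]
  lab_of <- function(am) {
    out <- matrix("0", n_ind, M)
    for (j in seq_len(M)) {
      out[, j] <- miss_tok(loci$allele_labels[[j]][am[, j]], "0")
    }
    out
  }
  l1 <- lab_of(a1); l2 <- lab_of(a2)
  # complete-genotype on output: a half-called genotype is written "0 0"
  half <- is.na(a1) != is.na(a2)
  l1[half] <- "0"; l2[half] <- "0"
  geno <- matrix("", n_ind, 2L * M)
  geno[, seq(1L, 2L * M, by = 2L)] <- l1
  geno[, seq(2L, 2L * M, by = 2L)] <- l2
  lead <- cbind(as.character(bundle$assignment$pop_of),
                panel$individual_ids, "0", "0", "0", "-9")
  writeLines(apply(cbind(lead, geno), 1L, paste, collapse = " "),
             paste0(stem, ".ped"))
  writeLines(paste(loci$chrom, loci$locus_id, "0", loci$position, sep = "\t"),
             paste0(stem, ".map"))
  invisible(paste0(stem, c(".ped", ".map")))
}

write_arp_panel <- function(bundle, path) {
  panel <- bundle$panel; loci <- bundle$loci
  genotypic <- panel$ploidy == 2L
  pops <- bundle$assignment$populations
  pop_of <- as.character(bundle$assignment$pop_of)
  lab_at <- function(row) {
    vapply(seq_len(n_loci(panel)), function(j) {
      a <- panel$matrix[row, j]
      if (is.na(a)) "?" else loci$allele_labels[[j]][a]
    }, "")
  }
  out <- c("[Profile]",
           "\tTitle=\"panelpop simulated panel\"",
           paste0("\tNbSamples=", length(pops)),
           "\tDataType=STANDARD",
           paste0("\tGenotypicData=", if (genotypic) 1L else 0L),
           "\tLocusSeparator=WHITESPACE",
           "\tMissingData='?'",
           "",
           "[Data]",
           "[[Samples]]")
  for (k in seq_along(pops)) {
    ind <- which(pop_of == pops[k])
    out <- c(out,
             paste0("\tSampleName=\"", pops[k], "\""),
             paste0("\tSampleSize=", length(ind)),
             "\tSampleData= {")
    for (i in ind) {
      if (genotypic) {
        out <- c(out,
                 paste(c(panel$individual_ids[i], "1", lab_at(2L * i - 1L)),
                       collapse = "\t"),
                 paste(c("", "", lab_at(2L * i)), collapse = "\t"))
      } else {
        out <- c(out,
                 paste(c(panel$individual_ids[i], "1", lab_at(i)),
                       collapse = "\t"))
      }
    }
    out <- c(out, "}")
  }
  writeLines(out, path)
  invisible(path)
}
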