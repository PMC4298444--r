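#' Construct a genotype panel
#'
#' A panel stores SNP calls as an integer haplotype-by-locus matrix. Rows are
#' chromosome copies: a diploid individual `i` owns rows `2i - 1` and `2i`, a
#' haploid individual owns row `i`. Entries are per-locus allele indices in
#' `1..4` (each locus carries its own label set, see [locus_table()]); missing
#' calls are `NA`.
#'
#' @param matrix integer matrix, `H x M` with `H = n_individuals * ploidy`.
#'   Non-missing entries must lie in `1..4`.
#' @param ploidy 1 or 2. Panel-wide; mixed-ploidy data is rejected by the
#'   readers.
#' @param individual_ids character vector of individual identifiers,
#'   length `H / ploidy`.
#' @return An object of class `genotype_panel`: a list with elements
#'   `matrix`, `ploidy`, `individual_ids`.
#' @examples
#' m <- rbind(c(1L, 1L), c(1L, 2L), c(2L, NA), c(2L, 1L))
#' genotype_panel(m, ploidy = 2, individual_ids = c("i1", "i2"))
#' @export
genotype_panel <- function(matrix, ploidy, individual_ids) {
  storage.mode(matrix) <- "integer"
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  if (nrow(matrix) != length(individual_ids) * ploidy) {
    stop("nrow(matrix) must equal length(individual_ids) * ploidy")
  }
  rng <- range(matrix, na.rm = TRUE)
  if (nrow(matrix) > 0 && ncol(matrix) > 0 && !all(is.na(matrix))) {
    if (rng[1] < 1L || rng[2] > 4L) {
      stop("allele indices must be in 1..4 (NA = missing)")
    }
  }
  structure(
    list(matrix = matrix, ploidy = as.integer(ploidy),
         individual_ids = as.character(individual_ids)),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals (ploidy %d), %d loci\n",
              length(x$individual_ids), x$ploidy, ncol(x$matrix)))
  invisible(x)
}

#' Number of individuals / loci in a panel
#' @param panel a [genotype_panel()]
#' @return integer count.
#' @export
n_individuals <- function(panel) length(panel$individual_ids)

#' @rdname n_individuals
#' @export
n_loci <- function(panel) ncol(panel$matrix)

#' Map haplotype rows to individuals
#'
#' @param panel a [genotype_panel()]
#' @return data.frame with one row per haplotype row: `individual` (index) and
#'   `copy` (chromosome copy, `1..ploidy`).
#' @export
haplotype_of <- function(panel) {
  h <- nrow(panel$matrix)
  data.frame(individual = rep(seq_len(n_individuals(panel)), each = panel$ploidy),
             copy = rep(seq_len(panel$ploidy), times = n_individuals(panel)))[seq_len(h), ]
}

#' Per-locus metadata table
#'
#' @param locus_id character locus identifiers.
#' @param chrom character chromosome labels.
#' @param position 1-based integer positions.
#' @param allele_labels list of character vectors (length 1..4 each), giving
#'   the label of allele index 1, 2, ... at each locus. Index order is
#'   reader-defined: REF then ALT order for VCF, lexicographic for ped,
#'   first appearance for arp.
#' @return data.frame of class `locus_table` with a list-column
#'   `allele_labels`.
#' @export
locus_table <- function(locus_id, chrom = "1",
                        position = seq_along(locus_id),
                        allele_labels) {
  n <- length(locus_id)
  stopifnot(length(allele_labels) == n)
  bad <- vapply(allele_labels, function(a) {
    length(a) < 1L || length(a) > 4L || anyDuplicated(a) > 0L
  }, logical(1))
  if (any(bad)) {
    stop("allele_labels must be 1..4 distinct labels per locus; offending locus: ",
         locus_id[which(bad)[1]])
  }
  out <- data.frame(locus_id = as.character(locus_id),
                    chrom = rep_len(as.character(chrom), n),
                    position = rep_len(as.integer(position), n),
                    stringsAsFactors = FALSE)
  out$allele_labels <- allele_labels
  class(out) <- c("locus_table", "data.frame")
  out
}

#' Population assignment of individuals
#'
#' @param pop_of character/factor vector, one population label per individual
#'   (panel order).
#' @param populations optional ordered set of population labels; defaults to
#'   order of first appearance.
#' @return object of class `pop_assignment`: list with `pop_of` (factor) and
#'   `populations` (character).
#' @export
pop_assignment <- function(pop_of, populations = NULL) {
  pop_of <- as.character(pop_of)
  if (anyNA(pop_of)) stop("every individual must map to exactly one population")
  if (is.null(populations)) populations <- unique(pop_of)
  if (!all(pop_of %in% populations)) {
    stop("pop_of contains labels not in populations")
  }
  structure(list(pop_of = factor(pop_of, levels = populations),
                 populations = populations),
            class = "pop_assignment")
}

#' @export
print.pop_assignment <- function(x, ...) {
  tb <- table(x$pop_of)
  cat("<pop_assignment>", length(x$pop_of), "individuals in",
      length(x$populations), "populations:\n")
  print(tb)
  invisible(x)
}

#' Bundle a panel with its locus table and population assignment
#'
#' The unit every reader returns and every writer/engine entry point consumes.
#'
#' @param panel a [genotype_panel()]
#' @param loci a [locus_table()] with `n_loci(panel)` rows
#' @param assignment a [pop_assignment()] covering the panel's individuals
#' @return list of class `panel_bundle`.
#' @export
panel_bundle <- function(panel, loci, assignment) {
  if (nrow(loci) != n_loci(panel)) {
    stop("loci table rows (", nrow(loci), ") != panel columns (", n_loci(panel), ")")
  }
  if (length(assignment$pop_of) != n_individuals(panel)) {
    stop("assignment covers ", length(assignment$pop_of),
         " individuals, panel has ", n_individuals(panel))
  }
  structure(list(panel = panel, loci = loci, assignment = assignment),
            class = "panel_bundle")
}

#' @export
print.panel_bundle <- function(x, ...) {
  cat(sprintf("<panel_bundle> %d individuals (ploidy %d) x %d loci, %d populations\n",
              n_individuals(x$panel), x$panel$ploidy, n_loci(x$panel),
              length(x$assignment$populations)))
  invisible(x)
}

#' Validate a panel against its locus table
#'
#' Reports (without mutating anything) loci that carry no data at all, loci
#' that are monomorphic, and dimension problems. More than 4 distinct alleles
#' at a locus cannot be represented and is rejected by the readers; the check
#' is repeated here for panels built by hand.
#'
#' @param panel a [genotype_panel()]
#' @param loci a [locus_table()]
#' @return data.frame with columns `locus`, `flag` (one row per finding;
#'   zero rows for a clean panel).
#' @export
validate_panel <- function(panel, loci) {
  if (nrow(loci) != n_loci(panel)) {
    stop("dimension mismatch: ", nrow(loci), " loci vs ", n_loci(panel), " columns")
  }
  m <- panel$matrix
  n_distinct <- apply(m, 2, function(col) length(unique(col[!is.na(col)])))
  flags <- character(0); which_l <- integer(0)
  all_missing <- n_distinct == 0L
  mono <- n_distinct == 1L
  over <- n_distinct > 4L   # unreachable through genotype_panel(), kept defensive
  nl <- vapply(seq_len(ncol(m)), function(j) {
    length(loci$allele_labels[[j]])
  }, integer(1))
  too_few_labels <- n_distinct > nl
  add <- function(idx, what) {
    which_l <<- c(which_l, idx); flags <<- c(flags, rep(what, length(idx)))
  }
  add(which(all_missing), "no data")
  add(which(mono), "monomorphic")
  add(which(over), ">4 alleles")
  add(which(too_few_labels), "more alleles observed than labels")
  data.frame(locus = loci$locus_id[which_l], flag = flags,
             stringsAsFactors = FALSE)
}
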