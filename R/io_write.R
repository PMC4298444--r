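# All tables are tab-separated; doubles are printed with %.17g so a written
# value re-parses to the identical double and cross-run byte comparison works.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, "")
  out
}

fmt_frame <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  }
  df
}

#' Write the per-locus statistics table
#'
#' One row per locus, one column per statistic, `"NA"` for values that are
#' not defined at that locus. Doubles are written at full precision.
#'
#' @param results per-locus data.frame (as produced by [run_panel()])
#' @param path output path
#' @export
write_per_locus <- function(results, path) {
  utils::write.table(fmt_frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Write the across-locus summary table
#'
#' One row per statistic with its mean, variance (over defined loci only)
#' and the count of defined loci; the `multilocus` column carries
#' component-based multilocus values where those exist (ratio-of-sums
#' Weir-Cockerham theta, component-recomputed Gst/G'st/D).
#'
#' @param summary data.frame with columns `statistic`, `mean`, `variance`,
#'   `n_defined`, `multilocus`
#' @param path output path
#' @export
write_summary <- function(summary, path) {
  utils::write.table(fmt_frame(summary), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Write a single-population spectrum as a two-column table
#' @param sfs an [single_sfs()] result
#' @param path output path
#' @export
write_sfs <- function(sfs, path) {
  utils::write.table(data.frame(bin = 0:sfs$n, count = sfs$spectrum),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a joint spectrum in a dadi-style flattened layout
#'
#' First line: the shape `(n_1+1) ... (n_s+1)` followed by `folded` or
#' `unfolded`; second line: the counts in row-major order (last population's
#' axis fastest), the layout dadi and ABC pipelines consume.
#'
#' @param jsfs a [joint_sfs()] result
#' @param path output path
#' @export
write_joint_sfs <- function(jsfs, path) {
  dims <- jsfs$n_k + 1L
  flat <- as.vector(aperm(jsfs$spectrum, rev(seq_along(dims))))
  writeLines(c(paste(c(dims, if (jsfs$folded) "folded" else "unfolded"),
                     collapse = " "),
               paste(flat, collapse = " ")), path)
}

#' Write the pairwise shared-allele matrix
#'
#' Square tab-separated matrix with individual ids as row/column headers and
#' a `population` column.
#'
#' @param ps a [shared_alleles()] result
#' @param path output path
#' @export
write_pair_share <- function(ps, path) {
  m <- ps$share
  df <- data.frame(individual = ps$individual_ids,
                   population = ps$pop_of,
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(m)
  names(vals) <- ps$individual_ids
  utils::write.table(cbind(df, fmt_frame(vals)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
}
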