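#' Run configuration for the statistics engine
#'
#' @param format input dialect: `"vcf"`, `"ped"`, `"arp"`, or `"bundle"` for
#'   an in-memory [panel_bundle()] passed via `bundle`.
#' @param path input file (VCF or arp), or the ped/map stem unless `ped` and
#'   `map` are given explicitly.
#' @param ped,map explicit ped/map paths (override `path`).
#' @param popmap optional VCF popmap sidecar path.
#' @param bundle in-memory [panel_bundle()] (with `format = "bundle"`).
#' @param stats statistics to compute, a subset of
#'   `c("freq","het","sfs","jointsfs","gst","d","wc","shared")`.
#' @param workers parallel workers (forked; 1 = serial). Outputs are
#'   byte-identical for any worker count.
#' @param chunk_size loci per chunk; outputs are byte-identical for any
#'   chunk size.
#' @param out_prefix output path prefix; `NULL` suppresses file output.
#' @param he `"unbiased"` or `"raw"` expected-heterozygosity estimator.
#' @param variance `"pop"` (1/n) or `"sample"` (1/(n-1)) across-locus
#'   variance denominator.
#' @param folded fold the spectra (default `TRUE`).
#' @param clamp_negative clamp negative differentiation estimates to 0 in
#'   the outputs (default `FALSE`: report as computed).
#' @param jost_raw use raw Hs/Ht in Jost's D.
#' @param log_file optional log path (skipped-site and exclusion tallies).
#' @param seed optional RNG seed (the engine itself is deterministic; kept
#'   for subsampling extensions).
#' @return list of class `run_config`.
#' @export
run_config <- function(format = c("vcf", "ped", "arp", "bundle"),
                       path = NULL, ped = NULL, map = NULL, popmap = NULL,
                       bundle = NULL,
                       stats = c("freq", "het", "sfs", "jointsfs", "gst",
                                 "d", "wc", "shared"),
                       workers = 1L, chunk_size = 10000L, out_prefix = NULL,
                       he = c("unbiased", "raw"),
                       variance = c("pop", "sample"),
                       folded = TRUE, clamp_negative = FALSE,
                       jost_raw = FALSE, log_file = NULL, seed = NULL) {
  format <- match.arg(format)
  he <- match.arg(he); variance <- match.arg(variance)
  known <- c("freq", "het", "sfs", "jointsfs", "gst", "d", "wc", "shared")
  bad <- setdiff(stats, known)
  if (length(bad)) stop("unknown statistic(s): ", paste(bad, collapse = ", "))
  if (length(stats) == 0L) stop("no statistics selected")
  if (workers < 1L || chunk_size < 1L) stop("workers and chunk_size must be >= 1")
  structure(list(format = format, path = path, ped = ped, map = map,
                 popmap = popmap, bundle = bundle, stats = stats,
                 workers = as.integer(workers),
                 chunk_size = as.integer(chunk_size),
                 out_prefix = out_prefix, he = he, variance = variance,
                 folded = folded, clamp_negative = clamp_negative,
                 jost_raw = jost_raw, log_file = log_file, seed = seed),
            class = "run_config")
}

load_bundle <- function(config) {
  switch(config$format,
         bundle = {
           if (is.null(config$bundle)) stop("format 'bundle' needs a bundle")
           config$bundle
         },
         vcf = read_vcf(config$path, config$popmap),
         ped = {
           ped <- if (!is.null(config$ped)) config$ped else paste0(config$path, ".ped")
           map <- if (!is.null(config$map)) config$map else paste0(config$path, ".map")
           read_ped_map(ped, map)
         },
         arp = read_arp(config$path),
         stop("unknown format: ", config$format))
}

# Per-chunk per-locus statistics, as a plain named list of vectors (one
# data.frame is assembled after the merge: building a frame per chunk is too
# slow for single-locus chunks). Every locus is computed independently of
# every other, so any partition of the loci yields identical values.
compute_chunk <- function(table, loci_idx, opts) {
  ct <- subset_counts(table, loci_idx)
  out <- list()
  pops <- table$populations
  if (opts$do_freq) {
    for (k in seq_along(pops)) {
      p <- allele_frequencies(ct, k)
      for (a in 1:4) out[[sprintf("freq_%s_%d", pops[k], a)]] <- p[, a]
    }
  }
  if (opts$do_het) {
    for (k in seq_along(pops)) {
      out[[paste0("Ho_", pops[k])]] <- observed_heterozygosity(ct, k)
      out[[paste0("He_", pops[k])]] <-
        expected_heterozygosity(ct, k, unbiased = opts$he_unbiased)
    }
  }
  if (opts$do_diff && length(pops) >= 2L) {
    d <- diff_components_list(ct)
    clamp <- if (opts$clamp) function(x) pmax(x, 0) else identity
    if (opts$do_gst) {
      out$Hs <- d$Hs; out$Ht <- d$Ht
      out$Gst73 <- clamp(d$Gst73)
      out$GstNC <- clamp(d$GstNC)
      out$GstHedrick <- clamp(d$GstHedrick)
    }
    if (opts$do_d) {
      out$JostD <- clamp(if (opts$jost_raw) d$JostD_raw else d$JostD)
    }
    if (opts$do_wc) {
      out$WC_a <- d$WC_a; out$WC_b <- d$WC_b; out$WC_c <- d$WC_c
      out$WC_theta <- clamp(d$WC_theta)
    }
  }
  out
}

chunk_opts <- function(config) {
  list(do_freq = "freq" %in% config$stats,
       do_het = "het" %in% config$stats,
       do_gst = "gst" %in% config$stats,
       do_d = "d" %in% config$stats,
       do_wc = "wc" %in% config$stats,
       do_diff = any(c("gst", "d", "wc") %in% config$stats),
       do_shared = "shared" %in% config$stats,
       he_unbiased = config$he == "unbiased",
       clamp = config$clamp_negative,
       jost_raw = config$jost_raw)
}

#' Run the statistics engine
#'
#' Loads the panel, partitions loci into contiguous chunks, computes the
#' per-locus statistics chunk by chunk (optionally across forked workers; no
#' statistic uses information across loci, so chunks are independent), and
#' merges results in chunk order. Summaries, spectra and the multilocus
#' Weir-Cockerham components are reduced over the merged full-length
#' per-locus vectors, so output files are byte-identical for any `workers` /
#' `chunk_size` combination.
#'
#' @param config a [run_config()]
#' @return list of class `run_result` with elements `per_locus` (data.frame),
#'   `summary` (data.frame), `sfs` (list per population), `joint_sfs`,
#'   `pair_share`, `wc_multilocus`, `table` (the allele-count table),
#'   `log` (character); file outputs are written when `out_prefix` is set.
#' @export
run_panel <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  bundle <- load_bundle(config)
  panel <- bundle$panel
  table <- build_allele_counts(panel, bundle$assignment)
  M <- n_loci(panel)
  logs <- c(sprintf("panel: %d individuals (ploidy %d), %d loci, %d populations",
                    n_individuals(panel), panel$ploidy, M,
                    length(table$populations)))
  skipped <- attr(bundle, "n_skipped_sites")
  if (!is.null(skipped)) logs <- c(logs, sprintf("skipped sites (>4 alleles): %d", skipped))

  chunks <- split(seq_len(M), ceiling(seq_len(M) / config$chunk_size))
  opts <- chunk_opts(config)
  worker <- function(idx) {
    list(per_locus = compute_chunk(table, chunks[[idx]], opts),
         shared = if (opts$do_shared)
           shared_partial(panel, chunks[[idx]]) else NULL)
  }
  parts <- if (config$workers > 1L) {
    parallel::mclapply(seq_along(chunks), worker,
                       mc.cores = config$workers, mc.preschedule = TRUE)
  } else {
    lapply(seq_along(chunks), worker)
  }
  err <- vapply(parts, inherits, logical(1), "try-error")
  if (any(err)) stop("worker failure: ", parts[[which(err)[1]]])

  # merge in chunk-index order: concatenate each per-locus column
  per_locus <- data.frame(locus_id = bundle$loci$locus_id,
                          chrom = bundle$loci$chrom,
                          position = bundle$loci$position,
                          stringsAsFactors = FALSE)
  for (cn in names(parts[[1]]$per_locus)) {
    per_locus[[cn]] <- unlist(lapply(parts, function(p) p$per_locus[[cn]]),
                              use.names = FALSE)
  }
  rownames(per_locus) <- NULL

  # summaries over merged per-locus vectors (chunking-invariant by design)
  stat_cols <- setdiff(names(per_locus), c("locus_id", "chrom", "position"))
  summ <- data.frame(statistic = character(0), mean = numeric(0),
                     variance = numeric(0), n_defined = integer(0),
                     multilocus = numeric(0), stringsAsFactors = FALSE)
  if (length(stat_cols)) summ <- do.call(rbind, lapply(stat_cols, function(cn) {
    s <- summarize_stat(per_locus[[cn]], sample = config$variance == "sample")
    data.frame(statistic = cn, mean = s$mean, variance = s$variance,
               n_defined = s$count, multilocus = NA_real_,
               stringsAsFactors = FALSE)
  }))
  wc_multi <- NULL
  if (!is.null(summ) && nrow(summ)) {
    ml <- function(stat, value) {
      summ$multilocus[summ$statistic == stat] <<- value
    }
    if (all(c("Hs", "Ht", "Gst73") %in% stat_cols)) {
      ok <- !is.na(per_locus$Gst73)
      sHs <- sum(per_locus$Hs[ok]); sHt <- sum(per_locus$Ht[ok])
      if (any(ok) && sHt != 0) ml("Gst73", (sHt - sHs) / sHt)
    }
    if ("WC_theta" %in% stat_cols) {
      ok <- !is.na(per_locus$WC_a)
      denom <- sum(per_locus$WC_a[ok] + per_locus$WC_b[ok] + per_locus$WC_c[ok])
      wc_multi <- if (any(ok) && denom != 0) sum(per_locus$WC_a[ok]) / denom else NA_real_
      ml("WC_theta", wc_multi)
    }
  }

  sfs_list <- NULL; jsfs <- NULL
  if ("sfs" %in% config$stats) {
    sfs_list <- lapply(table$populations, function(p)
      single_sfs(table, p, folded = config$folded))
    names(sfs_list) <- table$populations
    for (s in sfs_list) {
      logs <- c(logs, sprintf(
        "sfs %s: mass %d, excluded %d (missing) + %d (multiallelic)",
        s$pop, s$n_loci, s$n_excluded_missing, s$n_excluded_multiallelic))
    }
  }
  if ("jointsfs" %in% config$stats && length(table$populations) >= 2L) {
    jsfs <- joint_sfs(table, table$populations, folded = config$folded)
    logs <- c(logs, sprintf("joint sfs: mass %d over %s", jsfs$n_loci,
                            paste(jsfs$pops, collapse = " x ")))
  }
  pair_share <- NULL
  if ("shared" %in% config$stats) {
    S <- Reduce(`+`, lapply(parts, function(p) p$shared$S))
    N <- Reduce(`+`, lapply(parts, function(p) p$shared$N))
    share <- S / N; share[N == 0L] <- NA_real_
    ids <- panel$individual_ids
    dimnames(share) <- list(ids, ids)
    pair_share <- structure(list(share = share, n_loci_used = N,
                                 individual_ids = ids,
                                 pop_of = as.character(bundle$assignment$pop_of)),
                            class = "pair_share")
  }
  logs <- c(logs, sprintf("elapsed: %.2f s", proc.time()[["elapsed"]] - t0))

  res <- structure(list(per_locus = per_locus, summary = summ,
                        sfs = sfs_list, joint_sfs = jsfs,
                        pair_share = pair_share, wc_multilocus = wc_multi,
                        table = table, log = logs),
                   class = "run_result")
  if (!is.null(config$out_prefix)) write_outputs(res, config)
  res
}

write_outputs <- function(res, config) {
  pre <- config$out_prefix
  write_per_locus(res$per_locus, paste0(pre, "_perlocus.tsv"))
  write_summary(res$summary, paste0(pre, "_summary.tsv"))
  if (!is.null(res$sfs)) {
    for (p in names(res$sfs)) {
      write_sfs(res$sfs[[p]], paste0(pre, "_sfs_", p, ".tsv"))
    }
  }
  if (!is.null(res$joint_sfs)) {
    write_joint_sfs(res$joint_sfs, paste0(pre, "_jointsfs.tsv"))
  }
  if (!is.null(res$pair_share)) {
    write_pair_share(res$pair_share, paste0(pre, "_shared.tsv"))
  }
  logf <- if (!is.null(config$log_file)) config$log_file else paste0(pre, ".log")
  writeLines(res$log, logf)
  invisible(NULL)
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Merge across-locus summary partial sums
#'
#' Utility implementing the documented partial-sum merge contract: each
#' partial carries `(sum, sumsq, n)` over the defined loci of one chunk; the
#' pooled mean and variance come from the exactly summed partials. Note
#' [run_panel()] itself reduces over merged per-locus vectors instead (see
#' the methods vignette for why), but the pooled values agree to numerical
#' precision.
#'
#' @param partials list of lists with elements `sum`, `sumsq`, `n`
#' @param sample logical; sample (n-1) variance denominator
#' @return list with `mean`, `variance`, `count`.
#' @export
merge_summaries <- function(partials, sample = FALSE) {
  sx <- 0; sxx <- 0; n <- 0L
  for (p in partials) {
    if (is.null(p) || p$n == 0L) next     # empty chunk: neutral element
    sx <- sx + p$sum; sxx <- sxx + p$sumsq; n <- n + p$n
  }
  if (n == 0L) return(list(mean = NA_real_, variance = NA_real_, count = 0L))
  m <- sx / n
  ss <- sxx - n * m^2
  var <- if (sample) { if (n > 1L) ss / (n - 1) else NA_real_ } else ss / n
  list(mean = m, variance = max(var, 0), count = n)
}
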