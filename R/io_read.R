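#' Read a VCF (v4.1) file into a panel bundle
#'
#' Plain or gzip text VCF with GT genotypes. Sites with up to 3 ALT alleles
#' (REF + ALT <= 4 labels) are accepted; sites with more are skipped and
#' counted (reported via a warning and the `n_skipped_sites` attribute).
#' `"./."` and half-called genotypes become missing calls; `|` and `/`
#' separators are both accepted. Allele index 1 is REF, then ALT order.
#'
#' @param path VCF file (`.vcf` or `.vcf.gz`)
#' @param popmap optional two-column whitespace file (sample, population);
#'   must cover exactly the VCF samples. Without it all samples form one
#'   population `"pop1"`.
#' @return a [panel_bundle()]; attribute `n_skipped_sites` counts sites
#'   dropped for having more than 3 ALT alleles.
#' @export
read_vcf <- function(path, popmap = NULL) {
  con <- gzfile(path, "rt"); on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L || !startsWith(lines[1], "##fileformat")) {
    stop("malformed VCF header: missing ##fileformat line")
  }
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) != 1L) stop("malformed VCF header: expected one #CHROM line")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10L) stop("VCF has no sample columns")
  if (hdr[9] != "FORMAT") stop("malformed VCF header: no FORMAT column")
  samples <- hdr[-(1:9)]
  body <- lines[seq_len(length(lines)) > hdr_i]
  body <- body[nzchar(body)]

  n_ind <- length(samples)
  ploidy <- NA_integer_
  cols <- vector("list", length(body))
  ids <- chroms <- character(length(body)); poss <- integer(length(body))
  labels <- vector("list", length(body))
  keep <- logical(length(body))
  n_skipped <- 0L
  for (r in seq_along(body)) {
    f <- strsplit(body[r], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr)) {
      stop("VCF data line ", r, " has ", length(f), " fields, expected ", length(hdr))
    }
    alts <- if (f[5] %in% c(".", "")) character(0) else
      strsplit(f[5], ",", fixed = TRUE)[[1]]
    if (length(alts) > 3L) { n_skipped <- n_skipped + 1L; next }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gi <- match("GT", fmt)
    if (is.na(gi)) stop("no GT subfield at ", f[1], ":", f[2])
    gts <- f[-(1:9)]
    if (length(fmt) > 1L) {
      gts <- vapply(strsplit(gts, ":", fixed = TRUE), `[`, "", gi)
    }
    al <- strsplit(gsub("|", "/", gts, fixed = TRUE), "/", fixed = TRUE)
    lens <- lengths(al)
    if (any(lens < 1L | lens > 2L)) stop("unsupported ploidy in GT at line ", r)
    p <- max(lens)
    if (is.na(ploidy)) ploidy <- p
    if (ploidy == 1L && p == 2L) stop("mixed ploidy across sites is not supported")
    if (ploidy == 2L && any(lens == 1L)) {
      # lone-allele call in a diploid panel: treat as half-call
      al[lens == 1L] <- lapply(al[lens == 1L], function(x) c(x, "."))
    }
    v <- suppressWarnings(as.integer(unlist(al))) + 1L
    if (any(!is.na(v) & (v < 1L | v > length(alts) + 1L))) {
      stop("GT allele index out of range at ", f[1], ":", f[2])
    }
    keep[r] <- TRUE
    cols[[r]] <- v
    ids[r] <- if (f[3] == ".") paste0(f[1], ":", f[2]) else f[3]
    chroms[r] <- f[1]; poss[r] <- as.integer(f[2])
    labels[[r]] <- c(f[4], alts)
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " site(s) with more than 3 ALT alleles skipped")
  }
  if (is.na(ploidy)) ploidy <- 2L
  mat <- do.call(cbind, cols[keep])
  if (is.null(mat)) mat <- matrix(NA_integer_, n_ind * ploidy, 0L)
  panel <- genotype_panel(mat, ploidy, samples)
  loci <- locus_table(ids[keep], chroms[keep], poss[keep], labels[keep])
  assignment <- if (is.null(popmap)) {
    pop_assignment(rep("pop1", n_ind))
  } else {
    read_popmap(popmap, samples)
  }
  bundle <- panel_bundle(panel, loci, assignment)
  attr(bundle, "n_skipped_sites") <- n_skipped
  bundle
}

#' Read a sample-to-population map
#'
#' @param path two-column whitespace-delimited file: sample id, population.
#' @param samples sample ids in panel order; the map must name exactly these.
#' @return a [pop_assignment()] in `samples` order.
#' @export
read_popmap <- function(path, samples) {
  pm <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("sample", "pop"))
  unknown <- setdiff(pm$sample, samples)
  if (length(unknown)) stop("popmap names unknown sample(s): ",
                            paste(unknown, collapse = ", "))
  missing <- setdiff(samples, pm$sample)
  if (length(missing)) stop("popmap does not cover sample(s): ",
                            paste(missing, collapse = ", "))
  pop_assignment(pm$pop[match(samples, pm$sample)],
                 populations = unique(pm$pop))
}

#' Read a PLINK ped/map pair into a panel bundle
#'
#' Whitespace-delimited ped with the six leading columns FID, IID, father,
#' mother, sex, phenotype, then two allele columns per locus. The FID column
#' defines the population assignment. Allele code `"0"` is missing (and, by
#' the complete-genotype rule, masks the partner allele too). Allele indices
#' at each locus follow the lexicographic order of the observed codes.
#'
#' @param ped,map file paths; the map needs columns chrom, id, (cM,) position.
#' @return a [panel_bundle()] (always diploid).
#' @export
read_ped_map <- function(ped, map) {
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) < 3L) stop("map file needs at least 3 columns")
  pos_col <- if (ncol(mp) >= 4L) 4L else 3L
  M <- nrow(mp)
  rows <- strsplit(trimws(readLines(ped)), "[ \t]+")
  rows <- rows[lengths(rows) > 0L]
  n_ind <- length(rows)
  wid <- unique(lengths(rows))
  if (length(wid) != 1L) stop("ped rows have differing column counts")
  if ((wid - 6L) %% 2L != 0L) stop("odd number of allele columns in ped")
  if ((wid - 6L) / 2L != M) {
    stop("ped has ", (wid - 6L) / 2L, " loci but map has ", M)
  }
  fid <- vapply(rows, `[`, "", 1L)
  iid <- vapply(rows, `[`, "", 2L)
  am <- matrix(unlist(lapply(rows, `[`, -(1:6))), nrow = n_ind, byrow = TRUE)
  a1 <- am[, seq(1L, 2L * M, by = 2L), drop = FALSE]
  a2 <- am[, seq(2L, 2L * M, by = 2L), drop = FALSE]
  mat <- matrix(NA_integer_, 2L * n_ind, M)
  labels <- vector("list", M)
  for (j in seq_len(M)) {
    codes <- sort(unique(c(a1[, j], a2[, j])))
    codes <- codes[codes != "0"]
    if (length(codes) > 4L) {
      stop("locus ", mp[j, 2L], " has more than 4 alleles")
    }
    if (length(codes) == 0L) codes <- "N"   # all-missing column still needs a label
    labels[[j]] <- codes
    i1 <- match(a1[, j], codes); i2 <- match(a2[, j], codes)
    mat[seq(1L, 2L * n_ind, by = 2L), j] <- i1
    mat[seq(2L, 2L * n_ind, by = 2L), j] <- i2
  }
  panel <- genotype_panel(mat, 2L, iid)
  loci <- locus_table(as.character(mp[, 2L]), as.character(mp[, 1L]),
                      as.integer(mp[, pos_col]), labels)
  panel_bundle(panel, loci, pop_assignment(fid))
}

#' Read an Arlequin/fastsimcoal arp file into a panel bundle
#'
#' Accepts the documented Arlequin project structure with `[Data]` /
#' `[[Samples]]` blocks (`SampleName`, `SampleSize`, `SampleData`), DataType
#' STANDARD/DNA/SNP, and `GenotypicData` 0 (one haplotype row per entry, with
#' a frequency column) or 1 (two rows per diploid individual). Each sample
#' block becomes one population. Allele symbols are mapped to per-locus
#' indices by order of first appearance; `"?"` is missing. DNA haplotypes
#' written as contiguous strings are split into one symbol per locus.
#'
#' @param path arp file path
#' @return a [panel_bundle()].
#' @export
read_arp <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  kv <- function(key) {
    i <- grep(paste0("^\\s*", key, "\\s*="), lines)
    if (!length(i)) return(NA_character_)
    v <- sub(paste0("^\\s*", key, "\\s*=\\s*"), "", lines[i[1]])
    gsub("^[\"']|[\"']$", "", trimws(v))
  }
  genotypic <- identical(kv("GenotypicData"), "1")
  nb_declared <- suppressWarnings(as.integer(kv("NbSamples")))
  starts <- grep("^\\s*SampleName\\s*=", lines)
  if (!length(starts)) stop("no [[Samples]] blocks with SampleName found")
  if (!is.na(nb_declared) && nb_declared != length(starts)) {
    warning("NbSamples=", nb_declared, " but ", length(starts),
            " sample blocks found; using the blocks")
  }
  pops <- character(0); ids <- character(0); pop_of <- character(0)
  hap_rows <- list()
  for (b in seq_along(starts)) {
    i <- starts[b]
    pname <- gsub("^[\"']|[\"']$", "",
                  trimws(sub("^\\s*SampleName\\s*=", "", lines[i])))
    j <- i
    while (j <= length(lines) && !grepl("^\\s*SampleSize\\s*=", lines[j])) j <- j + 1L
    ssize <- as.integer(trimws(sub("^\\s*SampleSize\\s*=", "", lines[j])))
    while (j <= length(lines) && !grepl("^\\s*SampleData\\s*=", lines[j])) j <- j + 1L
    # data rows run to the closing brace
    j <- j + 1L
    block <- character(0)
    while (j <= length(lines) && !grepl("\\}", lines[j])) {
      if (nzchar(trimws(lines[j]))) block <- c(block, trimws(lines[j]))
      j <- j + 1L
    }
    toks <- strsplit(block, "[ \t]+")
    if (genotypic) {
      if (length(toks) %% 2L != 0L) {
        stop("GenotypicData=1 block '", pname, "' has an odd number of data rows")
      }
      n_here <- length(toks) / 2L
      if (!is.na(ssize) && n_here != ssize) {
        stop("SampleSize=", ssize, " but ", n_here,
             " individuals parsed in block '", pname, "'")
      }
      for (ii in seq_len(n_here)) {
        r1 <- toks[[2L * ii - 1L]]; r2 <- toks[[2L * ii]]
        id <- r1[1]
        h1 <- arp_symbols(r1[-(1:2)])
        h2 <- arp_symbols(r2)
        if (length(h1) != length(h2)) {
          stop("allele-count mismatch between the two rows of individual ", id)
        }
        ids <- c(ids, id); pop_of <- c(pop_of, pname)
        hap_rows <- c(hap_rows, list(h1), list(h2))
      }
    } else {
      total <- 0L
      for (tk in toks) {
        id <- tk[1]; freq <- as.integer(tk[2])
        h <- arp_symbols(tk[-(1:2)])
        for (rep_i in seq_len(freq)) {
          ids <- c(ids, if (freq > 1L) paste0(id, "_", rep_i) else id)
          pop_of <- c(pop_of, pname)
          hap_rows <- c(hap_rows, list(h))
        }
        total <- total + freq
      }
      if (!is.na(ssize) && total != ssize) {
        stop("SampleSize=", ssize, " but ", total,
             " haplotypes parsed in block '", pname, "'")
      }
    }
    pops <- c(pops, pname)
  }
  M <- unique(lengths(hap_rows))
  if (length(M) != 1L) stop("rows with differing locus counts in arp file")
  sym <- matrix(unlist(hap_rows), nrow = length(hap_rows), byrow = TRUE)
  mat <- matrix(NA_integer_, nrow(sym), M)
  labels <- vector("list", M)
  for (j in seq_len(M)) {
    col <- sym[, j]
    col[col == "?"] <- NA_character_
    seen <- unique(col[!is.na(col)])   # order of first appearance
    if (length(seen) > 4L) stop("locus ", j, " has more than 4 distinct symbols")
    if (length(seen) == 0L) seen <- "N"
    labels[[j]] <- seen
    mat[, j] <- match(col, seen)
  }
  ploidy <- if (genotypic) 2L else 1L
  panel <- genotype_panel(mat, ploidy, make.unique(ids))
  loci <- locus_table(paste0("L", seq_len(M)), "1", seq_len(M), labels)
  panel_bundle(panel, loci, pop_assignment(pop_of, populations = pops))
}

# One symbol per locus: multi-character single token (DNA string) is split
# into characters; otherwise each whitespace token is one locus symbol.
arp_symbols <- function(tokens) {
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 1L && nchar(tokens) > 1L) {
    strsplit(tokens, "")[[1]]
  } else {
    tokens
  }
}
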