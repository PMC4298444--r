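Package: panelpop
Title: Per-Locus Population Genetics Statistics for Large SNP Panels
Version: 0.1.0
Authors@R: person("panelpop", "developers", role = c("aut", "cre"),
    email = "panelpop@example.org")
Description: Loads large SNP panels from VCF (v4.1), PLINK ped/map, or
    Arlequin/fastsimcoal arp files into a haplotype-by-locus allele-index
    matrix and computes, in locus-partitioned deterministic chunks,
    per-locus and multilocus within-population statistics (allele
    frequencies, observed and expected heterozygosity, single- and
    multi-population allele frequency spectra) and between-population
    statistics (Nei 1973 Gst, Nei-Chesser 1983 Gst, Hedrick G'st, Jost's D,
    Weir-Cockerham theta, pairwise shared-allele proportions). Includes a
    Balding-Nichols panel simulator and format writers so every reader and
    statistic is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    optparse,
    parallel,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
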