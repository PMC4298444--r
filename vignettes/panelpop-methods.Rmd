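---
title: "panelpop: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panelpop: models, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

panelpop computes exploratory population-genetics statistics from large SNP
panels. This vignette is the package's account of the science: the data
model, the estimators and their assumptions, the numerical choices, what the
synthetic-data generator does and does not emulate, and the design decisions
that were genuinely open.

## The data model

A panel is a haplotype-by-locus matrix of allele indices: `H = N × ploidy`
rows (a diploid individual owns two adjacent rows) and `M` columns. Each
locus carries 1–4 alleles — a SNP site segregates for at most the four
nucleotides — indexed per locus in reader-defined order (REF first for VCF,
lexicographic for PLINK ped, order of first appearance for Arlequin arp).
All statistics are invariant under allele re-indexing, so the per-reader
orders are interchangeable.

Every statistic is computed from one intermediate, the **allele-count
table**: per locus × population, the called-chromosome count of each allele,
the number of completely genotyped individuals, and (for diploids) the
heterozygote counts, both total and per allele (the per-allele counts are
what the Weir–Cockerham components need).

**Missing data.** A diploid genotype with *any* missing allele contributes
nothing to its locus, in any statistic (the complete-genotype rule). This
keeps `n_called = 2 × n_ind_called` at every locus, which the Ho/He
estimators and the Nei–Chesser corrections rely on. The rule is a package
choice — half-calls could instead contribute their called allele to the
frequencies — made because every estimator below is written in terms of a
single per-locus sample size. Readers still *store* the called half of a
half-call; the counting layer drops it.

## Within-population statistics

Per locus and population with `n` called chromosomes and allele frequencies
`p_i = counts_i / n`:

* observed heterozygosity `Ho = het / n_ind_called` (diploid only);
* expected heterozygosity (gene diversity) `He = 1 − Σ p_i²`, by default
  with the small-sample correction `n/(n−1)` (Nei–Chesser's unbiased form).
  The raw form is a switch (`he = "raw"`). Which one the comparable C tools
  report is ambiguous, so both are first-class and the identity
  `He_unbiased = He_raw · n/(n−1)` is tested exactly.

Across-locus summaries report mean and variance over the loci where the
statistic is defined, with the count of such loci. The variance denominator
is the population form `1/count` by default (`variance = "sample"` switches
to `1/(count−1)`): the loci in hand are treated as the population of
interest, not a sample from a super-population. Monomorphic loci are
*defined* (value 0) for Ho/He and are included in those summaries; they are
undefined for differentiation statistics and excluded there, with the
exclusion count reported.

## Differentiation statistics

Populations with zero called chromosomes at a locus are dropped from that
locus; `s` is the count that remain, and a locus with `s < 2` is undefined
for every between-population statistic. With unweighted means across
populations:

* **Nei (1973) Gst** — `Hs = mean_k (1 − Σ p_ki²)`,
  `Ht = 1 − Σ p̄_i²` with `p̄_i` the unweighted mean frequency,
  `Gst = (Ht − Hs)/Ht`. No sample-size correction: this is the
  frequency-level definition, kept deliberately distinct from the estimators
  below so the three "formulations" differ in substance.
* **Nei & Chesser (1983)** — with `ñ` the harmonic mean number of genotyped
  individuals and `H̄o` the mean observed heterozygosity:
  `Ĥs = ñ/(ñ−1) · (1 − mean_k Σ p_ki² − H̄o/(2ñ))` and
  `Ĥt = 1 − Σ p̄_i² + Ĥs/(ñs) − H̄o/(2ñs)`, `Ĝst = (Ĥt − Ĥs)/Ĥt`.
  For haploid panels the `H̄o` terms drop and `ñ` counts chromosomes.
  Note these corrections do **not** cancel exactly when populations are
  identical: `Ĝst` carries an `O(1/(ñs))` residue (about −5·10⁻⁴ at
  `ñ = 500`), which is a property of the estimator, not a bug; the tests
  bound it by `2/ñ` rather than asserting zero.
* **Hedrick (2005)** — `G′st = Ĝst · (s − 1 + Ĥs) / ((s−1)(1 − Ĥs))`,
  Gst rescaled by its maximum attainable value at the observed `Ĥs`.
* **Jost (2008) D** — `D = s/(s−1) · (Ĥt − Ĥs)/(1 − Ĥs)`, using the
  Nei–Chesser estimators ("est D"); `jost_raw = TRUE` substitutes the raw
  `Hs`, `Ht`. The corrected form is the default because it is the form
  meant for data rather than parameters; the raw switch exists because the
  reference C implementation's choice is not documented.
* **Weir & Cockerham (1984) theta** — per locus and allele, the variance
  components `a` (among populations), `b` (among individuals within
  populations), `c` (within individuals), with `n_c` the usual sample-size
  coefficient and `h̄` the weighted heterozygote frequency per allele;
  summed over alleles, `θ = a/(a+b+c)`. The multilocus value is the
  ratio of sums `Σa / Σ(a+b+c)` — Weir & Cockerham's recommended weighting —
  which in general differs from the mean of per-locus thetas; the summary
  table reports the per-locus mean/variance *and* the ratio-of-sums in a
  separate `multilocus` column (Gst is likewise recomputed from summed
  Hs/Ht components there).

Negative estimates (θ, Ĝst, D can all go below zero around zero
differentiation) are reported as computed; `clamp_negative = TRUE` clamps
them at zero in the outputs for users who expect that convention.

**Shared alleles.** For two diploid genotypes the per-locus share is the
multiset intersection over 2: 1 for identical genotypes, 0.5 for one shared
allele copy (AA vs AG, or AG vs AT), 0 for disjoint. The pairwise matrix
averages over the loci where both genotypes are fully called and flags
pairs with none.

## Allele frequency spectra

An SFS bin is defined by one focal allele and one fixed sample size, so a
locus enters the spectrum only if (a) it carries calls on at most two
alleles and (b) every included population is completely genotyped there.
Both exclusion counts are reported; projection (hypergeometric downsampling
to a smaller `n`) is an explicit non-goal. The folded spectrum uses the
minor allele (ties at `n/2` sit in bin `n/2`); the unfolded spectrum uses
the designated allele — allele index 2, i.e. the first ALT for VCF — as a
stand-in for derived polarity, since ped and arp carry no polarity at all.

The joint spectrum folds on the *pooled* minor allele; a cell whose pooled
count is exactly half keeps whichever of the cell and its complement is
lexicographically smaller. That tie rule is what makes "fold the unfolded
spectrum" and "build the folded spectrum directly" agree cell for cell, and
it is asserted on every test run. One consequence worth knowing: marginals
of the *folded* joint spectrum do not equal per-population folded spectra
(folding does not commute with marginalisation); the marginal identity is
asserted for the unfolded spectrum.

The joint SFS is written in a dadi-style flattened layout (shape header,
then row-major counts) so it can feed demographic-inference or ABC
pipelines directly.

## The engine: chunked, deterministic, parallel-safe

No statistic uses information across loci, so the engine partitions the
columns into contiguous chunks, computes per-locus results per chunk
(serially or across forked workers), and merges in chunk-index order.

One deviation from the obvious design is deliberate: across-locus summaries
are computed from the merged full-length per-locus vectors, *not* by
combining per-chunk partial sums `(Σx, Σx²)`. R's `sum()` accumulates in
extended precision, so partial-sum merging gives results that differ in the
last bit as the chunking changes; reducing over the merged vectors makes
output files byte-identical for every `workers` × `chunk_size` combination,
which is the contract the tests enforce (a `merge_summaries()` utility
implementing the partial-sum algebra is still exported, and agrees to
numerical precision). Spectra are integer arrays and the shared-allele
partials are multiples of one half, so their chunk-wise sums are exact.

Outputs print doubles with `%.17g`, so a written value re-parses to the
identical double and cross-run byte comparison is meaningful. Default
`workers = 1`: on small panels forking costs more than it saves.

## The synthetic-data generator

`simulate_panel()` emulates a clean `s`-population split: ancestral
frequency `p0 ~ U(0.05, 0.95)` per locus (polymorphic in the ancestor, no
ascertainment model), present-day population frequencies from the
Balding–Nichols beta approximation
`Beta(p0(1−F)/F, (1−p0)(1−F)/F)` with `F = 1 − exp(−τ)` and `τ = t/2N`,
genotypes by binomial sampling under Hardy–Weinberg, and i.i.d. missing-call
masking. `F` is clamped to `[1e−9, 1−1e−9]` so `τ = 0` degenerates cleanly.
The default configuration (2 populations × 50 diploids) is the reduced-scale
version of the two-population, 500-diploid, 1000-generation regime used to
benchmark this class of tools; 50 diploids keeps every test fast while
leaving sample-size corrections visible.

The generator is deliberately simpler than a coalescent simulator: loci are
unlinked and exchangeable, there is no recombination, mutation model,
sequencing error, or demography beyond the clean split. A green recovery
test (multilocus θ within ±0.05 of `1 − exp(−τ)` at 5,000 loci) therefore
establishes that the estimators measure drift-induced differentiation
correctly under the stated model — not that they are robust to linkage,
ascertainment, or misspecified structure in real data.

One writer detail: for diploid bundles the arp writer emits
`GenotypicData=1` blocks (two rows per individual) rather than haplotype
blocks, because haplotype blocks re-read as ploidy 1 and would lose Ho and
the diploid estimators — the cross-format equivalence contract takes
precedence.

## Numerical and degenerate-input choices

* Undefined is a flag (`NA`), never an exception: `n = 0` frequencies,
  haploid Ho, `Ht = 0` Gst, `ñ ≤ 1` Nei–Chesser, `n_c ≤ 0` or
  `a+b+c = 0` Weir–Cockerham, pairs with no usable locus.
* `Ht` accumulates `Σ p̄_i²` before subtracting from 1 (rather than
  subtracting term by term), so biallelic results are bit-identical under
  allele relabeling — the property the cross-format test asserts.
* VCF sites with more than 3 ALT alleles cannot be represented in a 4-allele
  model and are skipped with a logged count rather than aborting the run.
* Indel/MNP alleles are accepted as opaque labels; statistics are
  label-agnostic.
* A locus-level population with zero called chromosomes is dropped from `s`
  at that locus only.

## Known limitations

* No confidence intervals or bootstrap over loci; no sliding windows; no
  pairwise-population Fst matrix (the multi-population estimators are
  global).
* No phasing, imputation, mixed ploidy, or sex chromosomes.
* SFS excludes rather than projects loci with missing data; panels with
  pervasive missingness will have thin spectra (the exclusion counts make
  this visible).
* The scale regime (10⁶ loci × 100 haplotypes, all statistics, single core,
  a few minutes, memory dominated by the 4-byte-per-entry matrix) is
  asserted at reduced scale in the routine test suite with a linear
  extrapolation bound; the full-size run is reproduced by
  `panelpop simulate --n-loci 1000000 ...` followed by a `panelpop` run.

## Worked example

```{r, eval = FALSE}
library(panelpop)
b <- simulate_panel(sim_config(n_loci = 2000, n_ind = 25, tau = 0.1, seed = 1))
res <- run_panel(run_config(format = "bundle", bundle = b))
res$summary[res$summary$statistic %in% c("He_pop1", "Gst73", "WC_theta"), ]
res$wc_multilocus          # ratio-of-sums theta, ~ 1 - exp(-0.1)
```
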