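---
title: "Chunked genotype storage and two-group variant filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chunked genotype storage and two-group variant filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genofilter)
```

## The problem and the storage model

Interactive exploration of a multi-sample variant callset mixes two very
different kinds of predicates. *Variant-level* predicates (sequence,
position, variant type, number of known alleles, functional annotation)
touch a handful of per-variant facts and can be answered from a small
indexed table. *Genotype-level* predicates (minor allele frequency in a
group, missing-data ratio, genotype patterns, per-sample DP/GQ thresholds)
must visit one value per individual per variant and dominate the cost of
every query.

`genofilter` keeps the two tiers physically separate. The variant-level
table is a single flat file scanned cheaply for every query; genotype runs
are stored as per-chunk blobs of fixed import-order extent (`chunk_size`
variants per chunk, default 5,000). The chunk is the unit of everything
downstream: query execution, count caching, early stopping, progress
reporting, and the optional worker pool. Missing genotypes are stored as
absences rather than explicit records, which both shrinks the store and
makes "no call" the natural default when a genotype is masked away later.

Two consequences of this layout are load-bearing and tested:

- **Partition invariant**: every variant belongs to exactly one chunk;
  per-chunk result counts must therefore sum to the query total.
- **Scheduling independence**: chunks are evaluated independently, so the
  result set equals a single-pass sequential scan of all variants in import
  order no matter how chunk evaluation is ordered or parallelized.

Queries that involve no group block never open a chunk at all: the match
set is recomputed on demand from the indexed table (annotation filters
included, since annotations are summarized into that table at ingest).

## Group statistics and filter semantics

For a group of selected individuals at one variant, after numeric-threshold
masking (a genotype whose value for any thresholded field is absent or
below the minimum is treated as missing; stored data are never modified):

- `missing_ratio` — fraction of *selected* individuals with no retained
  call.
- `maf` — frequency of the second-most-frequent allele among the alleles of
  retained calls. This generalizes min(p, 1−p) to multi-allelic variants,
  is 0 for a monomorphic variant and undefined when nothing is called (an
  undefined MAF fails any MAF-bounded filter).
- major genotype — the modal call under unphased equality (a call is the
  sorted multiset of its allele indices, so `1|0` ≡ `0/1`). Ties are broken
  deterministically toward the numerically smallest allele-index multiset.
- `major_ratio` — the major genotype's share of *called* genotypes.

The `ALL_OR_MOSTLY_SAME` pattern passes when `major_ratio` is at least the
similarity ratio; `ANY` imposes no pattern condition. Discrimination
requires two groups, both under `ALL_OR_MOSTLY_SAME`, both passing, with
distinct major genotypes — the screen for loci whose genotype separates two
phenotype classes. With two groups and no discrimination flag the group
blocks combine conjunctively.

Three semantic choices were genuinely open and are fixed as follows:

- **Similarity-ratio denominator.** The ratio is computed over *called*
  genotypes only; missingness is governed solely by `max_missing_ratio`.
  This keeps the two knobs orthogonal — a group with 9% missing data and a
  unanimous remainder passes (s = 1.0, missing max = 0.10) rather than
  being penalized twice for the same missing calls.
- **Inclusive boundaries everywhere.** A missing ratio of exactly the
  maximum, a major ratio of exactly the similarity ratio, and a MAF exactly
  on a bound all pass. Ratio comparisons carry a 1e-9 guard so that a
  decimal threshold like 0.90 cannot lose to binary representation against
  the exact fraction 9/10.
- **Unphased genotype equality.** Pattern matching and discrimination
  should not split `0|1` from `1|0`; phase is recorded at import but never
  used in comparisons (and is the one documented loss of VCF round trips).

## Caching and early stopping

Every executed query's per-chunk match counts are cached in the dataset
directory under a canonical key — a field-order-independent serialization
of the dataset name and the full query, with set-valued fields sorted, so
two spellings of the same query share one cache entry. A repeated count is
answered entirely from the cache; a repeated find skips chunks whose cached
count is zero and stops scanning a chunk (in import-order blocks of 512
variants) once the cached number of matches has been emitted. Because the
cache answers queries, staleness would be corruption: any ingest clears the
dataset's cache. The conservation property — cached per-chunk counts sum
exactly to the find-mode result length — is asserted over randomized
queries in the test suite.

## Import, export, formats

VCF parsing is delegated to `vcfR`; per-sample numeric FORMAT fields
declared `Number=1, Type=Integer|Float` are detected automatically from the
header and become thresholdable fields. SnpEff `ANN` and VEP `CSQ` INFO
annotations are parsed into (allele, consequence, impact, gene) records —
`CSQ` subfields mapped by the header's `Format:` declaration, `&`-joined
consequence terms split — and summarized into the variant index so
annotation filters stay on the indexed fast path.

PLINK PED/MAP and HapMap readers are hand-written (no installed R package
reads these text dialects). Their underspecified corners are fixed
deterministically: PLINK carries no REF, so the reference allele is the
alphabetically first observed allele; the HapMap dialect is the
TASSEL-style two-letter genotype cell with `NN` missing, 11 fixed header
columns, and a strand column that is stored verbatim but never applied
(strand flipping is error-prone and unspecified); haploid calls are written
as doubled letters on HapMap/PLINK export, which is the documented lossy
aspect of those round trips alongside REF choice and phasing.

Exports honor a query's result set and an independently chosen individual
subset, writing variants in import order. The export pipeline is decoupled
into a chunk reader feeding record batches to a per-format writer sink with
per-chunk progress; this is a logical pipeline in one process — R's
single-threaded I/O makes separate reader/writer processes pure overhead at
this scale, and the structure (and its row/column-count invariants) is what
matters for correctness. The Flapjack `.fjzip` container is a standard ZIP
archive written by a small stored-entry (uncompressed) ZIP writer with a
fixed timestamp, making exports byte-reproducible; member names
(`genotypes.fjgenotype`, `map.fjmap`) are documented constants following
the Flapjack project's flat genotype/map formats.

## The synthetic generator

The generator is first-class, tested code and defines the package's study
conditions. Neutral variants are biallelic SNPs with a per-variant ALT
frequency drawn uniformly from [0.05, 0.5], genotypes in Hardy–Weinberg
proportions *shared by all individuals* (so no neutral variant
systematically separates groups), per-call missingness at rate 0.05, and
per-sample DP ~ U{2..60}, GQ ~ U{10..99}; 30% of variants carry a
SnpEff-style ANN entry from a small consequence vocabulary. These defaults
are what a small resequencing panel typically looks like after standard
genotype filtering; they are fixed once and the tests run against them.

Planted variants carry distinct signature genotypes in two disjoint groups:
a `purity` fraction of each group receives its group's signature (exact
count, `round(purity * |group|)`), the remainder the opposite signature,
and group members are never set missing at planted sites — so purity 1.0
guarantees recovery by a discrimination query at similarity 1.0 and missing
maximum 0, and purity 0.92 in a group of 12 realizes 11/12 ≈ 0.917, below a
0.95 ratio by construction. The truth table records *realized* per-variant
MAF and missing counts (tallied from the emitted genotypes, not the
generating law), and generation is a pure function of the spec: one seed,
byte-identical output.

What the generator does **not** emulate bounds what green tests prove:
there is no linkage disequilibrium, no population structure, no
batch-correlated missingness, no depth-dependent genotype error. Passing
tests demonstrate the correctness of storage, statistics, filter semantics,
caching and format round trips on data with the right marginal structure —
not calibration of the discrimination screen on real cohorts.

## Numerical and degenerate-input choices

- Problem sizes in the routine suite: engine equivalence against a naive
  full-scan oracle on 1,000 variants × 50 individuals with 50 randomized
  queries; planted recovery with 10 planted among 5,000 neutral variants at
  50 individuals; a similarity sweep over 0.85–1.00 in steps of 0.05. These
  sizes exercise multi-chunk execution while keeping the whole suite near a
  minute.
- An empty group is rejected at construction; a group whose calls are all
  masked yields defined degenerate statistics (missing ratio 1, undefined
  MAF and major genotype) and fails any pattern or MAF condition.
- A position exactly at the upper end of a density range falls in the last
  bin (clamping), matching the 1-based inclusive convention used by every
  position filter.
- Variant ids default to `CHROM:POS` when the VCF ID column is `.`;
  id collisions are rejected at ingest.
- Chunk concurrency defaults to one worker; `workers > 1` forks via
  `parallel::mclapply`. No adaptive regulation is attempted — the
  correctness contract is scheduling independence, which is what the tests
  pin down.

## Known limitations

- The count cache is cleared on any ingest rather than selectively
  invalidated; with frequent incremental loads the cache provides little
  benefit.
- Genotype patterns beyond `ANY` and `ALL_OR_MOSTLY_SAME` (e.g.
  all-heterozygous) are not implemented.
- HapMap export is SNP-only (indels are skipped and counted); numeric
  per-sample fields survive VCF export only, as other formats have no slot
  for them.
- The PED writer holds its genotype columns in memory until the file is
  assembled (PED is row-per-individual while the store is
  row-per-variant), so PLINK export of very large datasets is
  memory-bound.
- Whether the similarity ratio should be computed over called or over all
  selected individuals cannot be settled against the published cichlid
  reference result without the original dataset (see README on reproducing
  the results); the called-only choice is the one that keeps the two
  missingness knobs independent.
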