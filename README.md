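# genofilter

A chunked genotype store and two-group variant filtering engine for R.

Population-scale variant callsets (VCFs with thousands of samples and
millions of sites) are awkward to explore interactively: most questions —
*which variants have a minor allele frequency between 10% and 30% in these
2,000 accessions?*, *which variants separate my resistant from my
susceptible lines?* — need genotype-level scans that command-line tools
answer one query at a time, from scratch, every time. `genofilter`
implements the storage and query model of a genotype investigator as a
library plus CLI: data are imported once into an on-disk store that splits
an **indexed variant-level table** (sequence, position, type, allele count,
functional annotation) from **chunked genotype runs** (calls, per-sample
numeric fields), and queries are evaluated chunk by chunk with per-chunk
result counts cached, so repeated counts are instant and repeated finds can
stop early.

## The query model

A query combines one variant-level block with up to two per-group
genotype-level blocks. For a group *G* of selected individuals at a variant
with called genotype multiset *C* (after masking genotypes whose DP, GQ, or
any other per-sample numeric field falls below a chosen minimum):

- **missing ratio** = (|G| − |C|) / |G|, compared against a maximum;
- **MAF** = frequency of the second-most-frequent allele among the alleles
  of *C* (0 if monomorphic, undefined if |C| = 0), compared against an
  inclusive [min, max] interval within [0, 0.5];
- **genotype pattern** `ANY` (no condition) or `ALL_OR_MOSTLY_SAME`: the
  modal ("major") genotype of *C* must account for at least a *similarity
  ratio* s of the called genotypes (unphased comparison: 0|1 ≡ 0/1);
- **discrimination**: with two groups, both under `ALL_OR_MOSTLY_SAME`, keep
  a variant only if both groups pass *and* their major genotypes differ —
  the case/control screen for genotype–phenotype signals.

All fraction comparisons are inclusive: a group in which exactly 90% of
called genotypes share the major genotype passes s = 0.90.

## Worked example

Generate a 16-sample dataset with two planted sex-linked-style variants,
store it, and ask which variants discriminate the two groups:

```r
library(genofilter)
td <- tempfile(); dir.create(td)
inds <- sprintf("ind%03d", 1:16)
spec <- synth_spec(n_individuals = 16, n_variants = 120, seed = 5,
                   planted = list(synth_plant("chr1", 50000, inds[1:5], inds[6:10]),
                                  synth_plant("chr1", 100000, inds[1:5], inds[6:10])))
paths <- synth_generate(spec, td, "demo")
batch <- read_vcf(paths$vcf)
ds <- gf_ingest(gf_create_dataset("demo", batch$individuals,
                                  chunk_size = 40, store_dir = td), batch)
q <- gf_query(
  group1 = gf_group_filter(inds[1:5], "ALL_OR_MOSTLY_SAME", 0.90,
                           max_missing_ratio = 0.10),
  group2 = gf_group_filter(inds[6:10], "ALL_OR_MOSTLY_SAME", 0.90,
                           max_missing_ratio = 0.10),
  discriminate = TRUE)
execute_query(ds, q, mode = "find")
#> <gf_query_result> 2 matching variant(s) over 3 chunk(s) [find]
execute_query(ds, q, mode = "count")
#> <gf_query_result> 2 matching variant(s) over 3 chunk(s) [cache] [count]
```

The two matches are exactly the planted variants (`v00002`, `v00003` in the
truth table `demo.truth.tsv`); the second call is answered from the
per-chunk count cache without touching genotype data. The result subset can
then be exported for two chosen individuals only, independent of the groups
used for filtering:

```r
gf_export(ds, file.path(td, "hits.vcf"), "vcf",
          individuals = c("ind001", "ind006"),
          ids = execute_query(ds, q, mode = "find")$variant_ids)
```

The same pipeline is available from a shell via the installed CLI script
(`system.file("cli", "genofilter", package = "genofilter")`) with
subcommands `synth`, `import`, `query`, `export`, `density`, `describe`;
run it without arguments for the flag reference.

## On-disk layout

Each dataset is a directory (not a public interchange format):

```
<store>/<name>/
  descriptor.json   # individuals, sequences, chunk sizes, numeric fields
  variants.tsv      # indexed variant-level table (id, seq, pos, type,
                    # alleles, annotation summaries, chunk/row address)
  chunks/chunk_*.rds# genotype runs: call matrix, numeric-field matrices,
                    # annotations; missing calls stored as absences
  cache.json        # canonical query key -> per-chunk match counts
  metadata.tsv      # optional individual metadata
```

Any ingest appends whole new chunks (existing chunks are never rewritten)
and clears the count cache.

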