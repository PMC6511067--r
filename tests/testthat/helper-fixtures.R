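# Programmatic fixtures: tiny hand-written files and synthetic datasets
# built at test time; nothing binary is stored in the repo.

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# A hand-written VCF exercising field mapping: missing call with a DP value,
# multi-allelic 1/2 call, phased het, haploid call, SnpEff ANN.
tiny_vcf <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Float,Description=\"Genotype quality\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name'\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("chr1", "101", "v1", "A", "T", ".", ".",
          "ANN=T|missense_variant|MODERATE|GENE1", "GT:DP", "0/1:12", "./.:3",
          sep = "\t"),
    paste("chr1", "202", "v2", "A", "T,G", ".", ".", ".", "GT:GQ",
          "1|2:50.5", "1/0:.", sep = "\t"),
    paste("chr2", "50", "v3", "AT", "A", ".", ".", ".", "GT", "0", "1/1",
          sep = "\t")), ".vcf")
}

tiny_csq_vcf <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence annotations from VEP. Format: Allele|Consequence|SYMBOL\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("chr1", "10", "c1", "G", "T", ".", ".", "CSQ=T|intron_variant|BRCA1",
          "GT", "0/1", sep = "\t"),
    paste("chr1", "20", "c2", "G", "A", ".", ".",
          "CSQ=A|missense_variant&splice_region_variant|GENE9,A|stop_gained|GENE8",
          "GT", "1/1", sep = "\t")), ".vcf")
}

tiny_plink <- function() {
  map <- write_lines_tmp(c("1\tv1\t0\t500", "1\tv2\t0\t900"), ".map")
  ped <- write_lines_tmp(c(
    "fam1 s1 0 0 1 -9 A A G T",
    "fam1 s2 0 0 2 -9 A T 0 0",
    "fam1 s3 0 0 1 -9 T T T T"), ".ped")
  list(ped = ped, map = map)
}

tiny_hapmap <- function() {
  hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                 "s1", "s2"), collapse = "\t")
  write_lines_tmp(c(
    hdr,
    paste(c("h1", "A/T", "1", "100", "+", rep("NA", 6), "AA", "AT"),
          collapse = "\t"),
    paste(c("h2", "C/G", "1", "200", "+", rep("NA", 6), "NN", "GG"),
          collapse = "\t")),
    ".hmp.txt")
}

tiny_metadata <- function() {
  write_lines_tmp(c("id\tsex\torigin",
                    "s1\tM\tlake",
                    "s2\tF\t"), ".tsv")
}

# Synthetic dataset helper: generate -> import -> ingest into a temp store.
make_synth_dataset <- function(spec, name = "ds", chunk_size = 100L) {
  td <- tempfile("store")
  dir.create(td, recursive = TRUE)
  paths <- synth_generate(spec, td, "g")
  batch <- read_vcf(paths$vcf)
  ds <- gf_create_dataset(name, batch$individuals, chunk_size = chunk_size,
                          store_dir = td)
  ds <- gf_ingest(ds, batch)
  truth <- utils::read.delim(paths$truth, stringsAsFactors = FALSE)
  list(ds = ds, batch = batch, paths = paths, truth = truth, store = td)
}

default_planted <- function(inds, n_planted = 2L, group_size = 8L,
                            seq_name = "chr1", spacing = 50000L) {
  g1 <- inds[seq_len(group_size)]
  g2 <- inds[group_size + seq_len(group_size)]
  lapply(seq_len(n_planted), function(i)
    synth_plant(seq_name, spacing * i, g1, g2))
}
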