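export_fixture <- local({
  x <- NULL
  function() {
    if (is.null(x)) x <<- make_synth_dataset(
      synth_spec(n_individuals = 20, n_variants = 250, seed = 41,
                 planted = default_planted(sprintf("ind%03d", 1:20), 1, 6)),
      chunk_size = 90)
    x
  }
})

test_that("VCF export round-trips the unphased genotype matrix exactly", {
  x <- export_fixture()
  out <- tempfile(fileext = ".vcf")
  s <- gf_export(x$ds, out, "vcf")
  expect_equal(s$n_variants, 250L)
  b2 <- read_vcf(out)
  expect_equal(b2$gt, x$batch$gt)
  expect_equal(b2$variants$position, x$batch$variants$position)
  expect_equal(b2$variants$alleles, x$batch$variants$alleles)
  expect_equal(b2$fields$DP, x$batch$fields$DP)
  # annotations survive the round trip too
  expect_equal(b2$annotation_source, "snpeff")
  expect_equal(vapply(b2$ann, nrow, 1L), vapply(x$batch$ann, nrow, 1L))
  # and a second round trip is byte-stable
  out2 <- tempfile(fileext = ".vcf")
  x2td <- tempfile(); dir.create(x2td)
  ds2 <- gf_ingest(gf_create_dataset("rt", b2$individuals, 90, x2td), b2)
  gf_export(ds2, out2, "vcf")
  expect_identical(readLines(out2), readLines(out))
})

test_that("gzip VCF export reads back identically", {
  x <- export_fixture()
  out <- tempfile(fileext = ".vcf.gz")
  gf_export(x$ds, out, "vcf", gzip = TRUE)
  expect_true(is_gz(out))
  expect_equal(read_vcf(out)$gt, x$batch$gt)
})

test_that("export honors the query result set and the individual subset", {
  x <- export_fixture()
  g <- sprintf("ind%03d", 1:6)
  q <- gf_query(group1 = gf_group_filter(g, maf_min = 0.1, maf_max = 0.5))
  res <- execute_query(x$ds, q, mode = "find")
  expect_gt(res$total_count, 0)
  out <- tempfile(fileext = ".vcf")
  sub <- c("ind003", "ind017")
  gf_export(x$ds, out, "vcf", individuals = sub, ids = res$variant_ids)
  b2 <- read_vcf(out)
  # row count = query total, column count = subset size
  expect_equal(nrow(b2$variants), res$total_count)
  expect_equal(b2$individuals, sub)
  expect_equal(b2$variants$variant_id, res$variant_ids)
  expect_equal(unname(b2$gt), unname(x$batch$gt[
    match(res$variant_ids, x$batch$variants$variant_id), sub]))
  expect_error(gf_export(x$ds, out, "vcf", individuals = "ghost"),
               class = "gf_validation_error")
})

test_that("a query matching nothing exports a valid header-only VCF", {
  x <- export_fixture()
  out <- tempfile(fileext = ".vcf")
  gf_export(x$ds, out, "vcf", ids = character())
  lines <- readLines(out)
  expect_true(all(startsWith(lines, "#")))
  expect_equal(sum(startsWith(lines, "#CHROM")), 1L)
})

test_that("PLINK export round-trips biallelic genotypes up to REF choice", {
  x <- export_fixture()
  out <- tempfile()
  s <- gf_export(x$ds, out, "plink")
  expect_setequal(s$files, paste0(out, c(".ped", ".map")))
  b2 <- read_plink(paste0(out, ".ped"), paste0(out, ".map"))
  expect_equal(b2$individuals, x$ds$individuals)
  expect_equal(b2$variants$position, x$batch$variants$position)
  # compare as unordered allele-letter pairs: PLINK re-derives the reference
  # alphabetically, so indices may flip but the letters may not
  letter_pairs <- function(b) {
    al <- strsplit(b$variants$alleles, ",", fixed = TRUE)
    vapply(seq_len(nrow(b$gt)), function(i) paste(vapply(b$gt[i, ], function(g) {
      if (is.na(g)) return("-")
      paste(sort(al[[i]][as.integer(strsplit(g, "/", fixed = TRUE)[[1]]) + 1L]),
            collapse = "")
    }, ""), collapse = " "), "")
  }
  expect_equal(letter_pairs(b2), letter_pairs(x$batch))
})

test_that("HapMap export round-trips SNPs and counts skipped indels", {
  x <- export_fixture()
  out <- tempfile(fileext = ".hmp.txt")
  s <- gf_export(x$ds, out, "hapmap")
  expect_equal(s$skipped, 0L)   # generator emits SNPs only
  b2 <- read_hapmap(out)
  expect_equal(unname(b2$gt), unname(x$batch$gt))

  # an indel is skipped with a count
  td <- tempfile(); dir.create(td)
  v <- data.frame(variant_id = c("i1", "s1"), sequence = "chr1",
                  position = c(5L, 9L), variant_type = c("INDEL", "SNP"),
                  alleles = c("AT,A", "A,G"), stringsAsFactors = FALSE)
  b <- gf_batch(v, matrix(c("0/1", "0/0"), 2, 2), c("a", "b"))
  ds <- gf_ingest(gf_create_dataset("hm", c("a", "b"), 10, td), b)
  out2 <- tempfile(fileext = ".hmp.txt")
  expect_message(s2 <- gf_export(ds, out2, "hapmap"), "skipped")
  expect_equal(s2$skipped, 1L)
  expect_equal(s2$n_variants, 1L)
  expect_equal(read_hapmap(out2)$variants$variant_id, "s1")
})

test_that("Flapjack export is a readable zip with genotype and map members", {
  x <- export_fixture()
  out <- tempfile(fileext = ".fjzip")
  gf_export(x$ds, out, "flapjack", individuals = c("ind001", "ind002"))
  listing <- utils::unzip(out, list = TRUE)
  expect_setequal(listing$Name, c("genotypes.fjgenotype", "map.fjmap"))
  td <- tempfile(); dir.create(td)
  utils::unzip(out, exdir = td)
  geno <- readLines(file.path(td, "genotypes.fjgenotype"))
  expect_equal(geno[1], "# fjFile = GENOTYPE")
  expect_equal(length(geno), 2L + 2L)   # header, marker row, 2 individuals
  markers <- strsplit(geno[2], "\t")[[1]][-1]
  expect_equal(markers, x$batch$variants$variant_id)
  row1 <- strsplit(geno[3], "\t")[[1]]
  expect_equal(row1[1], "ind001")
  # spot-check one cell against the stored genotype
  al <- strsplit(x$batch$variants$alleles[1], ",")[[1]]
  g <- x$batch$gt[1, "ind001"]
  want <- if (is.na(g)) ""
          else paste(al[as.integer(strsplit(g, "/")[[1]]) + 1], collapse = "/")
  expect_equal(row1[2], want)
  map <- readLines(file.path(td, "map.fjmap"))
  expect_equal(map[1], "# fjFile = MAP")
  expect_equal(length(map), 1L + 250L)

  # identical inputs give byte-identical archives (fixed timestamps)
  out2 <- tempfile(fileext = ".fjzip")
  gf_export(x$ds, out2, "flapjack", individuals = c("ind001", "ind002"))
  expect_identical(readBin(out2, "raw", file.size(out2)),
                   readBin(out, "raw", file.size(out)))
})
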