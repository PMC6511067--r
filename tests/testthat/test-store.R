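make_batch <- function(m, individuals, seq_name = "chrZ") {
  variants <- data.frame(
    variant_id = sprintf("b%06d", seq_len(m)), sequence = seq_name,
    position = seq_len(m) * 10L, variant_type = "SNP",
    alleles = "A,T", stringsAsFactors = FALSE)
  gt <- matrix("0/1", nrow = m, ncol = length(individuals))
  gf_batch(variants, gt, individuals)
}

test_that("dataset creation validates names and individuals", {
  td <- tempfile(); dir.create(td)
  ds <- gf_create_dataset("rice", sprintf("s%d", 1:30), chunk_size = 5000,
                          store_dir = td)
  expect_equal(length(ds$individuals), 30L)
  expect_equal(length(ds$chunk_sizes), 0L)
  expect_equal(ds$n_variants, 0L)
  expect_error(gf_create_dataset("rice", "s1", store_dir = td),
               class = "gf_already_exists_error")
  expect_error(gf_create_dataset("d", c("a", "a"), store_dir = td),
               class = "gf_validation_error")
  expect_error(gf_create_dataset("d", character(), store_dir = td),
               class = "gf_validation_error")
  expect_error(gf_create_dataset("d", "a", chunk_size = 0, store_dir = td),
               class = "gf_validation_error")
})

test_that("variants are chunked by ceiling division in import order", {
  td <- tempfile(); dir.create(td)
  ds <- gf_create_dataset("big", c("a", "b"), chunk_size = 5000, store_dir = td)
  ds <- gf_ingest(ds, make_batch(12001L, c("a", "b")))
  expect_equal(ds$chunk_sizes, c(5000L, 5000L, 2001L))
  expect_equal(ds$n_variants, 12001L)
  idx <- variant_index(ds)
  # every variant in exactly one chunk, chunk/row addressing consistent
  expect_equal(nrow(idx), 12001L)
  expect_equal(as.integer(table(idx$chunk)), ds$chunk_sizes)
  expect_equal(idx$row[idx$chunk == 3][2001], 2001L)
})

test_that("incremental ingest appends chunks without rewriting old ones", {
  td <- tempfile(); dir.create(td)
  ds <- gf_create_dataset("inc", c("a", "b"), chunk_size = 8, store_dir = td)
  b1 <- make_batch(10L, c("a", "b"))
  ds <- gf_ingest(ds, b1)
  expect_equal(ds$chunk_sizes, c(8L, 2L))
  mt1 <- file.mtime(file.path(ds$path, "chunks", "chunk_00001.rds"))
  b2 <- make_batch(5L, c("a", "b"))
  b2$variants$variant_id <- paste0("x", b2$variants$variant_id)
  ds <- gf_ingest(ds, b2)
  expect_equal(ds$chunk_sizes, c(8L, 2L, 5L))
  expect_equal(ds$n_variants, 15L)
  expect_equal(file.mtime(file.path(ds$path, "chunks", "chunk_00001.rds")), mt1)
  # reopening from disk restores the descriptor
  ds2 <- gf_open_dataset(ds$path)
  expect_equal(ds2$chunk_sizes, ds$chunk_sizes)
  expect_equal(ds2$individuals, ds$individuals)
})

test_that("ingest rejects id collisions and unknown individuals", {
  td <- tempfile(); dir.create(td)
  ds <- gf_create_dataset("v", c("a", "b"), chunk_size = 10, store_dir = td)
  ds <- gf_ingest(ds, make_batch(3L, c("a", "b")))
  expect_error(gf_ingest(ds, make_batch(3L, c("a", "b"))),
               class = "gf_collision_error")
  expect_error(gf_ingest(ds, make_batch(2L, c("a", "zz"))),
               class = "gf_validation_error")
})

test_that("generator output ingests with conserved variant counts", {
  x <- make_synth_dataset(synth_spec(n_individuals = 10, n_variants = 1000,
                                     seed = 3), chunk_size = 300)
  expect_equal(x$ds$n_variants, 1000L)
  expect_equal(sum(x$ds$chunk_sizes), 1000L)
  expect_equal(x$ds$chunk_sizes, c(300L, 300L, 300L, 100L))
  # count by an independent pass over the input stream
  expect_equal(x$ds$n_variants,
               sum(!startsWith(readLines(x$paths$vcf), "#")))
})

test_that("count cache round-trips, validates length, persists, clears on ingest", {
  td <- tempfile(); dir.create(td)
  ds <- gf_create_dataset("c", c("a", "b"), chunk_size = 2, store_dir = td)
  ds <- gf_ingest(ds, make_batch(5L, c("a", "b")))
  expect_equal(length(ds$chunk_sizes), 3L)
  put_cached_counts(ds, "k1", c(3L, 0L, 7L))
  expect_equal(get_cached_counts(ds, "k1"), c(3L, 0L, 7L))
  expect_null(get_cached_counts(ds, "unknown"))
  expect_error(put_cached_counts(ds, "k2", c(1L, 2L)),
               class = "gf_validation_error")
  # persists across a reopen
  ds2 <- gf_open_dataset(ds$path)
  expect_equal(get_cached_counts(ds2, "k1"), c(3L, 0L, 7L))
  # any ingest invalidates
  b <- make_batch(2L, c("a", "b")); b$variants$variant_id <- c("n1", "n2")
  ds <- gf_ingest(ds, b)
  expect_null(get_cached_counts(ds, "k1"))
})

test_that("semantically identical queries serialize to the same key", {
  td <- tempfile(); dir.create(td)
  ds <- gf_create_dataset("k", c("a", "b", "c"), store_dir = td)
  q1 <- gf_query(
    variant_filter = gf_variant_filter(sequences = c("chr2", "chr1"),
                                       variant_types = c("INDEL", "SNP")),
    group1 = gf_group_filter(c("c", "a"), maf_min = 0.1,
                             numeric_thresholds = c(GQ = 30, DP = 10)))
  q2 <- gf_query(
    variant_filter = gf_variant_filter(variant_types = c("SNP", "INDEL"),
                                       sequences = c("chr1", "chr2")),
    group1 = gf_group_filter(c("a", "c"), maf_min = 0.1,
                             numeric_thresholds = c(DP = 10, GQ = 30)))
  expect_equal(gf_query_key(ds, q1), gf_query_key(ds, q2))
  q3 <- gf_query(group1 = gf_group_filter(c("a", "c"), maf_min = 0.2))
  expect_false(gf_query_key(ds, q1) == gf_query_key(ds, q3))
  # ANY pattern ignores the similarity ratio in the key
  q4 <- gf_query(group1 = gf_group_filter("a", "ANY", similarity_ratio = 0.5))
  q5 <- gf_query(group1 = gf_group_filter("a", "ANY", similarity_ratio = 0.9))
  expect_equal(gf_query_key(ds, q4), gf_query_key(ds, q5))
})

test_that("metadata attachment enables group selection by attribute", {
  x <- make_synth_dataset(synth_spec(
    n_individuals = 20, n_variants = 20, seed = 5,
    planted = default_planted(sprintf("ind%03d", 1:20), 1, 6)))
  md <- read_metadata_tsv(x$paths$metadata, x$ds$individuals)
  gf_attach_metadata(x$ds, md)
  g1 <- gf_individuals_where(x$ds, "group", "group1")
  expect_equal(g1, sprintf("ind%03d", 1:6))
  expect_error(gf_individuals_where(x$ds, "nope", "x"),
               class = "gf_validation_error")
})
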