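test_that("group statistics count genotypes, alleles, MAF and missingness", {
  st <- group_stats(c("0/0", "0/0", "0/1", "1/1", NA))
  expect_equal(st$n_selected, 5L)
  expect_equal(st$n_called, 4L)
  expect_equal(st$missing_ratio, 0.2)
  expect_equal(unname(st$allele_counts), c(5L, 3L))
  expect_equal(st$maf, 0.375)
  expect_equal(st$major_genotype, "0/0")
  expect_equal(st$major_ratio, 0.5)

  mono <- group_stats(rep("0/0", 10))
  expect_equal(mono$maf, 0)
  expect_equal(mono$major_ratio, 1)
  expect_equal(mono$missing_ratio, 0)

  none <- group_stats(c(NA_character_, NA_character_))
  expect_equal(none$n_called, 0L)
  expect_true(is.na(none$maf))
  expect_true(is.na(none$major_genotype))
  expect_equal(none$missing_ratio, 1)
})

test_that("random group statistics match a brute-force tally", {
  set.seed(71)
  pool <- c("0/0", "0/1", "1/1", "0/2", "1/2", "2/2", "0", "1", NA)
  for (rep in 1:200) {
    calls <- sample(pool, sample(1:40, 1), replace = TRUE)
    st <- group_stats(calls)
    or <- oracle_group_stats(calls)
    expect_equal(st$n_called, or$n_called)
    expect_equal(st$missing_ratio, or$missing_ratio)
    expect_equal(st$major_genotype, or$major)
    if (st$n_called > 0) {
      expect_equal(st$major_ratio, or$major_ratio)
      expect_equal(st$maf, or$maf)
      expect_equal(unname(st$allele_counts[st$allele_counts > 0]),
                   unname(as.integer(or$allele_counts)))
    }
  }
})

test_that("numeric thresholds mask calls without touching stored data", {
  calls <- c(a = "0/1", b = "0/0", c = "1/1")
  values <- list(DP = c(a = 12, b = 3, c = NA))
  expect_equal(mask_by_thresholds(calls, values, c(DP = 10)),
               c(a = "0/1", b = NA, c = NA))
  # threshold exactly met is retained (inclusive)
  expect_equal(unname(mask_by_thresholds(calls, values, c(DP = 12))["a"]), "0/1")
  expect_equal(mask_by_thresholds(calls, values, NULL), calls)
  expect_equal(mask_by_thresholds(calls, values, c()), calls)
})

test_that("group filter boundaries are inclusive", {
  st <- group_stats(c(rep("0/0", 9), "0/1", NA))  # 9/10 called share major
  expect_true(evaluate_group_filter(
    st, gf_group_filter("x", "ALL_OR_MOSTLY_SAME", similarity_ratio = 0.9))$pass)
  expect_false(evaluate_group_filter(
    st, gf_group_filter("x", "ALL_OR_MOSTLY_SAME", similarity_ratio = 0.91))$pass)

  st2 <- group_stats(c("0/0", "0/0", "0/1", "1/1", NA))  # maf 0.375, missing 0.2
  expect_false(evaluate_group_filter(
    st2, gf_group_filter("x", maf_min = 0.10, maf_max = 0.30))$pass)
  expect_true(evaluate_group_filter(
    st2, gf_group_filter("x", maf_min = 0.10, maf_max = 0.375))$pass)
  expect_true(evaluate_group_filter(
    st2, gf_group_filter("x", max_missing_ratio = 0.2))$pass)
  expect_false(evaluate_group_filter(
    st2, gf_group_filter("x", max_missing_ratio = 0.19))$pass)
  # MAF bounds on an uncalled variant fail (undefined MAF)
  expect_false(evaluate_group_filter(
    group_stats(c(NA_character_)), gf_group_filter("x", maf_min = 0))$pass)
  # ANY imposes no pattern condition
  expect_true(evaluate_group_filter(st2, gf_group_filter("x", "ANY"))$pass)
})

test_that("random filter decisions match an independent rule evaluation", {
  set.seed(72)
  pool <- c("0/0", "0/1", "1/1", "0/2", NA)
  for (rep in 1:200) {
    calls <- sample(pool, sample(2:30, 1), replace = TRUE,
                    prob = c(0.4, 0.2, 0.2, 0.1, 0.1))
    lo <- if (runif(1) < 0.4) runif(1, 0, 0.3) else NULL
    hi <- if (runif(1) < 0.4) runif(1, 0.2, 0.5) else NULL
    if (!is.null(lo) && !is.null(hi) && lo > hi) { t <- lo; lo <- hi; hi <- t }
    gf <- gf_group_filter(
      "x",
      pattern = sample(c("ANY", "ALL_OR_MOSTLY_SAME"), 1),
      similarity_ratio = runif(1),
      maf_min = lo, maf_max = hi,
      max_missing_ratio = if (runif(1) < 0.5) runif(1) else NULL)
    st <- group_stats(calls)
    got <- evaluate_group_filter(st, gf)$pass
    want <- oracle_group_pass(oracle_group_stats(calls), gf)
    expect_equal(got, want)
  }
})

test_that("discrimination needs both passes and distinct unphased majors", {
  r <- function(pass, major) list(pass = pass, major = major)
  expect_true(evaluate_discrimination(r(TRUE, "0/0"), r(TRUE, "1/1")))
  # one stored phased 1|0 normalizes to 0/1: same major, no discrimination
  expect_false(evaluate_discrimination(r(TRUE, "0/1"),
                                       r(TRUE, normalize_gt("1|0")$calls)))
  expect_false(evaluate_discrimination(r(TRUE, "0/0"), r(FALSE, "1/1")))
  expect_false(evaluate_discrimination(r(TRUE, "0/0"), r(TRUE, NA_character_)))
})

test_that("variant-level filter is a conjunction over indexed facts", {
  rec <- list(sequence = "chr10", position = 28000000L, variant_type = "SNP",
              alleles = "A,T")
  vf <- gf_variant_filter(sequences = "chr10", position_min = 27530000,
                          position_max = 29520000)
  expect_true(evaluate_variant_level(rec, NULL, vf))
  expect_false(evaluate_variant_level(rec, NULL,
                                      gf_variant_filter(sequences = "chr9")))
  ann <- parse_snpeff_ann("T|intron_variant|MODIFIER|G1")
  expect_false(evaluate_variant_level(
    rec, ann, gf_variant_filter(effects = "missense_variant")))
  expect_true(evaluate_variant_level(
    rec, ann, gf_variant_filter(effects = c("intron_variant", "stop_gained"))))
  expect_true(evaluate_variant_level(rec, NULL, gf_variant_filter()))
  expect_false(evaluate_variant_level(
    rec, NULL, gf_variant_filter(allele_count_min = 3)))
})

test_that("invalid queries are rejected before evaluation", {
  x <- make_synth_dataset(synth_spec(n_individuals = 6, n_variants = 10,
                                     seed = 9), chunk_size = 4)
  expect_error(gf_query(group1 = gf_group_filter("ind001"),
                        discriminate = TRUE),
               class = "gf_validation_error")
  expect_error(gf_query(group1 = gf_group_filter("ind001", "ANY"),
                        group2 = gf_group_filter("ind002", "ANY"),
                        discriminate = TRUE),
               class = "gf_validation_error")
  expect_error(execute_query(x$ds, gf_query(
    group1 = gf_group_filter("nobody"))), class = "gf_validation_error")
  expect_error(execute_query(x$ds, gf_query(
    group1 = gf_group_filter("ind001", numeric_thresholds = c(XX = 1)))),
    "fields detected at import", class = "gf_validation_error")
  expect_error(execute_query(x$ds, gf_query(
    gf_variant_filter(sequences = "chr99"))), class = "gf_validation_error")
})

engine_fixture <- local({
  x <- NULL
  function() {
    if (is.null(x)) x <<- make_synth_dataset(
      synth_spec(n_individuals = 25, n_variants = 300, seed = 21,
                 planted = default_planted(sprintf("ind%03d", 1:25), 2, 8)),
      chunk_size = 75)
    x
  }
})

test_that("chunked execution equals a naive sequential full scan", {
  x <- engine_fixture()
  expect_equal(execute_query(x$ds, gf_query(), mode = "count")$total_count,
               300L)
  set.seed(22)
  for (i in 1:12) {
    q <- random_query(x$batch)
    got <- execute_query(x$ds, q, mode = "find")
    want <- oracle_query(x$batch, q)
    expect_equal(got$variant_ids, want, info = sprintf("query %d", i))
    expect_equal(got$total_count, length(want))
    expect_equal(sum(got$per_chunk_counts), got$total_count)
  }
})

test_that("count and find agree; repeats come from the cache unchanged", {
  x <- engine_fixture()
  set.seed(23)
  q <- random_query(x$batch)
  gf_clear_cache(x$ds)
  cnt <- execute_query(x$ds, q, mode = "count")
  expect_false(cnt$from_cache)
  fnd <- execute_query(x$ds, q, mode = "find")
  expect_true(fnd$from_cache)   # count pass populated the cache
  expect_equal(length(fnd$variant_ids), cnt$total_count)
  cnt2 <- execute_query(x$ds, q, mode = "count")
  expect_true(cnt2$from_cache)
  expect_equal(cnt2$per_chunk_counts, cnt$per_chunk_counts)
  fnd2 <- execute_query(x$ds, q, mode = "find")
  expect_equal(fnd2$variant_ids, fnd$variant_ids)
})

test_that("group-only queries take the fast path and match the oracle", {
  x <- engine_fixture()
  q <- gf_query(gf_variant_filter(sequences = "chr1",
                                  position_min = 1, position_max = 3e6))
  got <- execute_query(x$ds, q, mode = "find")
  expect_equal(got$variant_ids, oracle_query(x$batch, q))
})

test_that("scheduling does not change results (worker pool contract)", {
  x <- engine_fixture()
  set.seed(29)
  q <- random_query(x$batch)
  gf_clear_cache(x$ds)
  seq1 <- execute_query(x$ds, q, mode = "find")$variant_ids
  gf_clear_cache(x$ds)
  par2 <- execute_query(x$ds, q, mode = "find", workers = 2L)$variant_ids
  expect_equal(par2, seq1)
})

test_that("filter knobs are monotone in the expected direction", {
  x <- engine_fixture()
  g <- sprintf("ind%03d", 1:12)
  n_at <- function(ratio, mm = 0.3) execute_query(x$ds, gf_query(
    group1 = gf_group_filter(g, "ALL_OR_MOSTLY_SAME", ratio,
                             max_missing_ratio = mm)), mode = "count")$total_count
  ratios <- c(0.5, 0.7, 0.9, 1.0)
  sizes <- vapply(ratios, n_at, 1L)
  expect_true(all(diff(sizes) <= 0))

  maf_at <- function(lo, hi) execute_query(x$ds, gf_query(
    group1 = gf_group_filter(g, maf_min = lo, maf_max = hi)),
    mode = "count")$total_count
  expect_gte(maf_at(0.05, 0.45), maf_at(0.10, 0.40))
  expect_gte(maf_at(0.10, 0.45), maf_at(0.10, 0.40))

  mm_at <- function(mm) execute_query(x$ds, gf_query(
    group1 = gf_group_filter(g, max_missing_ratio = mm)),
    mode = "count")$total_count
  expect_gte(mm_at(0.2), mm_at(0.1))

  # raising a numeric threshold never lowers any group missing ratio
  chunk <- read_chunk(x$ds, 1L)
  for (thr in c(5, 20, 40)) {
    lo <- mask_chunk(chunk$gt[, g, drop = FALSE], chunk$fields,
                     c(DP = thr), g)
    hi <- mask_chunk(chunk$gt[, g, drop = FALSE], chunk$fields,
                     c(DP = thr + 10), g)
    expect_true(all(rowMeans(is.na(hi)) >= rowMeans(is.na(lo))))
  }
})

test_that("swapping the two groups leaves a discriminate query unchanged", {
  x <- engine_fixture()
  set.seed(24)
  for (i in 1:5) {
    q <- random_query(x$batch, discriminate_only = TRUE)
    swapped <- gf_query(q$variant_filter, group1 = q$group2,
                        group2 = q$group1, discriminate = TRUE)
    expect_equal(execute_query(x$ds, q, mode = "find")$variant_ids,
                 execute_query(x$ds, swapped, mode = "find")$variant_ids)
  }
})
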