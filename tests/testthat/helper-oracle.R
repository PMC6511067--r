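# Independent, naive re-implementation of the query semantics, used as the
# oracle against the chunked engine. Deliberately written as per-variant
# loops over the raw import batch (never touching the store, the cache or
# the vectorized chunk code), with table()-based tallies and string-rank
# tie-breaks instead of the engine's mechanisms.

oracle_mask <- function(calls, batch, row, gf) {
  thr <- gf$numeric_thresholds
  if (is.null(thr)) return(calls)
  for (f in names(thr)) {
    v <- batch$fields[[f]][row, names(calls)]
    calls[is.na(v) | v < thr[[f]]] <- NA
  }
  calls
}

# rank key for the major-genotype tie-break: numeric-lexicographic order of
# the allele multiset, via zero-padded strings
oracle_gt_rank <- function(g) {
  idx <- as.integer(strsplit(g, "/", fixed = TRUE)[[1]])
  paste(sprintf("%09d", idx), collapse = "|")
}

oracle_group_stats <- function(calls) {
  n_sel <- length(calls)
  called <- calls[!is.na(calls)]
  out <- list(n_selected = n_sel, n_called = length(called),
              missing_ratio = sum(is.na(calls)) / n_sel,
              major = NA_character_, major_ratio = NA_real_, maf = NA_real_,
              allele_counts = integer())
  if (length(called) == 0L) return(out)
  tab <- table(called)
  top <- names(tab)[tab == max(tab)]
  out$major <- top[order(vapply(top, oracle_gt_rank, ""))][1]
  out$major_ratio <- max(tab) / length(called)
  alleles <- unlist(strsplit(called, "/", fixed = TRUE))
  ac <- table(alleles)
  out$allele_counts <- ac
  freqs <- sort(as.numeric(ac) / sum(ac), decreasing = TRUE)
  out$maf <- if (length(freqs) >= 2) freqs[2] else 0
  out
}

oracle_group_pass <- function(st, gf) {
  if (!is.null(gf$max_missing_ratio) && st$missing_ratio > gf$max_missing_ratio)
    return(FALSE)
  if (!is.null(gf$maf_min) || !is.null(gf$maf_max)) {
    if (is.na(st$maf)) return(FALSE)
    if (!is.null(gf$maf_min) && st$maf < gf$maf_min) return(FALSE)
    if (!is.null(gf$maf_max) && st$maf > gf$maf_max) return(FALSE)
  }
  if (gf$pattern == "ALL_OR_MOSTLY_SAME") {
    if (st$n_called == 0L) return(FALSE)
    if (st$major_ratio < gf$similarity_ratio) return(FALSE)
  }
  TRUE
}

oracle_variant_pass <- function(batch, i, vf) {
  v <- batch$variants[i, ]
  if (!is.null(vf$variant_types) && !(v$variant_type %in% vf$variant_types))
    return(FALSE)
  na <- length(strsplit(v$alleles, ",", fixed = TRUE)[[1]])
  if (!is.null(vf$allele_count_min) && na < vf$allele_count_min) return(FALSE)
  if (!is.null(vf$allele_count_max) && na > vf$allele_count_max) return(FALSE)
  if (!is.null(vf$sequences) && !(v$sequence %in% vf$sequences)) return(FALSE)
  if (!is.null(vf$position_min) && v$position < vf$position_min) return(FALSE)
  if (!is.null(vf$position_max) && v$position > vf$position_max) return(FALSE)
  a <- if (is.null(batch$ann)) NULL else batch$ann[[i]]
  if (!is.null(vf$effects) && length(vf$effects)) {
    if (is.null(a) || !any(a$effect %in% vf$effects)) return(FALSE)
  }
  if (!is.null(vf$gene_names) && length(vf$gene_names)) {
    if (is.null(a) || !any(a$gene_name %in% vf$gene_names)) return(FALSE)
  }
  TRUE
}

# Full-scan evaluation of a query over an import batch; returns variant ids
# in import order.
oracle_query <- function(batch, query) {
  ids <- character()
  for (i in seq_len(nrow(batch$variants))) {
    if (!oracle_variant_pass(batch, i, query$variant_filter)) next
    ok <- TRUE
    majors <- list()
    for (gname in c("group1", "group2")) {
      gf <- query[[gname]]
      if (is.null(gf)) next
      calls <- batch$gt[i, gf$individuals]
      names(calls) <- gf$individuals
      calls <- oracle_mask(calls, batch, i, gf)
      st <- oracle_group_stats(calls)
      if (!oracle_group_pass(st, gf)) ok <- FALSE
      majors[[gname]] <- st$major
    }
    if (ok && query$discriminate) {
      ok <- !is.na(majors$group1) && !is.na(majors$group2) &&
        majors$group1 != majors$group2
    }
    if (ok) ids <- c(ids, batch$variants$variant_id[i])
  }
  ids
}

# Randomized query generator mixing variant-level, MAF, missing-ratio,
# pattern, threshold and discriminate filters.
random_query <- function(batch, discriminate_only = FALSE) {
  inds <- batch$individuals
  seqs <- unique(batch$variants$sequence)
  maybe <- function(p) stats::runif(1) < p
  rand_group <- function(force_aoms = FALSE) {
    n <- sample(3:max(3, length(inds) %/% 2), 1)
    aoms <- force_aoms || maybe(0.5)
    thr <- NULL
    if (length(batch$numeric_fields) && maybe(0.4)) {
      f <- sample(batch$numeric_fields, 1)
      rng <- range(batch$fields[[f]], na.rm = TRUE)
      thr <- stats::setNames(stats::runif(1, rng[1], rng[1] + diff(rng) * 0.4), f)
    }
    gf_group_filter(
      individuals = sample(inds, n),
      pattern = if (aoms) "ALL_OR_MOSTLY_SAME" else "ANY",
      similarity_ratio = stats::runif(1, 0.5, 1),
      maf_min = if (maybe(0.3)) stats::runif(1, 0, 0.2) else NULL,
      maf_max = if (maybe(0.3)) stats::runif(1, 0.25, 0.5) else NULL,
      max_missing_ratio = if (maybe(0.5)) stats::runif(1, 0.05, 0.5) else NULL,
      numeric_thresholds = thr)
  }
  vf <- gf_variant_filter(
    variant_types = if (maybe(0.2)) c("SNP") else NULL,
    allele_count_min = if (maybe(0.15)) 2 else NULL,
    allele_count_max = if (maybe(0.15)) 2 else NULL,
    sequences = if (maybe(0.3)) sample(seqs, max(1, length(seqs) - 1)) else NULL,
    position_min = if (maybe(0.3)) sample.int(2e6, 1) else NULL,
    position_max = if (maybe(0.3)) sample(3e6:5e6, 1) else NULL,
    effects = if (maybe(0.2)) sample(c("missense_variant", "stop_gained",
                                       "intron_variant"), 2) else NULL,
    gene_names = if (maybe(0.1)) sprintf("GENE%03d", sample.int(40, 3)) else NULL)
  disc <- discriminate_only || maybe(0.25)
  g1 <- if (disc || maybe(0.7)) rand_group(force_aoms = disc) else NULL
  g2 <- if (disc || maybe(0.4)) rand_group(force_aoms = disc) else NULL
  if (disc && (is.null(g1) || is.null(g2))) {
    g1 <- g1 %||% rand_group(TRUE); g2 <- g2 %||% rand_group(TRUE)
  }
  gf_query(variant_filter = vf, group1 = g1, group2 = g2,
           discriminate = disc && !is.null(g1) && !is.null(g2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
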