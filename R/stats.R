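#' Mask genotype calls by per-sample numeric thresholds
#'
#' A genotype whose value for any thresholded field is absent or below the
#' field's minimum is treated as missing for all downstream group statistics;
#' stored data are never modified. With no thresholds the view is identical
#' to the stored calls.
#'
#' @param calls named character vector of canonical genotype strings
#'   (individual id -> call, \code{NA} = missing).
#' @param values named list: field name -> named numeric vector of per-sample
#'   values for the same individuals (absent entries mean no value).
#' @param thresholds named numeric vector, field name -> minimum value.
#' @return character vector like \code{calls} with failing calls set to NA.
#' @export
mask_by_thresholds <- function(calls, values, thresholds = NULL) {
  if (is.null(thresholds) || length(thresholds) == 0L) return(calls)
  out <- calls
  for (f in names(thresholds)) {
    v <- values[[f]]
    if (is.null(v)) {
      out[] <- NA_character_
      next
    }
    v <- v[names(calls)]
    out[is.na(v) | v < thresholds[[f]]] <- NA_character_
  }
  out
}

#' Per-group genotype statistics at one variant
#'
#' Computes, over a group's (already masked) calls: the missing-data ratio
#' (fraction of selected individuals with no retained call), genotype counts,
#' the major (modal) genotype with a deterministic tie-break (lexicographically
#' smallest allele-index multiset), its share of called genotypes, allele
#' counts over retained calls, and the minor allele frequency — the frequency
#' of the second-most-frequent allele, 0 for a monomorphic variant, undefined
#' (NA) when nothing is called.
#'
#' @param calls character vector of canonical genotype strings for the
#'   group's selected individuals (\code{NA} = missing).
#' @return a \code{gf_group_stats} list: \code{n_selected}, \code{n_called},
#'   \code{missing_ratio}, \code{genotype_counts}, \code{major_genotype},
#'   \code{major_ratio}, \code{allele_counts}, \code{maf}.
#' @export
group_stats <- function(calls) {
  n_selected <- length(calls)
  if (n_selected == 0L) gf_validation_error("group must be non-empty")
  called <- calls[!is.na(calls)]
  n_called <- length(called)
  missing_ratio <- 1 - n_called / n_selected
  if (n_called == 0L) {
    return(structure(list(
      n_selected = n_selected, n_called = 0L, missing_ratio = missing_ratio,
      genotype_counts = integer(), major_genotype = NA_character_,
      major_ratio = NA_real_, allele_counts = integer(), maf = NA_real_),
      class = "gf_group_stats"))
  }
  ux <- unique(called)
  cnt <- tabulate(match(called, ux))
  idx <- gt_allele_indices(ux)
  # major genotype: modal, ties broken toward the smallest allele multiset
  top <- which(cnt == max(cnt))
  major <- ux[top[1]]
  for (t in top[-1]) if (gt_multiset_lt(idx[[ux[t]]], idx[[major]])) major <- ux[t]
  # allele counts over retained calls
  max_idx <- max(unlist(idx))
  allc <- integer(max_idx + 1L)
  for (j in seq_along(ux)) {
    for (a in idx[[ux[j]]]) allc[a + 1L] <- allc[a + 1L] + cnt[j]
  }
  names(allc) <- as.character(seq_along(allc) - 1L)
  observed <- allc[allc > 0L]
  maf <- if (length(observed) < 2L) 0
         else sort(observed, decreasing = TRUE)[2] / sum(observed)
  structure(list(
    n_selected = n_selected, n_called = n_called,
    missing_ratio = missing_ratio,
    genotype_counts = stats::setNames(cnt, ux),
    major_genotype = major, major_ratio = max(cnt) / n_called,
    allele_counts = allc, maf = unname(maf)),
    class = "gf_group_stats")
}

#' Evaluate one group filter against group statistics
#'
#' Fails when the missing ratio exceeds \code{max_missing_ratio}; when MAF
#' bounds are set and the MAF is undefined or outside them; and, for the
#' \code{ALL_OR_MOSTLY_SAME} pattern, when nothing is called or the major
#' genotype's share of called genotypes is below \code{similarity_ratio}.
#' All comparisons are inclusive. \code{ANY} imposes no pattern condition.
#'
#' @param stats a [group_stats()] result.
#' @param gf a [gf_group_filter()].
#' @return list with \code{pass} (logical) and \code{major} (the group's
#'   major genotype, for discrimination).
#' @export
evaluate_group_filter <- function(stats, gf) {
  pass <- TRUE
  if (!is.null(gf$max_missing_ratio) &&
      stats$missing_ratio > gf$max_missing_ratio + GF_EPS) pass <- FALSE
  if (pass && (!is.null(gf$maf_min) || !is.null(gf$maf_max))) {
    if (is.na(stats$maf)) pass <- FALSE
    else if (!is.null(gf$maf_min) && stats$maf < gf$maf_min - GF_EPS) pass <- FALSE
    else if (!is.null(gf$maf_max) && stats$maf > gf$maf_max + GF_EPS) pass <- FALSE
  }
  if (pass && gf$pattern == "ALL_OR_MOSTLY_SAME") {
    if (stats$n_called == 0L ||
        stats$major_ratio < gf$similarity_ratio - GF_EPS) pass <- FALSE
  }
  list(pass = pass, major = stats$major_genotype)
}

#' Combine two group evaluations into a discrimination verdict
#'
#' TRUE iff both groups pass their filters, both major genotypes are defined,
#' and the majors differ under unphased comparison — i.e. most individuals in
#' each group share a genotype and that genotype differs between the groups.
#'
#' @param result1,result2 results of [evaluate_group_filter()].
#' @return logical.
#' @export
evaluate_discrimination <- function(result1, result2) {
  isTRUE(result1$pass) && isTRUE(result2$pass) &&
    !is.na(result1$major) && !is.na(result2$major) &&
    result1$major != result2$major
}

#' Evaluate the variant-level filter for one variant
#'
#' Conjunction of: type membership, allele-count bounds, sequence membership,
#' inclusive position bounds, and — when the filter carries effect or gene
#' sets — existence of a matching functional annotation.
#'
#' @param record list or one-row data.frame with \code{sequence},
#'   \code{position}, \code{variant_type} and either \code{alleles}
#'   (comma-joined) or \code{n_alleles}.
#' @param annotations annotation data.frame for the variant (may be NULL).
#' @param vf a [gf_variant_filter()].
#' @return logical.
#' @export
evaluate_variant_level <- function(record, annotations, vf) {
  n_alleles <- record$n_alleles %||%
    length(strsplit(record$alleles, ",", fixed = TRUE)[[1]])
  if (!is.null(vf$variant_types) && !record$variant_type %in% vf$variant_types)
    return(FALSE)
  if (!is.null(vf$allele_count_min) && n_alleles < vf$allele_count_min)
    return(FALSE)
  if (!is.null(vf$allele_count_max) && n_alleles > vf$allele_count_max)
    return(FALSE)
  if (!is.null(vf$sequences) && !record$sequence %in% vf$sequences)
    return(FALSE)
  if (!is.null(vf$position_min) && record$position < vf$position_min)
    return(FALSE)
  if (!is.null(vf$position_max) && record$position > vf$position_max)
    return(FALSE)
  if (!is.null(vf$effects) && length(vf$effects)) {
    if (is.null(annotations) || nrow(annotations) == 0L ||
        !any(annotations$effect %in% vf$effects)) return(FALSE)
  }
  if (!is.null(vf$gene_names) && length(vf$gene_names)) {
    if (is.null(annotations) || nrow(annotations) == 0L ||
        !any(annotations$gene_name %in% vf$gene_names)) return(FALSE)
  }
  TRUE
}

# --- vectorized engine internals -------------------------------------------

# Variant-level mask over the indexed variant table (vectorized counterpart
# of evaluate_variant_level, using the ";"-joined annotation summaries).
variant_level_mask <- function(idx, vf) {
  ok <- rep(TRUE, nrow(idx))
  if (!is.null(vf$variant_types)) ok <- ok & idx$variant_type %in% vf$variant_types
  if (!is.null(vf$allele_count_min)) ok <- ok & idx$n_alleles >= vf$allele_count_min
  if (!is.null(vf$allele_count_max)) ok <- ok & idx$n_alleles <= vf$allele_count_max
  if (!is.null(vf$sequences)) ok <- ok & idx$sequence %in% vf$sequences
  if (!is.null(vf$position_min)) ok <- ok & idx$position >= vf$position_min
  if (!is.null(vf$position_max)) ok <- ok & idx$position <= vf$position_max
  set_match <- function(joined, wanted) {
    parts <- strsplit(joined, ";", fixed = TRUE)
    vapply(parts, function(p) any(p %in% wanted), logical(1))
  }
  if (!is.null(vf$effects) && length(vf$effects))
    ok <- ok & set_match(idx$effects, vf$effects)
  if (!is.null(vf$gene_names) && length(vf$gene_names))
    ok <- ok & set_match(idx$genes, vf$gene_names)
  ok
}

# Apply a group's numeric thresholds to a chunk's genotype submatrix
# (rows = the given chunk-row subset, cols = the group's individuals).
mask_chunk <- function(gtm, chunk_fields, thresholds, individuals,
                       rows = NULL) {
  if (is.null(thresholds) || length(thresholds) == 0L) return(gtm)
  if (is.null(rows)) rows <- seq_len(nrow(gtm))
  stopifnot(length(rows) == nrow(gtm))
  for (f in names(thresholds)) {
    v <- chunk_fields[[f]]
    if (is.null(v)) {
      gtm[] <- NA_character_   # field absent from this chunk: nothing retained
      next
    }
    v <- v[rows, individuals, drop = FALSE]
    gtm[is.na(v) | v < thresholds[[f]]] <- NA_character_
  }
  gtm
}

# Per-variant group statistics for a masked chunk submatrix. Returns a list
# of vectors (n_called, missing_ratio, major, major_ratio, maf).
group_stats_chunk <- function(gtm) {
  m <- nrow(gtm); n_sel <- ncol(gtm)
  n_called <- integer(m); major <- character(m)
  major_ratio <- rep(NA_real_, m); maf <- rep(NA_real_, m)
  idx_memo <- gt_allele_indices(gtm)
  for (i in seq_len(m)) {
    x <- gtm[i, ]
    x <- x[!is.na(x)]
    nc <- length(x)
    n_called[i] <- nc
    if (nc == 0L) { major[i] <- NA_character_; next }
    ux <- unique(x)
    cnt <- tabulate(match(x, ux))
    top <- which(cnt == max(cnt))
    mj <- ux[top[1]]
    if (length(top) > 1L)
      for (t in top[-1])
        if (gt_multiset_lt(idx_memo[[ux[t]]], idx_memo[[mj]])) mj <- ux[t]
    major[i] <- mj
    major_ratio[i] <- max(cnt) / nc
    al <- unlist(idx_memo[ux], use.names = FALSE)
    rep_cnt <- rep.int(cnt, lengths(idx_memo[ux]))
    allc <- vapply(split(rep_cnt, al), sum, numeric(1))
    maf[i] <- if (length(allc) < 2L) 0
              else sort(allc, decreasing = TRUE)[2] / sum(allc)
  }
  list(n_called = n_called,
       missing_ratio = 1 - n_called / n_sel,
       major = major, major_ratio = major_ratio, maf = maf)
}

# Vectorized group-filter decision over group_stats_chunk output.
group_filter_mask <- function(gs, gf) {
  m <- length(gs$n_called)
  pass <- rep(TRUE, m)
  if (!is.null(gf$max_missing_ratio))
    pass <- pass & gs$missing_ratio <= gf$max_missing_ratio + GF_EPS
  if (!is.null(gf$maf_min) || !is.null(gf$maf_max)) {
    pass <- pass & !is.na(gs$maf)
    if (!is.null(gf$maf_min)) pass <- pass & !is.na(gs$maf) & gs$maf >= gf$maf_min - GF_EPS
    if (!is.null(gf$maf_max)) pass <- pass & !is.na(gs$maf) & gs$maf <= gf$maf_max + GF_EPS
  }
  if (gf$pattern == "ALL_OR_MOSTLY_SAME")
    pass <- pass & gs$n_called > 0L &
      !is.na(gs$major_ratio) & gs$major_ratio >= gf$similarity_ratio - GF_EPS
  pass
}
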