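#' Variant-level filter block
#'
#' Filters on indexed per-variant facts: variant type, number of known
#' alleles, sequence, 1-based inclusive position bounds, and functional
#' annotation (consequence terms and gene names). Empty effect/gene sets mean
#' no annotation filtering; NULL bounds are unbounded.
#'
#' @param variant_types subset of \code{c("SNP","INDEL","MNP","OTHER")}, or
#'   NULL for all.
#' @param allele_count_min,allele_count_max bounds on the number of known
#'   alleles.
#' @param sequences subset of sequence names, or NULL for all.
#' @param position_min,position_max 1-based inclusive position bounds.
#' @param effects set of consequence terms (e.g. \code{"missense_variant"}).
#' @param gene_names set of gene names.
#' @return a \code{gf_variant_filter}.
#' @export
gf_variant_filter <- function(variant_types = NULL, allele_count_min = NULL,
                              allele_count_max = NULL, sequences = NULL,
                              position_min = NULL, position_max = NULL,
                              effects = NULL, gene_names = NULL) {
  if (!is.null(variant_types)) {
    bad <- setdiff(variant_types, c("SNP", "INDEL", "MNP", "OTHER"))
    if (length(bad))
      gf_validation_error(sprintf("unknown variant type(s): %s",
                                  paste(bad, collapse = ", ")))
  }
  if (!is.null(allele_count_min) && !is.null(allele_count_max) &&
      allele_count_min > allele_count_max)
    gf_validation_error("allele_count_min > allele_count_max")
  if (!is.null(position_min) && !is.null(position_max) &&
      position_min > position_max)
    gf_validation_error("position_min > position_max")
  structure(list(variant_types = variant_types,
                 allele_count_min = allele_count_min,
                 allele_count_max = allele_count_max,
                 sequences = sequences,
                 position_min = position_min, position_max = position_max,
                 effects = effects, gene_names = gene_names),
            class = "gf_variant_filter")
}

#' Per-group genotype-level filter block
#'
#' Applies to one group of selected individuals. Numeric thresholds mask a
#' genotype to missing when any thresholded per-sample field is absent or
#' below its minimum; group statistics (missing ratio, MAF, major genotype)
#' are then computed on the retained calls. The \code{ALL_OR_MOSTLY_SAME}
#' pattern requires at least \code{similarity_ratio} of the group's called
#' genotypes to equal the group's major (modal) genotype; \code{ANY} imposes
#' no pattern condition. All fraction comparisons are inclusive.
#'
#' @param individuals non-empty character vector of individual ids.
#' @param pattern \code{"ANY"} or \code{"ALL_OR_MOSTLY_SAME"}.
#' @param similarity_ratio fraction in [0,1]; used only with
#'   \code{ALL_OR_MOSTLY_SAME}.
#' @param maf_min,maf_max minor-allele-frequency bounds in [0, 0.5], or NULL.
#' @param max_missing_ratio maximum tolerated missing-data ratio, or NULL.
#' @param numeric_thresholds named numeric vector or list, field name ->
#'   minimum value (e.g. \code{c(DP = 10, GQ = 30)}).
#' @return a \code{gf_group_filter}.
#' @export
gf_group_filter <- function(individuals,
                            pattern = c("ANY", "ALL_OR_MOSTLY_SAME"),
                            similarity_ratio = 1.0,
                            maf_min = NULL, maf_max = NULL,
                            max_missing_ratio = NULL,
                            numeric_thresholds = NULL) {
  pattern <- match.arg(pattern)
  if (length(individuals) == 0L)
    gf_validation_error("group must contain at least one individual")
  if (anyDuplicated(individuals))
    gf_validation_error("duplicate individual id in group")
  if (similarity_ratio < 0 || similarity_ratio > 1)
    gf_validation_error("similarity_ratio must be in [0, 1]")
  for (b in c(maf_min, maf_max))
    if (!is.null(b) && (b < 0 || b > 0.5))
      gf_validation_error("MAF bounds must be in [0, 0.5]")
  if (!is.null(maf_min) && !is.null(maf_max) && maf_min > maf_max)
    gf_validation_error("maf_min > maf_max")
  if (!is.null(max_missing_ratio) &&
      (max_missing_ratio < 0 || max_missing_ratio > 1))
    gf_validation_error("max_missing_ratio must be in [0, 1]")
  thr <- NULL
  if (!is.null(numeric_thresholds) && length(numeric_thresholds)) {
    thr <- as.numeric(unlist(numeric_thresholds))
    names(thr) <- names(unlist(numeric_thresholds))
    if (is.null(names(thr)) || any(names(thr) == ""))
      gf_validation_error("numeric_thresholds must be named field -> minimum")
  }
  structure(list(individuals = as.character(individuals), pattern = pattern,
                 similarity_ratio = similarity_ratio,
                 maf_min = maf_min, maf_max = maf_max,
                 max_missing_ratio = max_missing_ratio,
                 numeric_thresholds = thr),
            class = "gf_group_filter")
}

#' Assemble a query
#'
#' A query is one variant-level block plus up to two group filter blocks and
#' a discriminate flag. With both groups present and \code{discriminate =
#' FALSE}, a variant must satisfy both group filters (conjunction). With
#' \code{discriminate = TRUE} (which requires both groups and the
#' \code{ALL_OR_MOSTLY_SAME} pattern on each), a variant additionally needs
#' the two groups' major genotypes to differ under unphased comparison.
#'
#' @param variant_filter a [gf_variant_filter()] (default: match everything).
#' @param group1,group2 optional [gf_group_filter()] blocks.
#' @param discriminate logical.
#' @return a \code{gf_query}.
#' @export
gf_query <- function(variant_filter = gf_variant_filter(),
                     group1 = NULL, group2 = NULL, discriminate = FALSE) {
  if (discriminate) {
    if (is.null(group1) || is.null(group2))
      gf_validation_error("discriminate requires both group filters")
    if (group1$pattern != "ALL_OR_MOSTLY_SAME" ||
        group2$pattern != "ALL_OR_MOSTLY_SAME")
      gf_validation_error(
        "discriminate requires the ALL_OR_MOSTLY_SAME pattern on both groups")
  }
  structure(list(variant_filter = variant_filter, group1 = group1,
                 group2 = group2, discriminate = isTRUE(discriminate)),
            class = "gf_query")
}

#' Canonical cache key for a query against a dataset
#'
#' A field-order-independent serialization of (dataset name, query): names
#' are sorted recursively and set-valued fields sorted, so two semantically
#' identical queries map to the same key however they were spelled.
#'
#' @param ds a \code{gf_dataset}.
#' @param query a [gf_query()].
#' @return a character scalar.
#' @export
gf_query_key <- function(ds, query) {
  canon_gf <- function(g) {
    if (is.null(g)) return(NULL)
    thr <- g$numeric_thresholds
    if (!is.null(thr)) thr <- as.list(thr[order(names(thr))])
    list(individuals = sort(g$individuals), pattern = g$pattern,
         similarity_ratio = if (g$pattern == "ALL_OR_MOSTLY_SAME")
           g$similarity_ratio else NULL,
         maf_min = g$maf_min, maf_max = g$maf_max,
         max_missing_ratio = g$max_missing_ratio,
         numeric_thresholds = thr)
  }
  vf <- query$variant_filter
  canonical_json(list(
    dataset = ds$name,
    variant_filter = list(
      variant_types = if (is.null(vf$variant_types)) NULL else sort(vf$variant_types),
      allele_count_min = vf$allele_count_min,
      allele_count_max = vf$allele_count_max,
      sequences = if (is.null(vf$sequences)) NULL else sort(vf$sequences),
      position_min = vf$position_min, position_max = vf$position_max,
      effects = if (is.null(vf$effects)) NULL else sort(vf$effects),
      gene_names = if (is.null(vf$gene_names)) NULL else sort(vf$gene_names)),
    group1 = canon_gf(query$group1),
    group2 = canon_gf(query$group2),
    discriminate = query$discriminate))
}

validate_query <- function(ds, query) {
  stopifnot(inherits(query, "gf_query"))
  vf <- query$variant_filter
  if (!is.null(vf$sequences)) {
    bad <- setdiff(vf$sequences, ds$sequences)
    if (length(bad))
      gf_validation_error(sprintf("unknown sequence(s): %s",
                                  paste(bad, collapse = ", ")))
  }
  for (g in list(query$group1, query$group2)) {
    if (is.null(g)) next
    bad <- setdiff(g$individuals, ds$individuals)
    if (length(bad))
      gf_validation_error(sprintf("group references unknown individual(s): %s",
                                  paste(utils::head(bad, 5), collapse = ", ")))
    badf <- setdiff(names(g$numeric_thresholds), ds$numeric_fields)
    if (length(badf))
      gf_validation_error(sprintf(
        "unknown numeric field(s) %s; fields detected at import: %s",
        paste(badf, collapse = ", "),
        if (length(ds$numeric_fields)) paste(ds$numeric_fields, collapse = ", ")
        else "(none)"))
  }
  invisible(TRUE)
}
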