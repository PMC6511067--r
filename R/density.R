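bin_of <- function(pos, range_min, range_max, n_bins) {
  width <- (range_max - range_min + 1) / n_bins
  pmin(floor((pos - range_min) / width), n_bins - 1L) + 1L
}

#' Binned variant density over a sequence interval
#'
#' Counts variants per bin over a 1-based inclusive position range,
#' optionally restricted to a query's matching variants. Each zoom level is a
#' fresh computation at the requested resolution; a position exactly at
#' \code{range_max} falls in the last bin (clamping).
#'
#' @param ds a \code{gf_dataset}.
#' @param sequence sequence name.
#' @param range_min,range_max 1-based inclusive interval bounds.
#' @param n_bins number of bins (>= 1).
#' @param query optional [gf_query()] restricting the counted variants.
#' @param ids optional explicit character vector of variant ids (overrides
#'   \code{query}).
#' @return a \code{gf_density_bins} list: \code{sequence}, \code{range_min},
#'   \code{range_max}, \code{n_bins}, \code{bin_start}, \code{bin_end},
#'   \code{counts} (and \code{field_sums} from [compute_field_series()]).
#' @export
compute_density <- function(ds, sequence, range_min, range_max, n_bins,
                            query = NULL, ids = NULL) {
  if (!sequence %in% ds$sequences)
    gf_validation_error(sprintf("unknown sequence '%s'", sequence))
  if (range_min > range_max) gf_validation_error("range_min > range_max")
  if (n_bins < 1L) gf_validation_error("n_bins must be >= 1")
  idx <- variant_index(ds)
  keep <- idx$sequence == sequence & idx$position >= range_min &
    idx$position <= range_max
  if (!is.null(ids)) {
    keep <- keep & idx$variant_id %in% ids
  } else if (!is.null(query)) {
    res <- execute_query(ds, query, mode = "find")
    keep <- keep & idx$variant_id %in% res$variant_ids
  }
  counts <- integer(n_bins)
  if (any(keep)) {
    b <- bin_of(idx$position[keep], range_min, range_max, n_bins)
    counts <- as.integer(tabulate(b, nbins = n_bins))
  }
  width <- (range_max - range_min + 1) / n_bins
  structure(list(sequence = sequence, range_min = range_min,
                 range_max = range_max, n_bins = as.integer(n_bins),
                 bin_start = floor(range_min + (seq_len(n_bins) - 1L) * width),
                 bin_end = c(floor(range_min + seq_len(n_bins - 1L) * width) - 1L,
                             range_max),
                 counts = counts, field_sums = NULL),
            class = "gf_density_bins")
}

#' Cumulated numeric-field series over density bins
#'
#' For each bin, sums a per-sample numeric field (e.g. DP) over the variants
#' in the bin and over a chosen selection of individuals; absent values
#' contribute 0. Used to view variant density against read-depth or quality
#' distributions.
#'
#' @inheritParams compute_density
#' @param field a numeric field detected at import.
#' @param individuals subset of dataset individuals to cumulate over.
#' @return a \code{gf_density_bins} with \code{field_sums} filled.
#' @export
compute_field_series <- function(ds, field, individuals, sequence,
                                 range_min, range_max, n_bins,
                                 query = NULL, ids = NULL) {
  if (!field %in% ds$numeric_fields)
    gf_validation_error(sprintf(
      "unknown numeric field '%s'; fields detected at import: %s", field,
      if (length(ds$numeric_fields)) paste(ds$numeric_fields, collapse = ", ")
      else "(none)"))
  bad <- setdiff(individuals, ds$individuals)
  if (length(bad))
    gf_validation_error(sprintf("unknown individual(s): %s",
                                paste(utils::head(bad, 5), collapse = ", ")))
  bins <- compute_density(ds, sequence, range_min, range_max, n_bins,
                          query = query, ids = ids)
  sums <- numeric(n_bins)
  if (length(individuals)) {
    idx <- variant_index(ds)
    keep <- idx$sequence == sequence & idx$position >= range_min &
      idx$position <= range_max
    if (!is.null(ids)) keep <- keep & idx$variant_id %in% ids
    else if (!is.null(query))
      keep <- keep & idx$variant_id %in%
        execute_query(ds, query, mode = "find")$variant_ids
    sel <- idx[keep, , drop = FALSE]
    for (k in unique(sel$chunk)) {
      chunk <- read_chunk(ds, k)
      v <- chunk$fields[[field]]
      if (is.null(v)) next
      rows <- sel$row[sel$chunk == k]
      pos <- sel$position[sel$chunk == k]
      per_variant <- rowSums(v[rows, individuals, drop = FALSE], na.rm = TRUE)
      b <- bin_of(pos, range_min, range_max, n_bins)
      for (i in seq_along(b)) sums[b[i]] <- sums[b[i]] + per_variant[i]
    }
  }
  bins$field_sums <- sums
  bins
}

#' Write density bins as TSV
#'
#' Emits \code{bin_start}, \code{bin_end}, \code{count} (and
#' \code{field_sum} when present) for external plotting.
#'
#' @param bins a \code{gf_density_bins}.
#' @param path output path ("" for stdout).
#' @export
write_density_tsv <- function(bins, path = "") {
  df <- data.frame(bin_start = bins$bin_start, bin_end = bins$bin_end,
                   count = bins$counts)
  if (!is.null(bins$field_sums)) df$field_sum <- bins$field_sums
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
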