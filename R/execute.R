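#' Execute a query against a dataset
#'
#' Evaluation is chunk-wise: the variant-level filter is applied first on the
#' indexed variant table; group logic then runs on threshold-masked genotype
#' calls, chunk by chunk, independently — the result is identical to a
#' single-pass evaluation of all variants in import order. Per-chunk match
#' counts are cached under the query's canonical key: a repeated count is
#' answered from the cache without touching genotypes, and a repeated find
#' skips chunks whose cached count is zero and stops scanning a chunk once
#' its cached number of matches has been emitted. A query with no group
#' filters takes an indexed fast path that never materializes genotype data.
#'
#' @param ds a \code{gf_dataset}.
#' @param query a [gf_query()].
#' @param mode \code{"count"} (total only) or \code{"find"} (matching variant
#'   ids, in dataset import order).
#' @param count_at_same_time in find mode, also record the per-chunk counts in
#'   the cache from the same single evaluation pass (default TRUE; counts are
#'   a free by-product here).
#' @param workers number of parallel chunk workers (forked via
#'   \code{parallel::mclapply} when > 1; results are scheduling-independent).
#' @param progress optional \code{function(chunk, n_chunks, matched)} called
#'   after each chunk.
#' @return a \code{gf_query_result}: \code{total_count},
#'   \code{per_chunk_counts}, \code{variant_ids} (find mode),
#'   \code{from_cache}.
#' @export
execute_query <- function(ds, query, mode = c("count", "find"),
                          count_at_same_time = TRUE, workers = 1L,
                          progress = NULL) {
  mode <- match.arg(mode)
  validate_query(ds, query)
  key <- gf_query_key(ds, query)
  n_chunks <- length(ds$chunk_sizes)
  cached <- get_cached_counts(ds, key)

  if (mode == "count" && !is.null(cached)) {
    return(query_result(sum(cached), cached, NULL, TRUE))
  }

  idx <- variant_index(ds)
  vmask <- variant_level_mask(idx, query$variant_filter)
  has_groups <- !is.null(query$group1) || !is.null(query$group2)

  if (!has_groups) {
    # indexed fast path: no genotype-level work, no id materialization needed
    counts <- integer(n_chunks)
    if (any(vmask)) {
      tab <- table(factor(idx$chunk[vmask], levels = seq_len(n_chunks)))
      counts <- as.integer(tab)
    }
    if (is.null(cached)) put_cached_counts(ds, key, counts)
    ids <- if (mode == "find") idx$variant_id[vmask] else NULL
    return(query_result(sum(counts), counts, ids, !is.null(cached)))
  }

  eval_chunk <- function(k) {
    rows <- which(vmask & idx$chunk == k)
    if (length(rows) == 0L) return(character())
    limit <- if (!is.null(cached)) cached[k] else NA_integer_
    if (!is.na(limit) && limit == 0L) return(character())
    chunk <- read_chunk(ds, k)
    crows <- idx$row[rows]
    matched <- chunk_group_matches(chunk, crows, query, limit)
    idx$variant_id[rows[matched]]
  }

  ids_per_chunk <- if (workers > 1L && n_chunks > 1L) {
    parallel::mclapply(seq_len(n_chunks), eval_chunk, mc.cores = workers)
  } else {
    out <- vector("list", n_chunks)
    for (k in seq_len(n_chunks)) {
      out[[k]] <- eval_chunk(k)
      if (!is.null(progress)) progress(k, n_chunks, length(out[[k]]))
    }
    out
  }
  counts <- lengths(ids_per_chunk)
  if (is.null(cached) && (mode == "count" || count_at_same_time))
    put_cached_counts(ds, key, counts)
  ids <- if (mode == "find") unlist(ids_per_chunk, use.names = FALSE) else NULL
  query_result(sum(counts), as.integer(counts), ids, !is.null(cached))
}

# Group-logic evaluation for the rows of one chunk that already passed the
# variant-level filter. `limit` (from the cache) allows early stop: rows are
# evaluated in import-order blocks and scanning stops once `limit` matches
# have been found.
chunk_group_matches <- function(chunk, crows, query, limit = NA_integer_,
                                block = 512L) {
  n <- length(crows)
  matched <- integer()
  done <- 0L
  while (done < n) {
    take <- seq.int(done + 1L, min(done + block, n))
    sub <- crows[take]
    pass <- rep(TRUE, length(sub))
    res1 <- res2 <- NULL
    for (gi in 1:2) {
      gf <- if (gi == 1L) query$group1 else query$group2
      if (is.null(gf)) next
      gtm <- chunk$gt[sub, gf$individuals, drop = FALSE]
      gtm <- mask_chunk(gtm, chunk$fields, gf$numeric_thresholds,
                        gf$individuals, rows = sub)
      gs <- group_stats_chunk(gtm)
      gpass <- group_filter_mask(gs, gf)
      pass <- pass & gpass
      if (gi == 1L) res1 <- list(pass = gpass, major = gs$major)
      else res2 <- list(pass = gpass, major = gs$major)
    }
    if (query$discriminate) {
      pass <- pass & !is.na(res1$major) & !is.na(res2$major) &
        res1$major != res2$major
    }
    matched <- c(matched, take[pass])
    done <- done + length(take)
    if (!is.na(limit) && length(matched) >= limit) {
      matched <- matched[seq_len(limit)]
      break
    }
  }
  matched
}

query_result <- function(total, per_chunk, ids, from_cache) {
  structure(list(total_count = as.integer(total),
                 per_chunk_counts = as.integer(per_chunk),
                 variant_ids = ids, from_cache = from_cache),
            class = "gf_query_result")
}

#' @export
print.gf_query_result <- function(x, ...) {
  cat(sprintf("<gf_query_result> %d matching variant(s) over %d chunk(s)%s%s\n",
              x$total_count, length(x$per_chunk_counts),
              if (x$from_cache) " [cache]" else "",
              if (!is.null(x$variant_ids)) " [find]" else " [count]"))
  invisible(x)
}
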