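#' Create an empty dataset in a store directory
#'
#' A dataset is a directory holding a JSON descriptor, a tab-separated
#' variant-level index (the indexed, cheap-to-scan tier), one serialized
#' genotype-run blob per chunk (the genotype tier), and a JSON count cache.
#' Variants are chunked in import order, \code{chunk_size} per chunk; the
#' chunk is the unit of query execution, caching and progress reporting.
#'
#' @param name dataset identifier (used as directory name).
#' @param individuals ordered character vector of unique individual ids.
#' @param chunk_size variants per chunk (default 5000).
#' @param store_dir parent directory for datasets.
#' @return a \code{gf_dataset} descriptor (list with name, path, individuals,
#'   sequences, chunk sizes, detected numeric fields, annotation source).
#' @export
gf_create_dataset <- function(name, individuals, chunk_size = 5000L,
                              store_dir = ".") {
  if (!grepl("^[A-Za-z0-9._-]+$", name))
    gf_validation_error("dataset name must match [A-Za-z0-9._-]+")
  if (length(individuals) == 0L)
    gf_validation_error("individuals must be non-empty")
  if (anyDuplicated(individuals))
    gf_validation_error(sprintf("duplicate individual id: '%s'",
                                individuals[duplicated(individuals)][1]))
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1L)
    gf_validation_error("chunk_size must be a positive integer")
  path <- file.path(store_dir, name)
  if (file.exists(file.path(path, "descriptor.json")))
    gf_error(sprintf("dataset '%s' already exists in %s", name, store_dir),
             "gf_already_exists_error")
  dir.create(file.path(path, "chunks"), recursive = TRUE, showWarnings = FALSE)
  ds <- list(name = name, path = path,
             individuals = as.character(individuals),
             sequences = character(), chunk_size = chunk_size,
             ploidy = 2L, numeric_fields = character(),
             field_types = character(),
             annotation_source = "none",
             n_variants = 0L, chunk_sizes = integer())
  class(ds) <- "gf_dataset"
  write_descriptor(ds)
  utils::write.table(empty_variant_index(), file.path(path, "variants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ds
}

empty_variant_index <- function() {
  data.frame(variant_id = character(), sequence = character(),
             position = integer(), variant_type = character(),
             alleles = character(), n_alleles = integer(),
             effects = character(), genes = character(),
             chunk = integer(), row = integer(), stringsAsFactors = FALSE)
}

write_descriptor <- function(ds) {
  d <- unclass(ds)
  d$path <- NULL
  d$field_types <- as.list(d$field_types)  # keep names in JSON
  jsonlite::write_json(d, file.path(ds$path, "descriptor.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Open an existing dataset
#'
#' @param path dataset directory (as created by [gf_create_dataset()]).
#' @return a \code{gf_dataset} descriptor.
#' @export
gf_open_dataset <- function(path) {
  dfile <- file.path(path, "descriptor.json")
  if (!file.exists(dfile)) gf_io_error(sprintf("no dataset at %s", path))
  ds <- jsonlite::read_json(dfile, simplifyVector = TRUE)
  ds$path <- path
  ds$individuals <- as.character(ds$individuals)
  ds$sequences <- as.character(ds$sequences)
  ds$numeric_fields <- as.character(ds$numeric_fields)
  ds$field_types <- unlist(ds$field_types) %||% character()
  ds$chunk_sizes <- as.integer(ds$chunk_sizes)
  class(ds) <- "gf_dataset"
  ds
}

#' @export
print.gf_dataset <- function(x, ...) {
  cat(sprintf("<gf_dataset '%s'> %d variants in %d chunk(s) (chunk_size %d), %d individuals\n",
              x$name, x$n_variants, length(x$chunk_sizes), x$chunk_size,
              length(x$individuals)))
  cat(sprintf("  sequences: %s\n  numeric fields: %s; annotations: %s\n",
              paste(utils::head(x$sequences, 8), collapse = ", "),
              if (length(x$numeric_fields)) paste(x$numeric_fields, collapse = ", ") else "none",
              x$annotation_source))
  invisible(x)
}

variant_index <- function(ds) {
  utils::read.table(file.path(ds$path, "variants.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE, quote = "",
                    comment.char = "",
                    colClasses = c("character", "character", "integer",
                                   "character", "character", "integer",
                                   "character", "character",
                                   "integer", "integer"))
}

chunk_path <- function(ds, k) file.path(ds$path, "chunks", sprintf("chunk_%05d.rds", k))

read_chunk <- function(ds, k) readRDS(chunk_path(ds, k))

#' Ingest an import batch into a dataset
#'
#' Appends the batch's variants in import order as new chunks of
#' \code{chunk_size} variants (the final chunk may be short). Existing chunks
#' are never rewritten; a pre-existing short final chunk stays short. Missing
#' genotypes are stored as absences (\code{NA}), never as explicit records.
#' Any ingest invalidates the dataset's cached query counts.
#'
#' @param ds a \code{gf_dataset}.
#' @param batch a [gf_batch()].
#' @return the updated descriptor, with an \code{ingest_summary} attribute
#'   (variants added, chunks created).
#' @export
gf_ingest <- function(ds, batch) {
  stopifnot(inherits(ds, "gf_dataset"), inherits(batch, "gf_batch"))
  unknown <- setdiff(batch$individuals, ds$individuals)
  if (length(unknown))
    gf_validation_error(sprintf("batch references unknown individual(s): %s",
                                paste(utils::head(unknown, 5), collapse = ", ")))
  idx <- variant_index(ds)
  coll <- intersect(batch$variants$variant_id, idx$variant_id)
  if (length(coll))
    gf_error(sprintf("variant id collision on ingest: %s",
                     paste(utils::head(coll, 5), collapse = ", ")),
             "gf_collision_error")

  m <- nrow(batch$variants)
  n_chunks0 <- length(ds$chunk_sizes)
  starts <- seq(1L, max(m, 1L), by = ds$chunk_size)
  if (m == 0L) starts <- integer()
  new_sizes <- integer()
  for (s in starts) {
    e <- min(s + ds$chunk_size - 1L, m)
    rows <- s:e
    k <- n_chunks0 + length(new_sizes) + 1L
    chunk <- list(
      variant_id = batch$variants$variant_id[rows],
      gt = expand_to_dataset(batch$gt[rows, , drop = FALSE],
                             batch$individuals, ds$individuals, NA_character_),
      phased = if (!is.null(batch$phased))
        expand_to_dataset(batch$phased[rows, , drop = FALSE],
                          batch$individuals, ds$individuals, FALSE) else NULL,
      fields = lapply(batch$fields, function(f)
        expand_to_dataset(f[rows, , drop = FALSE],
                          batch$individuals, ds$individuals, NA_real_)),
      ann = if (!is.null(batch$ann)) batch$ann[rows] else NULL)
    saveRDS(chunk, chunk_path(ds, k))
    new_sizes <- c(new_sizes, length(rows))
  }

  if (m > 0L) {
    new_idx <- batch$variants[, c("variant_id", "sequence", "position",
                                  "variant_type", "alleles", "n_alleles",
                                  "effects", "genes")]
    new_idx$chunk <- n_chunks0 + 1L +
      (seq_len(m) - 1L) %/% ds$chunk_size
    new_idx$row <- (seq_len(m) - 1L) %% ds$chunk_size + 1L
    utils::write.table(new_idx, file.path(ds$path, "variants.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE,
                       col.names = FALSE, append = TRUE)
  }

  ds$sequences <- union(ds$sequences, unique(batch$variants$sequence))
  new_fields <- setdiff(batch$numeric_fields, ds$numeric_fields)
  ds$numeric_fields <- union(ds$numeric_fields, batch$numeric_fields)
  ds$field_types <- c(ds$field_types, batch$field_types[new_fields])
  if (batch$annotation_source != "none")
    ds$annotation_source <- batch$annotation_source
  calls <- batch$gt[!is.na(batch$gt)]
  if (length(calls))
    ds$ploidy <- max(ds$ploidy %||% 1L,
                     max(lengths(gt_allele_indices(calls))))
  ds$n_variants <- ds$n_variants + m
  ds$chunk_sizes <- c(ds$chunk_sizes, new_sizes)
  write_descriptor(ds)
  gf_clear_cache(ds)
  attr(ds, "ingest_summary") <- list(variants_added = m,
                                     chunks_created = length(new_sizes))
  ds
}

# Reorder/expand a batch matrix to the dataset's full individual set;
# individuals absent from the batch get the fill value (missing).
expand_to_dataset <- function(mat, batch_ind, ds_ind, fill) {
  if (identical(batch_ind, ds_ind)) return(mat)
  out <- matrix(fill, nrow = nrow(mat), ncol = length(ds_ind),
                dimnames = list(NULL, ds_ind))
  out[, batch_ind] <- mat
  out
}

cache_file <- function(ds) file.path(ds$path, "cache.json")

read_cache <- function(ds) {
  f <- cache_file(ds)
  if (!file.exists(f)) return(list())
  jsonlite::read_json(f, simplifyVector = TRUE)
}

#' Per-query chunk-count cache
#'
#' Every executed query's per-chunk match counts are cached under a canonical
#' query key; their sum is the query's total result count. Cached counts give
#' instant answers for repeated counts and let a later find stop scanning a
#' chunk after emitting that many matches. The cache lives in the dataset
#' directory, so it survives process restarts; any ingest clears it.
#'
#' @param ds a \code{gf_dataset}.
#' @param query_key canonical key from [gf_query_key()].
#' @param counts integer vector, one count per chunk.
#' @return \code{get_cached_counts}: the cached integer vector, or NULL.
#' @export
get_cached_counts <- function(ds, query_key) {
  cache <- read_cache(ds)
  v <- cache[[query_key]]
  if (is.null(v)) NULL else as.integer(v)
}

#' @rdname get_cached_counts
#' @export
put_cached_counts <- function(ds, query_key, counts) {
  if (length(counts) != length(ds$chunk_sizes))
    gf_validation_error(sprintf(
      "count array length %d does not match chunk count %d",
      length(counts), length(ds$chunk_sizes)))
  cache <- read_cache(ds)
  cache[[query_key]] <- as.integer(counts)
  jsonlite::write_json(cache, cache_file(ds), auto_unbox = FALSE, digits = NA)
  invisible(NULL)
}

#' @rdname get_cached_counts
#' @export
gf_clear_cache <- function(ds) {
  f <- cache_file(ds)
  if (file.exists(f)) unlink(f)
  invisible(NULL)
}

#' Attach individual metadata to a dataset
#'
#' Stores a metadata table (as read by [read_metadata_tsv()]) inside the
#' dataset directory so groups can later be selected by attribute value.
#'
#' @param ds a \code{gf_dataset}.
#' @param metadata data.frame whose first column is \code{individual_id}.
#' @return invisibly, the number of rows stored.
#' @export
gf_attach_metadata <- function(ds, metadata) {
  unknown <- setdiff(metadata$individual_id, ds$individuals)
  if (length(unknown)) {
    warning(sprintf("metadata for %d unknown individual(s) skipped",
                    length(unknown)))
    metadata <- metadata[metadata$individual_id %in% ds$individuals, ,
                         drop = FALSE]
  }
  utils::write.table(metadata, file.path(ds$path, "metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(nrow(metadata))
}

#' Select individuals by a metadata attribute value
#'
#' @param ds a \code{gf_dataset} with attached metadata.
#' @param attribute metadata column name.
#' @param value attribute value to match.
#' @return character vector of individual ids.
#' @export
gf_individuals_where <- function(ds, attribute, value) {
  f <- file.path(ds$path, "metadata.tsv")
  if (!file.exists(f)) gf_validation_error("dataset has no attached metadata")
  md <- utils::read.table(f, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", colClasses = "character")
  if (!attribute %in% names(md))
    gf_validation_error(sprintf("no metadata attribute '%s' (have: %s)",
                                attribute, paste(names(md)[-1], collapse = ", ")))
  md$individual_id[md[[attribute]] == value]
}
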