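FJ_GENOTYPE_MEMBER <- "genotypes.fjgenotype"
FJ_MAP_MEMBER <- "map.fjmap"

#' Export a dataset (or a query's result set) to a standard format
#'
#' Writes the selected variants in dataset import order, emitting only the
#' chosen individuals' columns — the export subset is independent of any
#' group used for filtering. Reading and writing are decoupled: a chunk
#' reader feeds record batches to a format writer sink, so output of earlier
#' chunks proceeds while later ones are read, with per-chunk progress.
#'
#' Formats: \code{vcf} (genotypes plus numeric FORMAT fields and re-emitted
#' functional annotations), \code{plink} (PED+MAP pair, missing written
#' \code{"0 0"}), \code{hapmap} (SNPs only; other variants are skipped and
#' counted), \code{flapjack} (a \code{.fjzip} zip container holding a
#' tab-delimited genotype matrix and a map file).
#'
#' @param ds a \code{gf_dataset}.
#' @param out output path; for \code{plink} a prefix (writes
#'   \code{<out>.ped} and \code{<out>.map}).
#' @param format one of \code{"vcf"}, \code{"plink"}, \code{"hapmap"},
#'   \code{"flapjack"}.
#' @param individuals subset of dataset individuals (default: all).
#' @param ids variant ids to export, e.g. a query result's
#'   \code{variant_ids} (default: whole dataset).
#' @param gzip gzip-compress text outputs (appends \code{.gz}).
#' @param progress optional \code{function(chunk, n_chunks)}.
#' @return export summary: list with \code{format}, \code{files},
#'   \code{n_variants}, \code{n_individuals}, \code{skipped}.
#' @export
gf_export <- function(ds, out, format = c("vcf", "plink", "hapmap", "flapjack"),
                      individuals = NULL, ids = NULL, gzip = FALSE,
                      progress = NULL) {
  format <- match.arg(format)
  if (is.null(individuals)) individuals <- ds$individuals
  bad <- setdiff(individuals, ds$individuals)
  if (length(bad))
    gf_validation_error(sprintf("unknown individual(s) in export subset: %s",
                                paste(utils::head(bad, 5), collapse = ", ")))
  idx <- variant_index(ds)
  sel <- if (is.null(ids)) idx else idx[idx$variant_id %in% ids, , drop = FALSE]

  writer <- switch(format,
    vcf = vcf_writer(ds, out, individuals, gzip),
    plink = plink_writer(ds, out, individuals, gzip),
    hapmap = hapmap_writer(ds, out, individuals, gzip),
    flapjack = flapjack_writer(ds, out, individuals))

  chunks <- unique(sel$chunk)
  for (ci in seq_along(chunks)) {
    k <- chunks[ci]
    rows <- sel[sel$chunk == k, , drop = FALSE]
    chunk <- read_chunk(ds, k)
    batch <- list(
      variants = rows,
      gt = chunk$gt[rows$row, individuals, drop = FALSE],
      fields = lapply(chunk$fields, function(f)
        f[rows$row, individuals, drop = FALSE]),
      ann = if (!is.null(chunk$ann)) chunk$ann[rows$row] else NULL)
    writer$write(batch)
    if (!is.null(progress)) progress(ci, length(chunks))
  }
  files <- writer$finish()
  list(format = format, files = files, n_variants = nrow(sel) - writer$skipped(),
       n_individuals = length(individuals), skipped = writer$skipped())
}

alleles_of <- function(alleles_str) strsplit(alleles_str, ",", fixed = TRUE)

# --- VCF --------------------------------------------------------------------

vcf_writer <- function(ds, out, individuals, gzip) {
  if (gzip && !grepl("\\.gz$", out)) out <- paste0(out, ".gz")
  con <- open_text_sink(out)
  header <- c("##fileformat=VCFv4.2",
              "##source=genofilter",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  for (f in ds$numeric_fields)
    header <- c(header, sprintf(
      "##FORMAT=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
      f, ds$field_types[[f]] %||% "Float", f))
  if (ds$annotation_source == "snpeff")
    header <- c(header, paste0(
      "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations:",
      " 'Allele | Annotation | Annotation_Impact | Gene_Name'\">"))
  if (ds$annotation_source == "vep")
    header <- c(header, paste0(
      "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence annotations.",
      " Format: Allele|Consequence|IMPACT|SYMBOL\">"))
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", individuals),
                            collapse = "\t"))
  writeLines(header, con)
  miss_gt <- if ((ds$ploidy %||% 2L) >= 2L) "./." else "."
  fmt <- paste(c("GT", ds$numeric_fields), collapse = ":")

  write <- function(batch) {
    m <- nrow(batch$variants)
    if (m == 0L) return()
    al <- alleles_of(batch$variants$alleles)
    ref <- vapply(al, `[`, "", 1L)
    alt <- vapply(al, function(a)
      if (length(a) > 1L) paste(a[-1], collapse = ",") else ".", "")
    info <- rep(".", m)
    if (!is.null(batch$ann) && ds$annotation_source != "none") {
      key <- if (ds$annotation_source == "snpeff") "ANN" else "CSQ"
      info <- vapply(batch$ann, function(a) {
        if (is.null(a) || nrow(a) == 0L) return(".")
        paste0(key, "=", paste(
          a$allele, a$effect, a$impact, a$gene_name, sep = "|", collapse = ","))
      }, "")
    }
    cells <- batch$gt
    cells[is.na(cells)] <- miss_gt
    for (f in ds$numeric_fields) {
      v <- batch$fields[[f]]
      if (is.null(v)) {
        fv <- matrix(".", nrow = m, ncol = ncol(cells))
      } else {
        fv <- if (identical(ds$field_types[[f]], "Integer"))
          matrix(as.character(as.integer(v)), nrow = m)
          else matrix(as.character(v), nrow = m)
        fv[is.na(v)] <- "."
      }
      cells <- matrix(paste(cells, fv, sep = ":"), nrow = m)
    }
    lines <- paste(batch$variants$sequence, batch$variants$position,
                   batch$variants$variant_id, ref, alt, ".", ".", info, fmt,
                   apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  list(write = write,
       finish = function() { close(con); out },
       skipped = function() 0L)
}

# --- PLINK PED/MAP ----------------------------------------------------------

plink_writer <- function(ds, out, individuals, gzip) {
  sfx <- if (gzip) ".gz" else ""
  ped_path <- paste0(out, ".ped", sfx)
  map_path <- paste0(out, ".map", sfx)
  map_lines <- character()
  # PED is row-per-individual, so genotype columns accumulate until finish
  ped_cols <- vector("list", 0)

  write <- function(batch) {
    m <- nrow(batch$variants)
    if (m == 0L) return()
    map_lines <<- c(map_lines, paste(batch$variants$sequence,
                                     batch$variants$variant_id, 0L,
                                     batch$variants$position, sep = "\t"))
    al <- alleles_of(batch$variants$alleles)
    cells <- matrix("0 0", nrow = m, ncol = length(individuals))
    gts <- gt_allele_indices(batch$gt)
    for (g in names(gts)) {
      w <- which(batch$gt == g)
      if (!length(w)) next
      i <- (w - 1L) %% m + 1L
      a <- gts[[g]]
      if (length(a) == 1L) a <- c(a, a)   # haploid written as homozygous pair
      cells[w] <- paste(vapply(seq_along(w), function(j) al[[i[j]]][a[1] + 1L], ""),
                        vapply(seq_along(w), function(j) al[[i[j]]][a[2] + 1L], ""))
    }
    ped_cols[[length(ped_cols) + 1L]] <<- cells
  }
  list(write = write,
       finish = function() {
         mcon <- open_text_sink(map_path)
         writeLines(map_lines, mcon); close(mcon)
         all_cells <- do.call(rbind, ped_cols)
         pcon <- open_text_sink(ped_path)
         lead <- paste(individuals, individuals, 0L, 0L, 0L, -9L, sep = "\t")
         lines <- if (is.null(all_cells) || nrow(all_cells) == 0L) lead
           else paste(lead, apply(all_cells, 2L, paste, collapse = "\t"),
                      sep = "\t")
         writeLines(lines, pcon); close(pcon)
         c(ped_path, map_path)
       },
       skipped = function() 0L)
}

# --- HapMap -----------------------------------------------------------------

hapmap_writer <- function(ds, out, individuals, gzip) {
  if (gzip && !grepl("\\.gz$", out)) out <- paste0(out, ".gz")
  con <- open_text_sink(out)
  writeLines(paste(c(HAPMAP_HEADER, individuals), collapse = "\t"), con)
  n_skipped <- 0L

  write <- function(batch) {
    snp <- batch$variants$variant_type == "SNP"
    n_skipped <<- n_skipped + sum(!snp)
    if (!any(snp)) return()
    v <- batch$variants[snp, , drop = FALSE]
    gt <- batch$gt[snp, , drop = FALSE]
    m <- nrow(v)
    al <- alleles_of(v$alleles)
    cells <- matrix("NN", nrow = m, ncol = length(individuals))
    gts <- gt_allele_indices(gt)
    for (g in names(gts)) {
      w <- which(gt == g)
      if (!length(w)) next
      i <- (w - 1L) %% m + 1L
      a <- gts[[g]]
      if (length(a) == 1L) a <- c(a, a)
      cells[w] <- paste0(vapply(seq_along(w), function(j) al[[i[j]]][a[1] + 1L], ""),
                         vapply(seq_along(w), function(j) al[[i[j]]][a[2] + 1L], ""))
    }
    lines <- paste(v$variant_id,
                   vapply(al, paste, "", collapse = "/"),
                   v$sequence, v$position, "+", "NA", "NA", "NA", "NA", "NA",
                   "NA",
                   apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  list(write = write,
       finish = function() {
         close(con)
         if (n_skipped > 0L)
           message(sprintf("HapMap export: %d non-SNP variant(s) skipped",
                           n_skipped))
         out
       },
       skipped = function() n_skipped)
}

# --- Flapjack .fjzip --------------------------------------------------------

flapjack_writer <- function(ds, out, individuals) {
  if (!grepl("\\.fjzip$", out)) out <- paste0(out, ".fjzip")
  marker_ids <- character()
  map_rows <- character()
  cell_blocks <- list()

  write <- function(batch) {
    m <- nrow(batch$variants)
    if (m == 0L) return()
    marker_ids <<- c(marker_ids, batch$variants$variant_id)
    map_rows <<- c(map_rows, paste(batch$variants$variant_id,
                                   batch$variants$sequence,
                                   batch$variants$position, sep = "\t"))
    al <- alleles_of(batch$variants$alleles)
    cells <- matrix("", nrow = m, ncol = length(individuals))
    gts <- gt_allele_indices(batch$gt)
    for (g in names(gts)) {
      w <- which(batch$gt == g)
      if (!length(w)) next
      i <- (w - 1L) %% m + 1L
      a <- gts[[g]]
      cells[w] <- vapply(seq_along(w), function(j)
        paste(al[[i[j]]][a + 1L], collapse = "/"), "")
    }
    cell_blocks[[length(cell_blocks) + 1L]] <<- cells
  }
  list(write = write,
       finish = function() {
         all_cells <- do.call(rbind, cell_blocks)
         geno <- c("# fjFile = GENOTYPE",
                   paste(c("", marker_ids), collapse = "\t"))
         if (!is.null(all_cells) && nrow(all_cells) > 0L)
           geno <- c(geno, paste(individuals,
                                 apply(all_cells, 2L, paste, collapse = "\t"),
                                 sep = "\t"))
         else geno <- c(geno, individuals)
         map <- c("# fjFile = MAP", map_rows)
         members <- list(geno, map)
         names(members) <- c(FJ_GENOTYPE_MEMBER, FJ_MAP_MEMBER)
         write_zip(out, members)
         out
       },
       skipped = function() 0L)
}
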