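#' Construct an import batch
#'
#' An import batch is the in-memory exchange format between the readers
#' ([read_vcf()], [read_plink()], [read_hapmap()]) and [gf_ingest()]: a
#' variant-level table plus genotype/field matrices in matching row order.
#'
#' @param variants data.frame with columns \code{variant_id}, \code{sequence},
#'   \code{position}, \code{variant_type}, \code{alleles} (comma-joined,
#'   reference first).
#' @param gt character matrix (variants x individuals) of canonical unphased
#'   genotype strings, \code{NA} = missing call.
#' @param individuals character vector of individual ids (column order of
#'   \code{gt}).
#' @param phased logical matrix like \code{gt} (informational), or NULL.
#' @param fields named list of numeric matrices (per-sample numeric FORMAT
#'   values), or empty list.
#' @param field_types named character vector (\code{"Integer"}/\code{"Float"})
#'   for the fields.
#' @param ann list (one element per variant) of annotation data.frames as
#'   returned by [parse_snpeff_ann()], or NULL.
#' @param annotation_source one of \code{"none"}, \code{"snpeff"}, \code{"vep"}.
#' @return object of class \code{gf_batch}.
#' @export
gf_batch <- function(variants, gt, individuals, phased = NULL,
                     fields = list(), field_types = character(),
                     ann = NULL, annotation_source = "none") {
  stopifnot(is.data.frame(variants), is.matrix(gt),
            nrow(gt) == nrow(variants), ncol(gt) == length(individuals))
  if (anyDuplicated(individuals))
    gf_validation_error("duplicate individual ids in batch")
  if (anyDuplicated(variants$variant_id))
    gf_validation_error("duplicate variant ids in batch")
  if (nrow(variants) > 0 && any(variants$position < 1L))
    gf_validation_error("positions must be >= 1 (1-based)")
  colnames(gt) <- individuals
  if (!is.null(phased)) colnames(phased) <- individuals
  for (f in names(fields)) colnames(fields[[f]]) <- individuals
  # variant-level annotation summaries feed the indexed fast path
  eff <- gen <- character(nrow(variants))
  if (!is.null(ann)) {
    eff <- vapply(ann, function(a) if (is.null(a) || nrow(a) == 0) ""
                  else paste(unique(a$effect), collapse = ";"), "")
    gen <- vapply(ann, function(a) if (is.null(a) || nrow(a) == 0) ""
                  else paste(unique(a$gene_name[a$gene_name != ""]), collapse = ";"), "")
  }
  variants$n_alleles <- lengths(strsplit(variants$alleles, ",", fixed = TRUE))
  variants$effects <- eff
  variants$genes <- gen
  structure(list(variants = variants, gt = gt, phased = phased,
                 fields = fields, field_types = field_types,
                 ann = ann, individuals = individuals,
                 numeric_fields = names(fields),
                 annotation_source = annotation_source),
            class = "gf_batch")
}

#' @export
print.gf_batch <- function(x, ...) {
  cat(sprintf("<gf_batch> %d variants x %d individuals; numeric fields: %s; annotations: %s\n",
              nrow(x$variants), length(x$individuals),
              if (length(x$numeric_fields)) paste(x$numeric_fields, collapse = ",") else "none",
              x$annotation_source))
  invisible(x)
}

#' Read a multi-sample VCF into an import batch
#'
#' Accepts VCF 4.x, plain or gzip-compressed, with GT in FORMAT. One variant
#' record is produced per data line (multi-allelic lines stay one record with
#' all ALT alleles). Missing calls (\code{./.} or \code{.}) produce no call.
#' Per-sample numeric FORMAT fields declared \code{Number=1,
#' Type=Integer|Float} are detected automatically and extracted. An INFO key
#' \code{ANN} triggers SnpEff annotation parsing, \code{CSQ} triggers VEP
#' parsing using the header's \code{Format:} declaration.
#'
#' @param path path to the VCF file.
#' @return a [gf_batch()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) gf_io_error(sprintf("no such file: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- v@meta
  fix <- v@fix
  m <- nrow(fix)
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L)
    gf_parse_error("VCF has no sample columns")
  individuals <- colnames(gt_raw)[-1]

  if (m > 0) {
    fmt_ok <- vapply(strsplit(gt_raw[, 1], ":", fixed = TRUE),
                     function(x) "GT" %in% x, logical(1))
    if (!all(fmt_ok))
      gf_error(sprintf("FORMAT lacks GT at record %d; genotype-less VCFs are unsupported",
                       which(!fmt_ok)[1]), "gf_unsupported_file_error")
    pos <- suppressWarnings(as.integer(fix[, "POS"]))
    if (anyNA(pos))
      gf_parse_error(sprintf("malformed POS at record %d", which(is.na(pos))[1]))
  } else {
    pos <- integer()
  }

  ref <- toupper(fix[, "REF"])
  alt <- fix[, "ALT"]
  alleles <- vapply(seq_len(m), function(i) {
    a <- ref[i]
    if (!is.na(alt[i]) && alt[i] != ".")
      a <- c(a, toupper(strsplit(alt[i], ",", fixed = TRUE)[[1]]))
    paste(a, collapse = ",")
  }, "")
  vid <- fix[, "ID"]
  auto <- is.na(vid) | vid == "."
  vid[auto] <- paste0(fix[auto, "CHROM"], ":", fix[auto, "POS"])

  if (m > 0) {
    norm <- normalize_gt(as.vector(vcfR::extract.gt(v)))
    gt <- matrix(norm$calls, nrow = m, dimnames = list(NULL, individuals))
    phased <- matrix(norm$phased, nrow = m, dimnames = list(NULL, individuals))
    n_all <- lengths(strsplit(alleles, ",", fixed = TRUE))
    idx <- gt_allele_indices(gt)
    for (g in names(idx)) {
      bad <- which(gt == g & max(idx[[g]]) >= n_all)
      if (length(bad))
        gf_parse_error(sprintf(
          "genotype '%s' at record %d indexes allele %d but only %d alleles are known",
          g, (bad[1] - 1L) %% m + 1L, max(idx[[g]]),
          n_all[(bad[1] - 1L) %% m + 1L]))
    }
  } else {
    gt <- matrix(character(), nrow = 0, ncol = length(individuals),
                 dimnames = list(NULL, individuals))
    phased <- matrix(logical(), nrow = 0, ncol = length(individuals))
  }

  # numeric per-sample FORMAT fields, detected from the header
  fmt_meta <- regmatches(meta, regexec(
    "^##FORMAT=<ID=([^,]+),Number=1,Type=(Integer|Float)", meta))
  fmt_meta <- Filter(function(x) length(x) == 3, fmt_meta)
  fields <- list(); field_types <- character()
  for (fm in fmt_meta) {
    if (fm[2] == "GT") next
    vals <- if (m > 0) suppressWarnings(
      vcfR::extract.gt(v, element = fm[2], as.numeric = TRUE))
      else matrix(numeric(), nrow = 0, ncol = length(individuals))
    fields[[fm[2]]] <- matrix(as.numeric(vals), nrow = m,
                              dimnames = list(NULL, individuals))
    field_types[fm[2]] <- fm[3]
  }

  ann <- NULL; annotation_source <- "none"
  if (any(grepl("^##INFO=<ID=ANN[,>]", meta))) {
    annotation_source <- "snpeff"
    vals <- if (m > 0) vcfR::extract.info(v, element = "ANN") else character()
    ann <- lapply(vals, function(x)
      if (is.na(x)) empty_annotations() else parse_snpeff_ann(x))
  } else if (any(grepl("^##INFO=<ID=CSQ[,>]", meta))) {
    annotation_source <- "vep"
    fmt <- csq_format_from_meta(meta)
    vals <- if (m > 0) vcfR::extract.info(v, element = "CSQ") else character()
    ann <- lapply(vals, function(x)
      if (is.na(x)) empty_annotations() else parse_vep_csq(x, fmt))
  }

  variants <- data.frame(
    variant_id = vid, sequence = fix[, "CHROM"], position = pos,
    variant_type = vapply(strsplit(alleles, ",", fixed = TRUE),
                          classify_variant_type, ""),
    alleles = alleles, stringsAsFactors = FALSE)
  gf_batch(variants, gt, individuals, phased = phased, fields = fields,
           field_types = field_types, ann = ann,
           annotation_source = annotation_source)
}

#' Read a PLINK PED/MAP flat-file pair
#'
#' The MAP file carries 4 columns (chromosome, marker id, genetic distance,
#' bp position); the PED file 6 leading columns then two allele columns per
#' marker. Individual ids are taken from PED column 2; \code{"0"} allele
#' codes mean a missing call. PLINK carries no REF designation, so the
#' reference allele is the alphabetically first observed allele (documented,
#' deterministic).
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return a [gf_batch()].
#' @export
read_plink <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character", "integer"))
  if (ncol(map) != 4L)
    gf_error(sprintf("MAP file must have 4 columns, found %d", ncol(map)),
             "gf_structure_error")
  m <- nrow(map)
  rows <- strsplit(trimws(readLines(ped_path)), "[ \t]+")
  rows <- rows[lengths(rows) > 0]
  n <- length(rows)
  expected <- 6L + 2L * m
  bad <- which(lengths(rows) != expected)
  if (length(bad))
    gf_error(sprintf(
      "PED row %d has %d fields; expected %d (6 + 2 x %d MAP markers)",
      bad[1], lengths(rows)[bad[1]], expected, m), "gf_structure_error")
  individuals <- vapply(rows, `[[`, "", 2L)

  gt <- matrix(NA_character_, nrow = m, ncol = n)
  alleles <- character(m)
  a1 <- vapply(rows, function(r) r[seq(7L, by = 2L, length.out = m)],
               character(m))
  a2 <- vapply(rows, function(r) r[seq(8L, by = 2L, length.out = m)],
               character(m))
  if (m == 1L) { a1 <- matrix(a1, nrow = 1); a2 <- matrix(a2, nrow = 1) }
  for (j in seq_len(m)) {
    x1 <- toupper(a1[j, ]); x2 <- toupper(a2[j, ])
    miss <- x1 == "0" | x2 == "0"
    obs <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(obs) == 0L) obs <- "N"
    alleles[j] <- paste(obs, collapse = ",")
    i1 <- match(x1, obs) - 1L; i2 <- match(x2, obs) - 1L
    gt[j, !miss] <- paste(pmin(i1, i2)[!miss], pmax(i1, i2)[!miss], sep = "/")
  }
  variants <- data.frame(
    variant_id = map[[2]], sequence = map[[1]], position = map[[4]],
    variant_type = vapply(strsplit(alleles, ",", fixed = TRUE),
                          classify_variant_type, ""),
    alleles = alleles, stringsAsFactors = FALSE)
  gf_batch(variants, gt, individuals)
}

HAPMAP_HEADER <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                   "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

#' Read a HapMap genotype table
#'
#' Tab-delimited, TASSEL-style dialect: 11 fixed header columns
#' (\code{rs#, alleles, chrom, pos, strand, assembly#, center, protLSID,
#' assayLSID, panelLSID, QCcode}) followed by one column per individual.
#' Diploid genotype cells are two IUPAC base letters (\code{"AT"});
#' \code{"NN"} is missing. The strand column is stored verbatim but never
#' applied.
#'
#' @param path path to the HapMap file.
#' @return a [gf_batch()].
#' @export
read_hapmap <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "",
                           colClasses = "character")
  if (ncol(tab) < 12L || !identical(names(tab)[1:11], HAPMAP_HEADER))
    gf_error(sprintf(
      "not a HapMap file: first 11 header columns must be '%s'",
      paste(HAPMAP_HEADER, collapse = ", ")), "gf_structure_error")
  m <- nrow(tab)
  individuals <- names(tab)[-(1:11)]
  gt <- matrix(NA_character_, nrow = m, ncol = length(individuals))
  alleles <- character(m)
  for (j in seq_len(m)) {
    declared <- toupper(strsplit(tab$alleles[j], "/", fixed = TRUE)[[1]])
    cells <- toupper(as.character(tab[j, -(1:11)]))
    letters1 <- substr(cells, 1L, 1L)
    letters2 <- substr(cells, 2L, 2L)
    letters2[letters2 == ""] <- letters1[letters2 == ""]  # haploid-style cell
    miss <- cells %in% c("NN", "N", "") | letters1 == "N" | letters2 == "N"
    obs <- unique(c(declared, sort(unique(c(letters1[!miss], letters2[!miss])))))
    obs <- obs[obs != "N" & obs != ""]
    if (length(obs) == 0L) obs <- "N"
    alleles[j] <- paste(obs, collapse = ",")
    i1 <- match(letters1, obs) - 1L; i2 <- match(letters2, obs) - 1L
    ok <- !miss & !is.na(i1) & !is.na(i2)
    gt[j, ok] <- paste(pmin(i1, i2)[ok], pmax(i1, i2)[ok], sep = "/")
  }
  pos <- suppressWarnings(as.integer(tab$pos))
  if (anyNA(pos))
    gf_error(sprintf("malformed pos at HapMap row %d", which(is.na(pos))[1]),
             "gf_structure_error")
  variants <- data.frame(
    variant_id = tab[["rs#"]], sequence = tab$chrom, position = pos,
    variant_type = vapply(strsplit(alleles, ",", fixed = TRUE),
                          classify_variant_type, ""),
    alleles = alleles, stringsAsFactors = FALSE)
  gf_batch(variants, gt, individuals)
}

#' Read an individual-metadata TSV
#'
#' First column holds individual ids; remaining header names are attribute
#' names, preserved verbatim. When \code{known_individuals} is given, rows
#' for unknown individuals are reported with a warning and skipped, not
#' fatal.
#'
#' @param path path to the tab-separated file (header row required).
#' @param known_individuals optional character vector of valid individual ids.
#' @return data.frame whose first column is \code{individual_id}.
#' @export
read_metadata_tsv <- function(path, known_individuals = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "",
                           colClasses = "character")
  if (ncol(tab) < 1L) gf_error("metadata file has no columns", "gf_structure_error")
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    gf_validation_error(sprintf("duplicate individual row in metadata: '%s'",
                                ids[duplicated(ids)][1]))
  names(tab)[1] <- "individual_id"
  if (!is.null(known_individuals)) {
    unknown <- setdiff(ids, known_individuals)
    if (length(unknown)) {
      warning(sprintf("metadata rows for %d unknown individual(s) skipped: %s",
                      length(unknown),
                      paste(utils::head(unknown, 5), collapse = ", ")))
      tab <- tab[ids %in% known_individuals, , drop = FALSE]
    }
  }
  rownames(tab) <- NULL
  tab
}
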