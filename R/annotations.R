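empty_annotations <- function() {
  data.frame(allele = character(), effect = character(),
             impact = character(), gene_name = character(),
             stringsAsFactors = FALSE)
}

# Split a comma-separated INFO value into entries, each entry into pipe
# subfields, preserving trailing empty subfields (strsplit drops them).
split_entries <- function(value) strsplit(value, ",", fixed = TRUE)[[1]]

split_subfields <- function(entry) {
  n_sep <- lengths(gregexpr("|", entry, fixed = TRUE))
  if (entry == "" || !grepl("|", entry, fixed = TRUE)) n_sep <- 0L
  sp <- strsplit(entry, "|", fixed = TRUE)[[1]]
  length(sp) <- n_sep + 1L
  sp[is.na(sp)] <- ""
  sp
}

#' Parse a SnpEff ANN INFO value into functional annotations
#'
#' SnpEff writes one pipe-delimited entry per (allele, feature) pair,
#' comma-separated, with fixed leading subfields
#' \code{Allele|Annotation|Annotation_Impact|Gene_Name|...}. Effects joined
#' with \code{"&"} (e.g. \code{stop_gained&splice_region_variant}) are split
#' into one annotation row per consequence term.
#'
#' @param ann_value the raw ANN value (without the \code{ANN=} key).
#' @return data.frame with columns \code{allele}, \code{effect},
#'   \code{impact}, \code{gene_name}; one row per consequence term.
#' @export
parse_snpeff_ann <- function(ann_value) {
  if (is.na(ann_value) || ann_value == "") return(empty_annotations())
  rows <- lapply(split_entries(ann_value), function(entry) {
    sp <- split_subfields(entry)
    if (length(sp) < 4L)
      gf_parse_error(sprintf(
        "SnpEff ANN entry has %d subfields, need at least 4 (Allele|Annotation|Annotation_Impact|Gene_Name): '%s'",
        length(sp), entry))
    effects <- strsplit(sp[2], "&", fixed = TRUE)[[1]]
    if (length(effects) == 0L || all(effects == ""))
      gf_parse_error(sprintf("SnpEff ANN entry has empty Annotation subfield: '%s'", entry))
    data.frame(allele = sp[1], effect = effects, impact = sp[3],
               gene_name = sp[4], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Parse a VEP CSQ INFO value into functional annotations
#'
#' VEP declares its subfield layout in the VCF header
#' (\code{Description="... Format: Allele|Consequence|..."}); entries are
#' comma-separated. Subfields are mapped by name: \code{Allele},
#' \code{Consequence} (split on \code{"&"}), \code{IMPACT} when present, and
#' \code{SYMBOL} (falling back to \code{Gene}) for the gene name.
#'
#' @param csq_value the raw CSQ value (without the \code{CSQ=} key).
#' @param csq_format character vector of subfield names from the header.
#' @return data.frame as for [parse_snpeff_ann()].
#' @export
parse_vep_csq <- function(csq_value, csq_format) {
  if (is.na(csq_value) || csq_value == "") return(empty_annotations())
  if (!"Consequence" %in% csq_format)
    gf_parse_error("CSQ format declaration lacks a 'Consequence' subfield")
  gene_col <- if ("SYMBOL" %in% csq_format) "SYMBOL"
              else if ("Gene" %in% csq_format) "Gene" else NA_character_
  rows <- lapply(split_entries(csq_value), function(entry) {
    sp <- split_subfields(entry)
    if (length(sp) != length(csq_format))
      gf_parse_error(sprintf(
        "CSQ entry has %d subfields but the header declares %d: '%s'",
        length(sp), length(csq_format), entry))
    names(sp) <- csq_format
    effects <- strsplit(sp[["Consequence"]], "&", fixed = TRUE)[[1]]
    data.frame(
      allele = if ("Allele" %in% csq_format) sp[["Allele"]] else "",
      effect = effects,
      impact = if ("IMPACT" %in% csq_format) sp[["IMPACT"]] else "",
      gene_name = if (!is.na(gene_col)) sp[[gene_col]] else "",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Extract the CSQ "Format: a|b|c" declaration from VCF meta lines.
csq_format_from_meta <- function(meta) {
  line <- grep("^##INFO=<ID=CSQ", meta, value = TRUE)
  if (length(line) == 0L) return(NULL)
  m <- regmatches(line[1], regexpr("Format: ?[A-Za-z0-9_|]+", line[1]))
  if (length(m) == 0L)
    gf_parse_error("CSQ INFO header lacks a 'Format: ...' declaration")
  strsplit(sub("^Format: ?", "", m), "|", fixed = TRUE)[[1]]
}
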