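#' Normalize raw genotype strings to canonical unphased form
#'
#' Genotype equality throughout the package is unphased: a call is the
#' multiset of allele indices, stored sorted ascending and joined with "/"
#' (e.g. \code{"1|0"} and \code{"0/1"} both normalize to \code{"0/1"};
#' haploid calls keep a single index). Any call containing a missing allele
#' (\code{"."}) normalizes to \code{NA}.
#'
#' @param gt character vector of raw GT strings (\code{"0/1"}, \code{"1|0"},
#'   \code{"0"}, \code{"./."}, ...); \code{NA} passes through.
#' @return list with \code{calls} (canonical character, \code{NA} = missing)
#'   and \code{phased} (logical, \code{TRUE} where the raw string used
#'   \code{"|"}; informational only).
#' @export
normalize_gt <- function(gt) {
  ux <- unique(gt)
  ux <- ux[!is.na(ux)]
  canon <- rep(NA_character_, length(ux))
  phased <- logical(length(ux))
  for (i in seq_along(ux)) {
    parts <- strsplit(ux[i], "[/|]")[[1]]
    phased[i] <- grepl("|", ux[i], fixed = TRUE)
    if (length(parts) == 0L || any(parts == ".") || any(parts == "")) next
    idx <- suppressWarnings(as.integer(parts))
    if (anyNA(idx)) gf_parse_error(sprintf("malformed genotype string '%s'", ux[i]))
    canon[i] <- paste(sort(idx), collapse = "/")
  }
  m <- match(gt, ux)
  list(calls = canon[m], phased = ifelse(is.na(m), FALSE, phased[m]))
}

# Parse canonical genotype strings into integer allele-index vectors.
# Memoized over the unique strings, which are few per chunk.
gt_allele_indices <- function(calls) {
  ux <- unique(calls[!is.na(calls)])
  parsed <- lapply(strsplit(ux, "/", fixed = TRUE), as.integer)
  names(parsed) <- ux
  parsed
}

# Compare two allele-index multisets (sorted integer vectors) for the
# deterministic major-genotype tie-break: elementwise, then shorter first.
gt_multiset_lt <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Classify a variant from its known alleles
#'
#' Pure function of the allele set: all alleles of length 1 are a SNP; all
#' alleles of equal length > 1 an MNP; differing lengths (or a spanning
#' deletion \code{"*"}) an INDEL; symbolic alleles (\code{"<DEL>"}, breakend
#' notation) OTHER.
#'
#' @param known_alleles character vector of allele strings, reference first.
#' @return one of \code{"SNP"}, \code{"INDEL"}, \code{"MNP"}, \code{"OTHER"}.
#' @export
classify_variant_type <- function(known_alleles) {
  if (length(known_alleles) == 0L) gf_validation_error("empty allele list")
  if (any(known_alleles == "*")) return("INDEL")
  if (any(grepl("[^ACGTN]", known_alleles))) return("OTHER")  # symbolic/breakend
  len <- nchar(known_alleles)
  if (all(len == 1L)) return("SNP")
  if (length(unique(len)) == 1L) return("MNP")
  "INDEL"
}
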