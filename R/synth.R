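#' Describe a planted group-discriminating variant
#'
#' A planted variant carries a distinct signature genotype in each of two
#' disjoint individual groups: a \code{purity} fraction of each group gets
#' its group's signature, the remainder get the opposite group's signature,
#' and individuals outside both groups draw a random genotype. Group members
#' are never set missing at a planted variant, so a variant planted with
#' purity 1.0 passes a discrimination query at similarity ratio 1.0 and
#' maximum missing ratio 0 by construction.
#'
#' @param sequence,position placement of the variant.
#' @param group1_ids,group2_ids disjoint individual id vectors.
#' @param signature1,signature2 distinct canonical genotypes (unphased).
#' @param purity1,purity2 fraction of each group carrying its signature.
#' @return a \code{gf_planted} list.
#' @export
synth_plant <- function(sequence, position, group1_ids, group2_ids,
                        signature1 = "0/0", signature2 = "1/1",
                        purity1 = 1.0, purity2 = 1.0) {
  if (length(intersect(group1_ids, group2_ids)))
    gf_validation_error("planted groups must be disjoint")
  norm <- function(g) normalize_gt(g)$calls
  if (norm(signature1) == norm(signature2))
    gf_validation_error("signature genotypes must differ (unphased comparison)")
  structure(list(sequence = sequence, position = as.integer(position),
                 group1_ids = group1_ids, group2_ids = group2_ids,
                 signature1 = norm(signature1), signature2 = norm(signature2),
                 purity1 = purity1, purity2 = purity2),
            class = "gf_planted")
}

#' Specification for a synthetic multi-sample diploid VCF
#'
#' Generation is a pure function of the spec: the same seed yields a
#' byte-identical file. Neutral variants are biallelic SNPs with an allele
#' frequency drawn per variant from \code{allele_freq} (a fixed value or a
#' uniform range), genotypes drawn under Hardy-Weinberg proportions shared by
#' all individuals (so no neutral variant systematically separates groups),
#' missing calls at \code{missing_rate}, and per-sample DP/GQ integers drawn
#' uniformly from their ranges. A fraction \code{annotation_rate} of variants
#' gets a SnpEff-style ANN entry.
#'
#' @param n_individuals,n_variants dataset dimensions.
#' @param sequences named numeric vector, sequence name -> length in bp.
#' @param allele_freq single frequency or range c(lo, hi) in [0.01, 0.5].
#' @param missing_rate per-call missing probability in [0, 1].
#' @param dp_range,gq_range integer ranges for the DP and GQ fields.
#' @param annotation_rate fraction of variants annotated.
#' @param planted list of [synth_plant()] descriptions.
#' @param seed integer RNG seed.
#' @return a \code{gf_synth_spec}.
#' @export
synth_spec <- function(n_individuals = 50L, n_variants = 1000L,
                       sequences = c(chr1 = 5e6, chr2 = 5e6),
                       allele_freq = c(0.05, 0.5), missing_rate = 0.05,
                       dp_range = c(2L, 60L), gq_range = c(10L, 99L),
                       annotation_rate = 0.3, planted = list(), seed = 1L) {
  for (r in list(missing_rate, annotation_rate))
    if (r < 0 || r > 1) gf_validation_error("rates must be in [0, 1]")
  if (length(allele_freq) == 1L) allele_freq <- rep(allele_freq, 2L)
  for (p in planted) {
    if (!p$sequence %in% names(sequences))
      gf_validation_error(sprintf("planted variant on unknown sequence '%s'",
                                  p$sequence))
    if (p$position < 1L || p$position > sequences[[p$sequence]])
      gf_validation_error(sprintf(
        "planted position %d outside sequence '%s' (length %d)",
        p$position, p$sequence, as.integer(sequences[[p$sequence]])))
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_variants = as.integer(n_variants),
                 sequences = sequences, allele_freq = allele_freq,
                 missing_rate = missing_rate,
                 dp_range = as.integer(dp_range),
                 gq_range = as.integer(gq_range),
                 annotation_rate = annotation_rate,
                 planted = planted, seed = as.integer(seed)),
            class = "gf_synth_spec")
}

#' Individual ids of a synthetic spec
#' @param spec a [synth_spec()].
#' @return character vector \code{ind001 ...}.
#' @export
synth_individuals <- function(spec)
  sprintf("ind%03d", seq_len(spec$n_individuals))

SYNTH_EFFECTS <- c("missense_variant", "synonymous_variant", "intron_variant",
                   "stop_gained", "upstream_gene_variant")
SYNTH_IMPACTS <- c(missense_variant = "MODERATE", synonymous_variant = "LOW",
                   intron_variant = "MODIFIER", stop_gained = "HIGH",
                   upstream_gene_variant = "MODIFIER")

#' Generate a synthetic VCF with its truth table
#'
#' Writes \code{<prefix>.vcf}, a truth table \code{<prefix>.truth.tsv} with
#' the realized (not nominal) per-variant minor allele frequency, missing
#' count and planted flag, and — when planted variants define groups — a
#' metadata file \code{<prefix>.metadata.tsv} assigning a \code{group}
#' attribute.
#'
#' @param spec a [synth_spec()].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return list of written paths (\code{vcf}, \code{truth}, \code{metadata}).
#' @export
synth_generate <- function(spec, dir = ".", prefix = "synth") {
  stopifnot(inherits(spec, "gf_synth_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inds <- synth_individuals(spec)
  n <- spec$n_individuals
  m <- spec$n_variants
  with_seed(spec$seed, {
    # placement: variants spread over sequences proportionally to length,
    # planted variants at their stated coordinates
    seq_names <- names(spec$sequences)
    n_planted <- length(spec$planted)
    if (n_planted > m) gf_validation_error("more planted variants than variants")
    m_neutral <- m - n_planted
    probs <- spec$sequences / sum(spec$sequences)
    vseq <- sample(seq_names, m_neutral, replace = TRUE, prob = probs)
    vpos <- vapply(vseq, function(s)
      sample.int(as.integer(spec$sequences[[s]]), 1L), 1L)
    vseq <- c(vseq, vapply(spec$planted, `[[`, "", "sequence"))
    vpos <- c(vpos, vapply(spec$planted, `[[`, 1L, "position"))
    planted_flag <- c(rep(FALSE, m_neutral), rep(TRUE, n_planted))
    ord <- order(match(vseq, seq_names), vpos, planted_flag)
    vseq <- vseq[ord]; vpos <- vpos[ord]; planted_flag <- planted_flag[ord]
    plant_of <- integer(m)
    plant_of[planted_flag] <- order(
      match(vapply(spec$planted, `[[`, "", "sequence"), seq_names),
      vapply(spec$planted, `[[`, 1L, "position"))

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(seq_len(m), function(i)
      sample(setdiff(bases, ref[i]), 1L), "")

    gt <- matrix(NA_character_, nrow = m, ncol = n)
    freq <- stats::runif(m, spec$allele_freq[1], spec$allele_freq[2])
    for (i in seq_len(m)) {
      if (planted_flag[i]) {
        p <- spec$planted[[plant_of[i]]]
        row <- character(n)
        draw_group <- function(ids, sig, other, purity) {
          k <- length(ids)
          n_sig <- round(purity * k)
          carriers <- sample(ids, n_sig)
          row[match(ids, inds)] <<- other
          row[match(carriers, inds)] <<- sig
        }
        outside <- setdiff(inds, c(p$group1_ids, p$group2_ids))
        row[match(outside, inds)] <- sample(c(p$signature1, p$signature2, "0/1"),
                                            length(outside), replace = TRUE)
        draw_group(p$group1_ids, p$signature1, p$signature2, p$purity1)
        draw_group(p$group2_ids, p$signature2, p$signature1, p$purity2)
        # missingness only outside the groups, preserving nominal purity
        if (spec$missing_rate > 0 && length(outside)) {
          drop <- outside[stats::runif(length(outside)) < spec$missing_rate]
          row[match(drop, inds)] <- NA_character_
        }
        gt[i, ] <- row
      } else {
        q <- freq[i]   # ALT allele frequency, shared by all individuals
        g <- sample(c("0/0", "0/1", "1/1"), n, replace = TRUE,
                    prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
        if (spec$missing_rate > 0)
          g[stats::runif(n) < spec$missing_rate] <- NA_character_
        gt[i, ] <- g
      }
    }

    dp <- matrix(sample(seq(spec$dp_range[1], spec$dp_range[2]), m * n,
                        replace = TRUE), nrow = m)
    gq <- matrix(sample(seq(spec$gq_range[1], spec$gq_range[2]), m * n,
                        replace = TRUE), nrow = m)
    annotated <- stats::runif(m) < spec$annotation_rate
    ann_effect <- sample(SYNTH_EFFECTS, m, replace = TRUE)
    ann_gene <- sprintf("GENE%03d", sample.int(40L, m, replace = TRUE))

    vid <- sprintf("v%05d", seq_len(m))
    info <- rep(".", m)
    info[annotated] <- paste0("ANN=", alt[annotated], "|",
                              ann_effect[annotated], "|",
                              SYNTH_IMPACTS[ann_effect[annotated]], "|",
                              ann_gene[annotated])
    cells <- gt
    cells[is.na(cells)] <- "./."
    cells <- matrix(paste(cells, dp, gq, sep = ":"), nrow = m)

    header <- c("##fileformat=VCFv4.2",
                "##source=genofilter-synth",
                sprintf("##contig=<ID=%s,length=%d>", seq_names,
                        as.integer(spec$sequences)),
                "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name'\">",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
                "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", inds), collapse = "\t"))
    body <- paste(vseq, vpos, vid, ref, alt, ".", ".", info, "GT:DP:GQ",
                  apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
    vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
    writeLines(c(header, body), vcf_path)

    # truth from the realized genotype matrix, not from the generating law
    alt_count <- rowSums(matrix(
      vapply(gt, function(g) if (is.na(g)) 0L
             else sum(as.integer(strsplit(g, "/", fixed = TRUE)[[1]])), 1L),
      nrow = m), na.rm = TRUE)
    n_missing <- rowSums(is.na(gt))
    called2 <- 2L * (n - n_missing)
    p_alt <- ifelse(called2 > 0, alt_count / called2, NA_real_)
    truth <- data.frame(variant_id = vid, sequence = vseq, position = vpos,
                        maf = pmin(p_alt, 1 - p_alt), n_missing = n_missing,
                        planted = planted_flag)
    truth_path <- file.path(dir, paste0(prefix, ".truth.tsv"))
    utils::write.table(truth, truth_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)

    md_path <- NULL
    if (n_planted > 0L) {
      p1 <- spec$planted[[1]]
      group <- rep("none", n)
      group[match(p1$group1_ids, inds)] <- "group1"
      group[match(p1$group2_ids, inds)] <- "group2"
      md <- data.frame(individual_id = inds, group = group)
      md_path <- file.path(dir, paste0(prefix, ".metadata.tsv"))
      utils::write.table(md, md_path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    }
    list(vcf = vcf_path, truth = truth_path, metadata = md_path)
  })
}

#' Recovery check for planted discriminating variants
#'
#' Imports nothing itself: runs the discrimination query against an already
#' ingested dataset at each requested similarity ratio and compares the
#' matches with the planted set from the truth table.
#'
#' @param ds a \code{gf_dataset} holding the generated data.
#' @param truth the truth table data.frame (from the generator's
#'   \code{.truth.tsv}).
#' @param group1,group2 individual id vectors (e.g. from the generated
#'   metadata).
#' @param ratios similarity ratios to sweep.
#' @param max_missing_ratio missing-data ceiling for both groups.
#' @return list with \code{sweep} (data.frame ratio/n_matches), and at the
#'   last ratio: \code{matches}, \code{recovered}, \code{missed},
#'   \code{extra}.
#' @export
plant_recovery_check <- function(ds, truth, group1, group2,
                                 ratios = c(1.0), max_missing_ratio = 0) {
  planted_ids <- truth$variant_id[truth$planted]
  n_matches <- integer(length(ratios))
  matches <- character()
  for (i in seq_along(ratios)) {
    q <- gf_query(
      group1 = gf_group_filter(group1, pattern = "ALL_OR_MOSTLY_SAME",
                               similarity_ratio = ratios[i],
                               max_missing_ratio = max_missing_ratio),
      group2 = gf_group_filter(group2, pattern = "ALL_OR_MOSTLY_SAME",
                               similarity_ratio = ratios[i],
                               max_missing_ratio = max_missing_ratio),
      discriminate = TRUE)
    res <- execute_query(ds, q, mode = "find")
    n_matches[i] <- res$total_count
    matches <- res$variant_ids
  }
  list(sweep = data.frame(ratio = ratios, n_matches = n_matches),
       matches = matches,
       recovered = intersect(matches, planted_ids),
       missed = setdiff(planted_ids, matches),
       extra = setdiff(matches, planted_ids))
}
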