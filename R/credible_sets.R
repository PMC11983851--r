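# Cross-trait credible-set comparison and cell-lineage attribution.
# A credible set here is represented as a data.frame with columns
# snp_id, chrom, pos, pip (one row per member), plus identifying metadata.

#' Classify a pair of credible sets as shared or trait-specific
#'
#' Two credible sets from the same LD block are called shared if they share
#' more than half of their SNPs (relative to either set's own size, strict
#' majority), or if the total PIP of the shared SNPs exceeds 50% of the
#' total PIP of either credible set (evaluated within each trait's own
#' PIPs). Otherwise each set is trait-specific.
#'
#' @param csA Data.frame for the first trait's set: `snp_id`, `pip`.
#' @param csB Data.frame for the second trait's set: `snp_id`, `pip`.
#' @param block_a,block_b Block ids of the two sets (must match).
#' @return list of class `sharing_call`: `status` ("shared" or "specific"),
#'   `overlap_n`, `overlap_frac_a`, `overlap_frac_b`, `shared_pip_frac_a`,
#'   `shared_pip_frac_b`.
#' @export
classify_sharing <- function(csA, csB, block_a = NULL, block_b = NULL) {
  if (!is.null(block_a) && !is.null(block_b) && block_a != block_b) {
    stop("credible sets are from different LD blocks: ", block_a, " vs ",
         block_b)
  }
  shared_ids <- intersect(csA$snp_id, csB$snp_id)
  frac_a <- length(shared_ids) / nrow(csA)
  frac_b <- length(shared_ids) / nrow(csB)
  pip_frac_a <- sum(csA$pip[csA$snp_id %in% shared_ids]) / sum(csA$pip)
  pip_frac_b <- sum(csB$pip[csB$snp_id %in% shared_ids]) / sum(csB$pip)
  shared <- frac_a > 0.5 || frac_b > 0.5 ||
    pip_frac_a > 0.5 || pip_frac_b > 0.5
  structure(list(status = if (shared) "shared" else "specific",
                 overlap_n = length(shared_ids),
                 overlap_frac_a = frac_a, overlap_frac_b = frac_b,
                 shared_pip_frac_a = pip_frac_a,
                 shared_pip_frac_b = pip_frac_b),
            class = "sharing_call")
}

#' Compare all credible sets of two traits
#'
#' Evaluates [classify_sharing()] for every within-block pair of credible
#' sets across two traits and labels every credible set as shared or
#' trait-specific (a set shared with none is specific to its trait).
#'
#' @param cs_snps_a,cs_snps_b Long credible-set tables (as produced by
#'   [finemap_blocks()]): columns `block_id`, `cs`, `snp_id`, `pip`.
#' @param trait_a,trait_b Trait labels (default "A", "B").
#' @return data.frame of pairwise calls (`block_id`, `cs_a`, `cs_b`,
#'   `status`, overlap and PIP-fraction columns) with attribute
#'   `set_status`, a data.frame labeling each individual credible set.
#' @export
sharing_calls <- function(cs_snps_a, cs_snps_b, trait_a = "A", trait_b = "B") {
  pair_rows <- list()
  split_a <- split(cs_snps_a, cs_snps_a$cs)
  split_b <- split(cs_snps_b, cs_snps_b$cs)
  for (ca in split_a) {
    for (cb in split_b) {
      if (ca$block_id[1L] != cb$block_id[1L]) next
      call <- classify_sharing(ca, cb)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        block_id = ca$block_id[1L], cs_a = ca$cs[1L], cs_b = cb$cs[1L],
        status = call$status, overlap_n = call$overlap_n,
        overlap_frac_a = call$overlap_frac_a,
        overlap_frac_b = call$overlap_frac_b,
        shared_pip_frac_a = call$shared_pip_frac_a,
        shared_pip_frac_b = call$shared_pip_frac_b, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(block_id = character(), cs_a = character(),
               cs_b = character(), status = character(),
               overlap_n = integer(), overlap_frac_a = numeric(),
               overlap_frac_b = numeric(), shared_pip_frac_a = numeric(),
               shared_pip_frac_b = numeric(), stringsAsFactors = FALSE)
  shared_a <- unique(pairs$cs_a[pairs$status == "shared"])
  shared_b <- unique(pairs$cs_b[pairs$status == "shared"])
  set_status <- rbind(
    data.frame(trait = trait_a, cs = names(split_a),
               status = ifelse(names(split_a) %in% shared_a, "shared",
                               paste0(trait_a, "-specific")),
               stringsAsFactors = FALSE),
    data.frame(trait = trait_b, cs = names(split_b),
               status = ifelse(names(split_b) %in% shared_b, "shared",
                               paste0(trait_b, "-specific")),
               stringsAsFactors = FALSE))
  attr(pairs, "set_status") <- set_status
  pairs
}

#' Summarize sharing between two traits
#'
#' Counts shared and trait-specific credible sets. Two accountings are
#' reported: unit-based, where a shared pair contributes one shared unit
#' occupying two of the set slots (fraction = shared pairs /
#' (total sets - shared pairs)), and set-based, where the fraction is the
#' proportion of individual credible sets involved in any shared pair.
#'
#' @param calls Output of [sharing_calls()].
#' @return list with `n_sets_a`, `n_sets_b`, `n_shared_pairs`,
#'   `n_shared_sets`, `fraction_shared_units`, `fraction_shared_sets`,
#'   `set_status`.
#' @export
summarize_sharing <- function(calls) {
  set_status <- attr(calls, "set_status")
  traits <- unique(set_status$trait)
  n_a <- sum(set_status$trait == traits[1L])
  n_b <- if (length(traits) > 1L) sum(set_status$trait == traits[2L]) else 0L
  shared_pairs <- calls[calls$status == "shared", , drop = FALSE]
  n_pairs <- nrow(shared_pairs)
  n_shared_sets <- sum(set_status$status == "shared")
  total <- n_a + n_b
  list(n_sets_a = n_a, n_sets_b = n_b, n_shared_pairs = n_pairs,
       n_shared_sets = n_shared_sets,
       fraction_shared_units = if (total - n_pairs > 0)
         n_pairs / (total - n_pairs) else NA_real_,
       fraction_shared_sets = if (total > 0) n_shared_sets / total
       else NA_real_,
       set_status = set_status)
}

#' Attribute a credible set's PIP mass to cell lineages
#'
#' Each member SNP's PIP is assigned to the lineages whose open-chromatin
#' regions contain it; a SNP overlapping OCRs of m >= 1 lineages contributes
#' PIP/m to each, and a SNP in no OCR contributes to the "none" category.
#' Proportions are lineage totals over the set's total PIP.
#'
#' @param cs Data.frame of members: `chrom`, `pos` (1-based), `pip`.
#' @param peaks Data.frame of OCRs: `chrom`, `start`, `end` (BED
#'   coordinates), `lineage`.
#' @param lineages Lineage universe (default: those present in `peaks`).
#' @return Named numeric vector of proportions over `lineages` plus
#'   `"none"`; sums to 1.
#' @export
attribute_lineages <- function(cs, peaks, lineages = NULL) {
  if (nrow(cs) == 0L) stop("empty credible set")
  if (is.null(lineages)) lineages <- sort(unique(peaks$lineage))
  totals <- setNames(rep(0, length(lineages) + 1L), c(lineages, "none"))
  if (nrow(peaks) > 0L) {
    hits <- GenomicRanges::findOverlaps(snp_granges(cs$chrom, cs$pos),
                                        bed_granges(peaks))
    hit_df <- unique(data.frame(snp = S4Vectors::queryHits(hits),
                                lineage = peaks$lineage[S4Vectors::subjectHits(hits)]))
  } else {
    hit_df <- data.frame(snp = integer(), lineage = character())
  }
  for (i in seq_len(nrow(cs))) {
    lin_i <- unique(hit_df$lineage[hit_df$snp == i])
    if (length(lin_i) == 0L) {
      totals["none"] <- totals["none"] + cs$pip[i]
    } else {
      totals[lin_i] <- totals[lin_i] + cs$pip[i] / length(lin_i)
    }
  }
  totals / sum(cs$pip)
}

#' Bin PIPs into confidence categories
#'
#' Low confidence: 0.1 < PIP <= 0.5; mid: 0.5 < PIP <= 0.8; high:
#' PIP > 0.8. PIPs at or below 0.1 are not counted.
#'
#' @param pips Numeric vector of PIPs in `[0, 1]`.
#' @return Named integer vector `c(low, mid, high)`.
#' @export
confidence_bins <- function(pips) {
  stopifnot(all(pips >= 0 & pips <= 1))
  c(low = sum(pips > 0.1 & pips <= 0.5),
    mid = sum(pips > 0.5 & pips <= 0.8),
    high = sum(pips > 0.8))
}

#' Percent change in confidence bins between prior modes
#'
#' `(functional - uniform) / uniform * 100` per bin; `NA` where the uniform
#' count is zero.
#'
#' @param bins_functional,bins_uniform Outputs of [confidence_bins()] on the
#'   same SNP universe.
#' @return Named numeric vector of percent changes.
#' @export
compare_prior_modes <- function(bins_functional, bins_uniform) {
  stopifnot(identical(names(bins_functional), names(bins_uniform)))
  out <- ifelse(bins_uniform == 0, NA_real_,
                (bins_functional - bins_uniform) / bins_uniform * 100)
  setNames(as.numeric(out), names(bins_functional))
}
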