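# Candidate cis-regulatory elements: per-cell-type ATAC-seq peaks are merged
# into a disjoint catalog (bedtools `merge -d -1` semantics: intervals merge
# iff they overlap by >= 1 bp; bookended intervals stay separate), and each
# element is scored per trait by its ePIP — the sum of the PIPs of the
# credible-set SNPs it contains.

#' Merge per-cell-type peaks into candidate CREs
#'
#' Merges open-chromatin peaks across cell types into non-overlapping
#' elements. Intervals are merged iff they overlap by at least 1 bp;
#' bookended (abutting) intervals are not merged, matching
#' `bedtools merge -d -1`. Each element records the union of contributing
#' cell types and lineages; output is sorted by chrom and start and is
#' invariant to the order peak files are supplied.
#'
#' @param peaks Data.frame with `chrom`, `start`, `end` (BED coordinates),
#'   `cell_type`, `lineage`.
#' @return Data.frame: `cre_id`, `chrom`, `start`, `end`, `cell_types`,
#'   `lineages` (comma-joined, sorted unique), `n_lineages`.
#' @export
merge_peaks <- function(peaks) {
  stopifnot(all(c("chrom", "start", "end", "cell_type", "lineage") %in%
                  names(peaks)))
  if (nrow(peaks) == 0L) {
    return(data.frame(cre_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      cell_types = character(), lineages = character(),
                      n_lineages = integer(), stringsAsFactors = FALSE))
  }
  gr <- bed_granges(peaks)
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  merged <- GenomicRanges::sort(merged)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  q <- S4Vectors::queryHits(hits)
  cell_types <- vapply(split(peaks$cell_type[S4Vectors::subjectHits(hits)], q),
                       function(x) paste(sort(unique(x)), collapse = ","),
                       character(1))
  lineages <- vapply(split(peaks$lineage[S4Vectors::subjectHits(hits)], q),
                     function(x) paste(sort(unique(x)), collapse = ","),
                     character(1))
  n_lin <- vapply(strsplit(lineages, ",", fixed = TRUE), length, integer(1))
  data.frame(cre_id = paste0("cre", seq_along(merged)),
             chrom = as.character(GenomicRanges::seqnames(merged)),
             start = GenomicRanges::start(merged) - 1L,
             end = GenomicRanges::end(merged),
             cell_types = unname(cell_types), lineages = unname(lineages),
             n_lineages = unname(n_lin), stringsAsFactors = FALSE)
}

#' Compute per-trait element PIPs (ePIPs)
#'
#' The ePIP of a candidate CRE for a trait is the sum of the PIPs of the
#' trait's credible-set SNPs falling inside the element; SNPs outside any
#' credible set contribute nothing. Because the catalog is disjoint, a SNP
#' can fall in at most one element (asserted). Elements with ePIP 0 are
#' retained in the catalog; filter with [candidate_cres()] for reporting.
#'
#' @param cres CRE catalog from [merge_peaks()].
#' @param cs_snps Named list of long credible-set tables (one per trait,
#'   as from [finemap_blocks()]; columns `chrom`, `pos`, `pip`, `snp_id`),
#'   or a single table for one trait.
#' @return `cres` with, per trait `T`, columns `epip_T` and `top_snp_T`
#'   (credible-set SNP with the highest PIP inside the element).
#' @export
compute_epip <- function(cres, cs_snps) {
  if (is.data.frame(cs_snps)) cs_snps <- list(trait = cs_snps)
  cre_gr <- bed_granges(cres)
  if (length(cre_gr) > 1L) {
    ov <- GenomicRanges::findOverlaps(cre_gr, cre_gr)
    stopifnot(sum(S4Vectors::queryHits(ov) != S4Vectors::subjectHits(ov)) == 0L)
  }
  for (trait in names(cs_snps)) {
    cs <- cs_snps[[trait]]
    epip <- rep(0, nrow(cres))
    top_snp <- rep(NA_character_, nrow(cres))
    if (nrow(cs) > 0L) {
      hits <- GenomicRanges::findOverlaps(snp_granges(cs$chrom, cs$pos),
                                          cre_gr)
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      stopifnot(!anyDuplicated(q))      # disjoint catalog: <= 1 CRE per SNP
      for (j in unique(s)) {
        members <- q[s == j]
        epip[j] <- sum(cs$pip[members])
        top_snp[j] <- cs$snp_id[members[which.max(cs$pip[members])]]
      }
    }
    cres[[paste0("epip_", trait)]] <- epip
    cres[[paste0("top_snp_", trait)]] <- top_snp
  }
  cres
}

#' Filter the catalog to candidate CREs (nonzero ePIP in any trait)
#' @param cres_epip Output of [compute_epip()].
#' @return Subset of rows with ePIP > 0 for at least one trait.
#' @export
candidate_cres <- function(cres_epip) {
  epip_cols <- grep("^epip_", names(cres_epip), value = TRUE)
  stopifnot(length(epip_cols) > 0L)
  keep <- rowSums(as.matrix(cres_epip[, epip_cols, drop = FALSE])) > 0
  cres_epip[keep, , drop = FALSE]
}

#' Lineage multiplicity of candidate CREs
#'
#' Histogram of the number of contributing cell lineages among candidate
#' CREs (ePIP > 0), and the fraction defined by two or more lineages.
#'
#' @param cres_epip Output of [compute_epip()] (filtered internally to
#'   candidates).
#' @return list with `counts` (table over n_lineages) and
#'   `fraction_multi_lineage`.
#' @export
lineage_multiplicity <- function(cres_epip) {
  cand <- candidate_cres(cres_epip)
  stopifnot(nrow(cand) > 0L)
  counts <- table(factor(cand$n_lineages,
                         levels = seq_len(max(cand$n_lineages))))
  list(counts = counts,
       fraction_multi_lineage = mean(cand$n_lineages >= 2))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with mid-ranks for ties. When both groups have
#' at most 10 observations the p-value is computed by exact enumeration of
#' all rank assignments; otherwise a normal approximation with tie
#' correction and continuity correction is used. The statistic is the
#' rank-sum W of the first group.
#'
#' @param x,y Numeric samples.
#' @return list with `statistic` (W), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  if (n1 <= 10L && n2 <= 10L) {
    combos <- utils::combn(N, n1)
    Ws <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      dev <- abs(W - mu) - 0.5      # continuity correction
      p <- min(1, 2 * pnorm(-max(dev, 0) / sqrt(sigma2)))
    }
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = W, p_value = p, method = method)
}

#' Compare ePIPs of CREs overlapping MPRA-positive vs MPRA-negative sequences
#'
#' Matches candidate CREs to MPRA-tested sequences by >= 1 bp overlap and
#' compares the ePIP distributions of elements overlapping at least one
#' MPRA-positive sequence against those overlapping only negatives, with a
#' two-sided Wilcoxon rank-sum test. A sequence-level summary (each tested
#' sequence labeled with the ePIP of its overlapping CRE, 0 if none) is also
#' returned.
#'
#' @param cres_epip Output of [compute_epip()].
#' @param mpra Data.frame of tested sequences: `chrom`, `start`, `end`,
#'   `label` ("+" or "-").
#' @param trait Trait name whose `epip_<trait>` column is compared.
#' @return list with `cre_level` and `sequence_level`, each a list with
#'   `statistic`, `p_value`, `method`, `n_pos`, `n_neg`.
#' @export
mpra_epip_test <- function(cres_epip, mpra, trait) {
  col <- paste0("epip_", trait)
  stopifnot(col %in% names(cres_epip), all(mpra$label %in% c("+", "-")))
  cre_gr <- bed_granges(cres_epip)
  mpra_gr <- bed_granges(mpra)
  hits <- GenomicRanges::findOverlaps(cre_gr, mpra_gr)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  # CRE level: group by whether the element touches any MPRA+ sequence
  touched <- unique(q)
  pos_cre <- unique(q[mpra$label[s] == "+"])
  neg_cre <- setdiff(touched, pos_cre)
  if (length(pos_cre) == 0L || length(neg_cre) == 0L) {
    stop("need CREs overlapping both MPRA+ and MPRA- sequences")
  }
  cre_test <- wilcoxon_rank_sum(cres_epip[[col]][pos_cre],
                                cres_epip[[col]][neg_cre])
  cre_test$n_pos <- length(pos_cre); cre_test$n_neg <- length(neg_cre)
  # sequence level: each tested sequence carries its overlapping CRE's ePIP
  seq_epip <- rep(0, nrow(mpra))
  for (i in seq_along(q)) {
    seq_epip[s[i]] <- max(seq_epip[s[i]], cres_epip[[col]][q[i]])
  }
  seq_test <- wilcoxon_rank_sum(seq_epip[mpra$label == "+"],
                                seq_epip[mpra$label == "-"])
  seq_test$n_pos <- sum(mpra$label == "+")
  seq_test$n_neg <- sum(mpra$label == "-")
  list(cre_level = cre_test, sequence_level = seq_test)
}
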