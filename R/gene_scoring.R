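# CRE-to-gene linking and effector-gene scoring. Four element-level features
# nominate target genes for each candidate CRE — nearest gene (midpoint to
# TSS), eQTL of the top-PIP SNP, >= 50% overlap with the non-promoter anchor
# of a PCHi-C loop, and >= 50% overlap (of the element) with an ABC
# enhancer, all lineage-matched — plus variant-level exonic links. Analysis
# is restricted to protein-coding genes. A gene's score S_g sums the PIPs of
# the distinct credible-set variants linked to it; S_g >= 0.95 flags a
# high-confidence candidate causal gene.

cre_lineages <- function(cre) strsplit(cre$lineages, ",", fixed = TRUE)[[1L]]

# overlap in bp between one CRE row and interval columns (BED coords)
overlap_bp <- function(cre, start, end) {
  pmax(0, pmin(cre$end, end) - pmax(cre$start, start))
}

#' Nearest protein-coding gene to a CRE
#'
#' Finds the protein-coding gene whose TSS is closest to the CRE midpoint
#' (`floor((start + end) / 2)` in BED coordinates). Ties are broken by
#' lexicographic gene id.
#'
#' @param cre One-row data.frame with `chrom`, `start`, `end`.
#' @param genes Gene table: `gene`, `chrom`, `tss`, `biotype`.
#' @return list with `gene` and `distance`, or `NULL` (with a warning) if
#'   the chromosome has no protein-coding gene.
#' @export
nearest_gene <- function(cre, genes) {
  g <- genes[genes$chrom == cre$chrom & genes$biotype == "protein_coding", ,
             drop = FALSE]
  if (nrow(g) == 0L) {
    warning("no protein-coding gene on ", cre$chrom, "; no Nearest link")
    return(NULL)
  }
  mid <- floor((cre$start + cre$end) / 2)
  d <- abs(mid - g$tss)
  cand <- g$gene[d == min(d)]
  list(gene = sort(cand)[1L], distance = min(d))
}

#' eQTL links for a CRE
#'
#' Emits links only for the top-PIP credible-set SNP inside the CRE (all
#' tied SNPs if tied), for genes where that SNP is an eQTL in a tissue
#' matching one of the CRE's cell lineages.
#'
#' @param cre One-row CRE data.frame (with `lineages`).
#' @param cre_snps Credible-set SNPs inside the CRE: `snp_id`, `pip`.
#' @param eqtl eQTL table: `snp_id`, `gene`, `tissue`.
#' @param tissue_lineage Optional named character vector mapping tissues to
#'   lineages; by default tissue names are taken to be lineage names.
#' @return data.frame of links: `snp_id`, `gene`, `category`, `context`.
#' @export
eqtl_link <- function(cre, cre_snps, eqtl, tissue_lineage = NULL) {
  empty <- data.frame(snp_id = character(), gene = character(),
                      category = character(), context = character(),
                      stringsAsFactors = FALSE)
  if (nrow(cre_snps) == 0L || nrow(eqtl) == 0L) return(empty)
  top <- cre_snps$snp_id[cre_snps$pip == max(cre_snps$pip)]
  lin <- cre_lineages(cre)
  tiss_lin <- if (is.null(tissue_lineage)) {
    setNames(eqtl$tissue, eqtl$tissue)
  } else {
    tissue_lineage
  }
  hit <- eqtl[eqtl$snp_id %in% top &
                tiss_lin[eqtl$tissue] %in% lin, , drop = FALSE]
  if (nrow(hit) == 0L) return(empty)
  unique(data.frame(snp_id = hit$snp_id, gene = hit$gene, category = "eQTL",
                    context = hit$tissue, stringsAsFactors = FALSE))
}

#' PCHi-C links for a CRE
#'
#' Links the CRE to a loop's promoter gene when the CRE covers at least 50%
#' of the loop's non-promoter anchor (anchor B), in a lineage-matched cell
#' type.
#'
#' @param cre One-row CRE data.frame.
#' @param loops Loop table from [read_loops()] (optional `cell_type`).
#' @param tissue_lineage Optional tissue-to-lineage map as in [eqtl_link()].
#' @return data.frame of links: `gene`, `category`, `context`.
#' @export
pchic_link <- function(cre, loops, tissue_lineage = NULL) {
  empty <- data.frame(gene = character(), category = character(),
                      context = character(), stringsAsFactors = FALSE)
  if (nrow(loops) == 0L) return(empty)
  lin <- cre_lineages(cre)
  if ("cell_type" %in% names(loops)) {
    ct_lin <- if (is.null(tissue_lineage)) setNames(loops$cell_type,
                                                    loops$cell_type)
    else tissue_lineage
    loops <- loops[ct_lin[loops$cell_type] %in% lin, , drop = FALSE]
  }
  loops <- loops[loops$chromB == cre$chrom, , drop = FALSE]
  if (nrow(loops) == 0L) return(empty)
  ov <- overlap_bp(cre, loops$startB, loops$endB)
  keep <- ov >= 0.5 * (loops$endB - loops$startB)
  if (!any(keep)) return(empty)
  unique(data.frame(gene = loops$gene[keep], category = "PCHi-C",
                    context = if ("cell_type" %in% names(loops))
                      loops$cell_type[keep] else NA_character_,
                    stringsAsFactors = FALSE))
}

#' ABC links for a CRE
#'
#' Among lineage-matched ABC elements overlapping the CRE by at least 50%
#' of the ABC element's length, emits one link per cell type to that cell
#' type's highest-scoring gene (all genes if tied).
#'
#' @param cre One-row CRE data.frame.
#' @param abc ABC table: `chrom`, `start`, `end`, `gene`, `score`,
#'   `cell_type`.
#' @param tissue_lineage Optional cell-type-to-lineage map.
#' @return data.frame of links: `gene`, `category`, `context`.
#' @export
abc_link <- function(cre, abc, tissue_lineage = NULL) {
  empty <- data.frame(gene = character(), category = character(),
                      context = character(), stringsAsFactors = FALSE)
  if (nrow(abc) == 0L) return(empty)
  lin <- cre_lineages(cre)
  ct_lin <- if (is.null(tissue_lineage)) setNames(abc$cell_type, abc$cell_type)
  else tissue_lineage
  abc <- abc[ct_lin[abc$cell_type] %in% lin & abc$chrom == cre$chrom, ,
             drop = FALSE]
  if (nrow(abc) == 0L) return(empty)
  ov <- overlap_bp(cre, abc$start, abc$end)
  abc <- abc[ov >= 0.5 * (abc$end - abc$start), , drop = FALSE]
  if (nrow(abc) == 0L) return(empty)
  rows <- lapply(split(abc, abc$cell_type), function(a) {
    a[a$score == max(a$score), c("gene", "cell_type"), drop = FALSE]
  })
  out <- do.call(rbind, rows)
  unique(data.frame(gene = out$gene, category = "ABC",
                    context = out$cell_type, stringsAsFactors = FALSE))
}

#' Exonic links for credible-set variants
#'
#' Links each variant to every protein-coding gene with an exon containing
#' its position.
#'
#' @param snps Data.frame: `snp_id`, `chrom`, `pos` (1-based).
#' @param genes Gene table with `gene`, `biotype`.
#' @param exons Exon table: `gene`, `chrom`, `start`, `end` (BED coords).
#' @return data.frame of links: `snp_id`, `gene`, `category`.
#' @export
exon_link <- function(snps, genes, exons) {
  empty <- data.frame(snp_id = character(), gene = character(),
                      category = character(), stringsAsFactors = FALSE)
  if (nrow(snps) == 0L || nrow(exons) == 0L) return(empty)
  pc <- genes$gene[genes$biotype == "protein_coding"]
  exons <- exons[exons$gene %in% pc, , drop = FALSE]
  if (nrow(exons) == 0L) return(empty)
  hits <- GenomicRanges::findOverlaps(snp_granges(snps$chrom, snps$pos),
                                      bed_granges(exons))
  if (length(hits) == 0L) return(empty)
  unique(data.frame(snp_id = snps$snp_id[S4Vectors::queryHits(hits)],
                    gene = exons$gene[S4Vectors::subjectHits(hits)],
                    category = "Exon", stringsAsFactors = FALSE))
}

#' Nominate target genes for one candidate CRE
#'
#' Applies the four element-level features — nearest protein-coding gene,
#' eQTL of the element's top-PIP credible SNP, PCHi-C non-promoter-anchor
#' overlap, and ABC element overlap — and returns the union of nominated
#' genes with their supporting categories.
#'
#' @param cre One-row CRE data.frame (`cre_id`, `chrom`, `start`, `end`,
#'   `lineages`).
#' @param cre_snps Credible-set SNPs inside the CRE (`snp_id`, `pip`); may
#'   be empty (then no eQTL nominations).
#' @param annotation list with `genes` and `exons`.
#' @param eqtl,loops,abc Evidence tables.
#' @param tissue_lineage Optional tissue/cell-type to lineage map.
#' @return data.frame of nominations: `gene`, `category`, `context`,
#'   `snp_id` (NA except for eQTL nominations).
#' @export
nominate_genes <- function(cre, cre_snps, annotation, eqtl = NULL,
                           loops = NULL, abc = NULL, tissue_lineage = NULL) {
  genes <- annotation$genes
  rows <- list()
  ng <- nearest_gene(cre, genes)
  if (!is.null(ng)) {
    rows$nearest <- data.frame(gene = ng$gene, category = "Nearest",
                               context = NA_character_,
                               snp_id = NA_character_,
                               stringsAsFactors = FALSE)
  }
  if (!is.null(eqtl) && nrow(cre_snps) > 0L) {
    el <- eqtl_link(cre, cre_snps, eqtl, tissue_lineage)
    if (nrow(el) > 0L) {
      rows$eqtl <- data.frame(gene = el$gene, category = el$category,
                              context = el$context, snp_id = el$snp_id,
                              stringsAsFactors = FALSE)
    }
  }
  if (!is.null(loops)) {
    pl <- pchic_link(cre, loops, tissue_lineage)
    if (nrow(pl) > 0L) {
      rows$pchic <- data.frame(gene = pl$gene, category = pl$category,
                               context = pl$context, snp_id = NA_character_,
                               stringsAsFactors = FALSE)
    }
  }
  if (!is.null(abc)) {
    al <- abc_link(cre, abc, tissue_lineage)
    if (nrow(al) > 0L) {
      rows$abc <- data.frame(gene = al$gene, category = al$category,
                             context = al$context, snp_id = NA_character_,
                             stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene = character(), category = character(),
                      context = character(), snp_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  pc <- genes$gene[genes$biotype == "protein_coding"]
  out <- unique(out[out$gene %in% pc, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' All variant-to-gene evidence links for one trait
#'
#' Maps each credible-set variant to its containing candidate CRE (if any)
#' and propagates the CRE's Nearest / eQTL / PCHi-C / ABC links to the
#' variant (eQTL only for the CRE's top-PIP variant), then adds the
#' variant's own exonic links. Non-protein-coding genes are filtered out.
#'
#' @param cs_snps Long credible-set table for the trait: `snp_id`, `chrom`,
#'   `pos`, `pip`, `cs`.
#' @param cres CRE catalog from [merge_peaks()] (or [compute_epip()]).
#' @param annotation list with `genes` and `exons` (see
#'   [read_gene_annotation()]).
#' @param eqtl,loops,abc Evidence tables (any may be empty / NULL).
#' @param tissue_lineage Optional tissue/cell-type to lineage map.
#' @return data.frame of links: `snp_id`, `gene`, `category`, `cre_id`
#'   (NA for Exon), `context`, `cs`, `pip`.
#' @export
variant_gene_links <- function(cs_snps, cres, annotation, eqtl = NULL,
                               loops = NULL, abc = NULL,
                               tissue_lineage = NULL) {
  genes <- annotation$genes
  exons <- annotation$exons
  if (is.null(eqtl)) eqtl <- data.frame(snp_id = character(),
                                        gene = character(),
                                        tissue = character())
  if (is.null(loops)) loops <- data.frame(chromA = character(),
                                          startA = integer(),
                                          endA = integer(),
                                          chromB = character(),
                                          startB = integer(),
                                          endB = integer(),
                                          gene = character())
  if (is.null(abc)) abc <- data.frame(chrom = character(), start = integer(),
                                      end = integer(), gene = character(),
                                      score = numeric(),
                                      cell_type = character())
  link_rows <- list()
  add <- function(df) link_rows[[length(link_rows) + 1L]] <<- df

  if (nrow(cs_snps) > 0L && nrow(cres) > 0L) {
    hits <- GenomicRanges::findOverlaps(snp_granges(cs_snps$chrom,
                                                    cs_snps$pos),
                                        bed_granges(cres))
    snp_cre <- setNames(S4Vectors::subjectHits(hits),
                        cs_snps$snp_id[S4Vectors::queryHits(hits)])
    for (j in unique(snp_cre)) {
      cre <- cres[j, , drop = FALSE]
      in_cre <- cs_snps[cs_snps$snp_id %in% names(snp_cre)[snp_cre == j], ,
                        drop = FALSE]
      nom <- nominate_genes(cre, in_cre, annotation, eqtl = eqtl,
                            loops = loops, abc = abc,
                            tissue_lineage = tissue_lineage)
      if (nrow(nom) == 0L) next
      # every credible variant in the CRE inherits the element-level links;
      # eQTL links stay attached to the top-PIP variant(s) that earned them
      shared <- nom[nom$category != "eQTL", , drop = FALSE]
      el <- nom[nom$category == "eQTL", , drop = FALSE]
      for (i in seq_len(nrow(in_cre))) {
        if (nrow(shared) > 0L) {
          add(data.frame(snp_id = in_cre$snp_id[i], gene = shared$gene,
                         category = shared$category,
                         cre_id = cre$cre_id, context = shared$context,
                         stringsAsFactors = FALSE))
        }
      }
      if (nrow(el) > 0L) {
        add(data.frame(snp_id = el$snp_id, gene = el$gene,
                       category = el$category, cre_id = cre$cre_id,
                       context = el$context, stringsAsFactors = FALSE))
      }
    }
  }
  ex <- exon_link(cs_snps, genes, exons)
  if (nrow(ex) > 0L) {
    add(data.frame(snp_id = ex$snp_id, gene = ex$gene, category = ex$category,
                   cre_id = NA_character_, context = NA_character_,
                   stringsAsFactors = FALSE))
  }
  if (length(link_rows) == 0L) {
    return(data.frame(snp_id = character(), gene = character(),
                      category = character(), cre_id = character(),
                      context = character(), cs = character(),
                      pip = numeric(), stringsAsFactors = FALSE))
  }
  links <- unique(do.call(rbind, link_rows))
  pc <- genes$gene[genes$biotype == "protein_coding"]
  links <- links[links$gene %in% pc, , drop = FALSE]
  idx <- match(links$snp_id, cs_snps$snp_id)
  links$cs <- cs_snps$cs[idx]
  links$pip <- cs_snps$pip[idx]
  rownames(links) <- NULL
  links
}

#' Aggregate variant links into gene scores
#'
#' A gene's score `S_g` is the sum over distinct linked variants of the
#' variant's PIP; a variant contributes its full PIP once per gene no
#' matter how many evidence categories support the link. For reporting,
#' each variant's PIP is split equally among its supporting categories
#' (category decomposition) and grouped by credible set (credible-set
#' decomposition); both decompositions sum to `S_g`. Genes with
#' `S_g >= 0.95` are flagged high-confidence.
#'
#' @param links Link table from [variant_gene_links()] (needs `snp_id`,
#'   `gene`, `category`, `cs`, `pip`).
#' @param trait Trait label for the output.
#' @param high_conf_threshold Score threshold for the high-confidence flag
#'   (default 0.95).
#' @return list of class `gene_scores`: `scores` (data.frame gene, trait,
#'   score, n_variants, high_confidence), `by_category` (gene x category
#'   matrix), `by_cs` (data.frame gene, cs, contribution).
#' @export
gene_score <- function(links, trait = "trait", high_conf_threshold = 0.95) {
  categories <- c("Nearest", "ABC", "PCHi-C", "eQTL", "Exon")
  if (nrow(links) == 0L) {
    return(structure(list(
      scores = data.frame(gene = character(), trait = character(),
                          score = numeric(), n_variants = integer(),
                          high_confidence = logical(),
                          stringsAsFactors = FALSE),
      by_category = matrix(0, 0L, length(categories),
                           dimnames = list(NULL, categories)),
      by_cs = data.frame(gene = character(), cs = character(),
                         contribution = numeric(), stringsAsFactors = FALSE)),
      class = "gene_scores"))
  }
  no_cs <- is.na(links$cs)
  if (any(no_cs)) {
    warning(sum(no_cs), " link(s) from variants without a credible set ",
            "excluded")
    links <- links[!no_cs, , drop = FALSE]
    if (nrow(links) == 0L) return(gene_score(links, trait = trait))
  }
  genes <- sort(unique(links$gene))
  by_cat <- matrix(0, length(genes), length(categories),
                   dimnames = list(genes, categories))
  score_rows <- list()
  cs_rows <- list()
  for (g in genes) {
    lg <- links[links$gene == g, , drop = FALSE]
    variants <- unique(lg$snp_id)
    s_g <- 0
    for (v in variants) {
      lv <- lg[lg$snp_id == v, , drop = FALSE]
      pip_v <- lv$pip[1L]
      s_g <- s_g + pip_v
      cats <- unique(lv$category)
      by_cat[g, cats] <- by_cat[g, cats] + pip_v / length(cats)
    }
    dedup <- lg[!duplicated(lg$snp_id), , drop = FALSE]
    per_cs <- tapply(dedup$pip, dedup$cs, sum)
    for (cs_id in names(per_cs)) {
      cs_rows[[length(cs_rows) + 1L]] <- data.frame(
        gene = g, cs = cs_id, contribution = unname(per_cs[cs_id]),
        stringsAsFactors = FALSE)
    }
    score_rows[[length(score_rows) + 1L]] <- data.frame(
      gene = g, trait = trait, score = s_g, n_variants = length(variants),
      high_confidence = s_g >= high_conf_threshold, stringsAsFactors = FALSE)
  }
  structure(list(scores = do.call(rbind, score_rows), by_category = by_cat,
                 by_cs = do.call(rbind, cs_rows)),
            class = "gene_scores")
}

#' Ranked gene report
#'
#' Orders genes by descending score (ties by gene id) and attaches the
#' per-category contribution matrix and variant counts.
#'
#' @param gs `gene_scores` object from [gene_score()].
#' @return data.frame sorted by score with one column per evidence category.
#' @export
rank_report <- function(gs) {
  sc <- gs$scores
  if (nrow(sc) == 0L) return(sc)
  ord <- order(-sc$score, sc$gene)
  sc <- sc[ord, , drop = FALSE]
  cat_df <- as.data.frame(gs$by_category[sc$gene, , drop = FALSE])
  names(cat_df) <- paste0("score_", gsub("-", "", names(cat_df)))
  out <- cbind(sc, cat_df)
  rownames(out) <- NULL
  out
}

#' @export
print.gene_scores <- function(x, ...) {
  cat("gene_scores: ", nrow(x$scores), " gene(s), ",
      sum(x$scores$high_confidence), " high-confidence\n", sep = "")
  print(head(rank_report(x), 10L))
  invisible(x)
}
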