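mk_cre <- function(start = 900, end = 1100, lineages = "lymphoid",
                   chrom = "chr1", id = "cre1") {
  data.frame(cre_id = id, chrom = chrom, start = start, end = end,
             cell_types = "x", lineages = lineages,
             n_lineages = length(strsplit(lineages, ",")[[1]]),
             stringsAsFactors = FALSE)
}

mk_genes <- function(gene, tss, biotype = "protein_coding", chrom = "chr1") {
  data.frame(gene = gene, chrom = chrom, tss = tss, strand = "+",
             biotype = biotype, stringsAsFactors = FALSE)
}

test_that("nearest_gene minimizes midpoint-to-TSS distance with
           lexicographic ties", {
  cre <- mk_cre(0, 2000)                       # midpoint 1000
  g <- mk_genes(c("B", "A"), c(500, 5000))
  out <- nearest_gene(cre, g)
  expect_equal(out$gene, "B")
  expect_equal(out$distance, 500)

  # equidistant -> lexicographically first
  g2 <- mk_genes(c("ZZ", "AA"), c(600, 1400))
  expect_equal(nearest_gene(cre, g2)$gene, "AA")

  # midpoint convention: floor((0 + 10) / 2) = 5
  cre2 <- mk_cre(0, 10)
  g3 <- mk_genes(c("L", "R"), c(4, 7))
  expect_equal(nearest_gene(cre2, g3)$gene, "L")

  # non-protein-coding genes never nominated
  g4 <- mk_genes(c("PC", "LNC"), c(5000, 1000),
                 biotype = c("protein_coding", "lincRNA"))
  expect_equal(nearest_gene(cre, g4)$gene, "PC")
  expect_warning(out4 <- nearest_gene(mk_cre(chrom = "chrX"), g),
                 "no protein-coding gene")
  expect_null(out4)
})

test_that("eqtl_link fires only for the top-PIP SNP in lineage-matched
           tissue", {
  cre <- mk_cre(lineages = "lymphoid")
  snps <- data.frame(snp_id = c("rs1", "rs2"), pip = c(0.7, 0.2))
  eqtl <- data.frame(snp_id = c("rs1", "rs1", "rs2"),
                     gene = c("G1", "G2", "G3"),
                     tissue = c("lymphoid", "lymphoid", "lymphoid"),
                     stringsAsFactors = FALSE)
  out <- eqtl_link(cre, snps, eqtl)
  expect_setequal(out$gene, c("G1", "G2"))     # two genes for top SNP
  expect_false("G3" %in% out$gene)             # second-ranked SNP ignored

  # non-matching tissue yields nothing
  eqtl2 <- data.frame(snp_id = "rs1", gene = "G1", tissue = "epithelial")
  expect_equal(nrow(eqtl_link(cre, snps, eqtl2)), 0L)

  # tied top SNPs all emit links
  snps_tie <- data.frame(snp_id = c("rs1", "rs2"), pip = c(0.5, 0.5))
  expect_setequal(eqtl_link(cre, snps_tie, eqtl)$snp_id, c("rs1", "rs2"))
})

test_that("pchic_link requires >= 50% overlap of the non-promoter anchor", {
  loops <- data.frame(chromA = "chr1", startA = 10000, endA = 11000,
                      chromB = "chr1", startB = 1000, endB = 2000,
                      gene = "G1", cell_type = "lymphoid",
                      stringsAsFactors = FALSE)
  # CRE covering the whole anchor
  expect_equal(pchic_link(mk_cre(900, 2100), loops)$gene, "G1")
  # 40% anchor overlap -> no link
  expect_equal(nrow(pchic_link(mk_cre(1600, 2600), loops)), 0L)
  # exactly 50% fires (>= threshold)
  expect_equal(nrow(pchic_link(mk_cre(1500, 2000), loops)), 1L)
  # lineage mismatch -> no link
  expect_equal(nrow(pchic_link(mk_cre(900, 2100, lineages = "myeloid"),
                               loops)), 0L)
  # two loops at >= 50% -> one link per promoter gene
  loops2 <- rbind(loops, transform(loops, gene = "G2"))
  expect_setequal(pchic_link(mk_cre(900, 2100), loops2)$gene, c("G1", "G2"))
})

test_that("abc_link keeps the top-scoring gene per cell type at >= 50%
           element overlap", {
  abc <- data.frame(chrom = "chr1", start = 1000, end = 2000,
                    gene = c("G1", "G2"), score = c(0.3, 0.1),
                    cell_type = "lymphoid", stringsAsFactors = FALSE)
  out <- abc_link(mk_cre(900, 2100), abc)
  expect_equal(out$gene, "G1")                 # max rule

  # 49% overlap of the element -> no link
  expect_equal(nrow(abc_link(mk_cre(1510, 2600), abc)), 0L)

  # two cell types with different top genes -> two links
  abc2 <- rbind(abc,
                data.frame(chrom = "chr1", start = 1000, end = 2000,
                           gene = "G9", score = 0.9,
                           cell_type = "epithelial"))
  out2 <- abc_link(mk_cre(900, 2100, lineages = "epithelial,lymphoid"), abc2)
  expect_setequal(out2$gene, c("G1", "G9"))
})

test_that("exon_link maps variants into protein-coding exons only", {
  genes <- mk_genes(c("G1", "G2", "LNC"), c(100, 150, 120),
                    biotype = c("protein_coding", "protein_coding",
                                "lincRNA"))
  exons <- data.frame(gene = c("G1", "G2", "LNC"), chrom = "chr1",
                      start = c(500, 550, 500), end = c(700, 650, 700),
                      stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = "chr1",
                     pos = c(600, 5000))
  out <- exon_link(snps, genes, exons)
  expect_setequal(out$gene[out$snp_id == "rs1"], c("G1", "G2"))
  expect_false("LNC" %in% out$gene)
  expect_false("rs2" %in% out$snp_id)          # intronic/intergenic
})

test_that("variant_gene_links composes element and variant evidence", {
  cres <- mk_cre(900, 1400, lineages = "lymphoid")
  annotation <- list(
    genes = mk_genes(c("EFF", "OTHER"), c(1600, 9000)),
    exons = data.frame(gene = "OTHER", chrom = "chr1", start = 8000,
                       end = 8200, stringsAsFactors = FALSE))
  abc <- data.frame(chrom = "chr1", start = 900, end = 1400, gene = "EFF",
                    score = 1, cell_type = "lymphoid",
                    stringsAsFactors = FALSE)
  cs <- data.frame(trait = "A", block_id = "b", cs = c("cs1", "cs1"),
                   snp_id = c("rs1", "rs2"), chrom = "chr1",
                   pos = c(1000, 8100), pip = c(0.9, 0.3),
                   stringsAsFactors = FALSE)
  links <- variant_gene_links(cs, cres, annotation, abc = abc)
  # rs1 in the CRE: Nearest + ABC to EFF; rs2 outside any CRE: Exon only
  rs1 <- links[links$snp_id == "rs1", ]
  expect_setequal(rs1$category, c("Nearest", "ABC"))
  expect_true(all(rs1$gene == "EFF"))
  rs2 <- links[links$snp_id == "rs2", ]
  expect_equal(rs2$category, "Exon")
  expect_equal(rs2$gene, "OTHER")
  expect_true(is.na(rs2$cre_id))
})

test_that("gene_score sums each variant's PIP once per gene with category
           and credible-set decompositions", {
  links <- data.frame(
    snp_id = "rs1", gene = "G", category = c("Nearest", "ABC"),
    cre_id = "cre1", context = NA, cs = "cs1", pip = 0.96,
    stringsAsFactors = FALSE)
  gs <- gene_score(links)
  expect_equal(gs$scores$score, 0.96)
  expect_true(gs$scores$high_confidence)
  expect_equal(unname(gs$by_category["G", c("Nearest", "ABC")]),
               c(0.48, 0.48))
  expect_equal(sum(gs$by_category["G", ]), gs$scores$score)

  # two credible sets contributing 0.6 and 0.5
  links2 <- data.frame(
    snp_id = c("rs1", "rs2"), gene = "G", category = "Nearest",
    cre_id = "cre1", context = NA, cs = c("cs1", "cs2"), pip = c(0.6, 0.5),
    stringsAsFactors = FALSE)
  gs2 <- gene_score(links2)
  expect_equal(gs2$scores$score, 1.1)
  expect_equal(sort(gs2$by_cs$contribution), c(0.5, 0.6))
  expect_equal(sum(gs2$by_cs$contribution), gs2$scores$score)

  # a variant linked to two genes contributes fully to both
  links3 <- data.frame(
    snp_id = "rs1", gene = c("G1", "G2"), category = "Nearest",
    cre_id = "cre1", context = NA, cs = "cs1", pip = 0.7,
    stringsAsFactors = FALSE)
  gs3 <- gene_score(links3)
  expect_equal(gs3$scores$score, c(0.7, 0.7))

  # variants without a credible set are excluded with a warning
  links4 <- links
  links4$cs <- NA
  expect_warning(gs4 <- gene_score(links4), "without a credible set")
  expect_equal(nrow(gs4$scores), 0L)
})

test_that("rank_report orders by descending score with gene-id tie break", {
  links <- data.frame(
    snp_id = c("r1", "r2", "r3"), gene = c("A", "B", "C"),
    category = "Nearest", cre_id = "cre1", context = NA,
    cs = "cs1", pip = c(1.2 / 2, 0.97, 0.3), stringsAsFactors = FALSE)
  links <- rbind(links, transform(links[1, ], snp_id = "r9"))
  gs <- gene_score(links)
  rep <- rank_report(gs)
  expect_equal(rep$gene, c("A", "B", "C"))
  expect_equal(rep$high_confidence, c(TRUE, TRUE, FALSE))
  expect_equal(rank_report(gene_score(links[0, ])),
               gene_score(links[0, ])$scores)
})

test_that("gene scores never exceed total credible-set PIP and collapse to
           Nearest + Exon without evidence tables", {
  set.seed(121)
  sim <- simulate_two_traits(sim_config(n_blocks = 5, seed = 121))
  fA <- finemap_blocks(lapply(sim$blocks_A, function(b) {
    b$prior <- NULL; b
  }), trait = "A")
  cres <- merge_peaks(sim$peaks)
  links_full <- variant_gene_links(fA$cs_snps, cres, sim$annotation,
                                   eqtl = sim$eqtl, loops = sim$loops,
                                   abc = sim$abc)
  gs <- gene_score(links_full)
  total_pip <- sum(fA$cs_snps$pip)
  expect_true(all(gs$scores$score <= total_pip + 1e-8))

  links_bare <- variant_gene_links(fA$cs_snps, cres, sim$annotation)
  gs_bare <- gene_score(links_bare)
  expect_true(all(links_bare$category %in% c("Nearest", "Exon")))

  links_none <- variant_gene_links(fA$cs_snps, cres[0, ],
                                   list(genes = sim$annotation$genes[0, ],
                                        exons = sim$annotation$exons[0, ]))
  expect_equal(nrow(gene_score(links_none)$scores), 0L)
})
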