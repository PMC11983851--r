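# Synthetic two-trait GWAS + functional landscape with known ground truth.
# z-scores follow the RSS model z ~ MVN(R lambda, R) with lambda on the
# non-centrality scale; causal variants are enriched in open-chromatin
# annotations via a logistic prior; evidence tables (eQTL / PCHi-C / ABC),
# gene annotations and MPRA labels are planted consistently with per-signal
# effector genes so the full pipeline can be validated end to end.

#' Simulation configuration
#'
#' Defaults encode the stated world the generator emulates: five cell
#' lineages; annotation enrichment log-odds of 2 for lymphoid and 1 for
#' epithelial and mesenchymal cells (the lineages with significant
#' heritability enrichment), 0 elsewhere; effect magnitude 6 on the z-score
#' scale (a typical genome-wide-significant signal); 16% of signals shared
#' between the two traits; a second independent signal in one-third of
#' blocks; decoy gene-link rate 0.3.
#'
#' @param n_blocks Number of LD blocks (default 20).
#' @param snps_per_block SNPs per block (default 100).
#' @param rho AR(1) LD decay parameter in `[0, 1)` (default 0.9).
#' @param n GWAS sample size (default 10000).
#' @param annotation_density Per-lineage probability a SNP is annotated
#'   (default 0.1).
#' @param enrichment_log_odds Named log-odds per lineage.
#' @param alpha0 Baseline causal log-odds (default -4).
#' @param n_signals Signals per block: `NULL` (default) draws 2 with
#'   probability `prob_two_signals`, else 1; an integer fixes the count.
#' @param prob_two_signals Probability of a second signal when
#'   `n_signals = NULL` (default 1/3).
#' @param effect_size Causal effect magnitude on the z-scale (default 6).
#' @param fraction_shared Probability a signal is shared between the two
#'   traits (default 0.16).
#' @param decoy_rate Per-category probability of a decoy gene link per
#'   signal (default 0.3).
#' @param mpra_pos_rate Probability a causal element is labeled MPRA
#'   positive (default 0.9).
#' @param mpra_bg_pos_rate Probability a background element is labeled MPRA
#'   positive (default 0.05).
#' @param spacing Base pairs between adjacent SNPs (default 300).
#' @param peak_halfwidth Peak extent around an annotated SNP (default
#'   produces 251-bp peaks).
#' @param n_decoy_genes Decoy genes per block (default 4).
#' @param ensure_peak_at_causal Force open chromatin at causal SNPs in 1-5
#'   lineages (default TRUE; mirrors candidate CREs arising from OCRs of
#'   one to five lineages, about 64% multi-lineage).
#' @param seed Integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_blocks = 20L, snps_per_block = 100L, rho = 0.9,
                       n = 10000L, annotation_density = 0.1,
                       enrichment_log_odds = c(lymphoid = 2, myeloid = 0,
                                               epithelial = 1,
                                               mesenchymal = 1,
                                               endothelial = 0),
                       alpha0 = -4, n_signals = NULL,
                       prob_two_signals = 1 / 3, effect_size = 6,
                       fraction_shared = 0.16, decoy_rate = 0.3,
                       mpra_pos_rate = 0.9, mpra_bg_pos_rate = 0.05,
                       spacing = 300L, peak_halfwidth = 125L,
                       n_decoy_genes = 4L, ensure_peak_at_causal = TRUE,
                       seed = 1L) {
  stopifnot(rho >= 0, rho < 1, n_blocks >= 1, snps_per_block >= 1,
            fraction_shared >= 0, fraction_shared <= 1,
            all(is.finite(enrichment_log_odds)))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an AR(1) LD matrix
#'
#' `R[i, j] = rho^|i - j|`; positive semi-definite by construction.
#'
#' @param snps_per_block Number of SNPs.
#' @param rho Decay parameter in `[0, 1)`.
#' @return Correlation matrix.
#' @export
simulate_ld <- function(snps_per_block, rho) {
  if (rho >= 1 || rho < 0) stop("rho must be in [0, 1)")
  rho^abs(outer(seq_len(snps_per_block), seq_len(snps_per_block), `-`))
}

#' Plant annotations and causal SNPs for one block
#'
#' Draws a binary SNP x lineage annotation matrix at the configured density
#' and selects `n_signals` distinct causal SNPs with probabilities
#' proportional to `logistic(alpha0 + sum_k alpha_k a_jk)` (i.e. rescaled to
#' yield the requested signal count). When `ensure_peak_at_causal` is set,
#' causal SNPs are additionally annotated in 1-5 randomly chosen lineages.
#'
#' @param snps_per_block Number of SNPs in the block.
#' @param config `sim_config`.
#' @param n_signals Number of causal SNPs to plant.
#' @return list with `A` (binary matrix, lineages as columns) and `causal`
#'   (causal SNP indices).
#' @export
plant_annotations_and_causals <- function(snps_per_block, config,
                                          n_signals = 1L) {
  p <- snps_per_block
  if (n_signals > p) stop("requested more signals than SNPs in block")
  lineages <- names(config$enrichment_log_odds)
  A <- matrix(stats::rbinom(p * length(lineages), 1L,
                            config$annotation_density),
              p, length(lineages), dimnames = list(NULL, lineages))
  w <- plogis(config$alpha0 + drop(A %*% config$enrichment_log_odds))
  causal <- sample.int(p, n_signals, prob = w)
  if (config$ensure_peak_at_causal && n_signals > 0L) {
    # 1-5 lineages per causal element; ~64% get two or more
    n_lin_probs <- c(0.36, 0.26, 0.16, 0.12, 0.10)
    for (j in causal) {
      k <- sample.int(5L, 1L, prob = n_lin_probs)
      A[j, sample(lineages, k)] <- 1L
    }
  }
  list(A = A, causal = causal)
}

#' Simulate GWAS z-scores from the RSS model
#'
#' Draws `z ~ MVN(R lambda, R)` where `lambda` holds causal non-centrality
#' effects.
#'
#' @param R LD correlation matrix (positive definite).
#' @param lambda Effect vector, length `nrow(R)`.
#' @return Vector of z-scores.
#' @export
simulate_z <- function(R, lambda) {
  stopifnot(length(lambda) == nrow(R))
  ch <- tryCatch(chol(R), error = function(e)
    stop("R is not positive definite; regularize first"))
  drop(R %*% lambda) + drop(crossprod(ch, rnorm(nrow(R))))
}

# peak intervals (BED coords) covering the annotated SNP positions of one
# lineage column; SNP at pos p is covered since start < p <= end
peaks_for_lineage <- function(chrom, pos, ann_col, lineage, halfwidth) {
  idx <- which(ann_col == 1L)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), cell_type = character(),
                      lineage = character(), stringsAsFactors = FALSE))
  }
  data.frame(chrom = chrom, start = pos[idx] - 1L - halfwidth,
             end = pos[idx] + halfwidth,
             cell_type = paste0(lineage, ".ct1"), lineage = lineage,
             stringsAsFactors = FALSE)
}

#' Simulate a complete two-trait dataset with ground truth
#'
#' Generates `n_blocks` LD blocks, plants annotation-enriched causal
#' signals that are shared between the two traits or trait-specific, draws
#' z-scores for each trait independently given the truth (traits are
#' fine-mapped separately, so no shared-control correlation is simulated),
#' and builds the surrounding functional landscape with
#' [plant_evidence()].
#'
#' @param config `sim_config`.
#' @param seed Overrides `config$seed` when given.
#' @return list of class `sim_data`: `config`, `blocks_A`, `blocks_B` (lists
#'   of per-block data: `block_id`, `chrom`, `snp_id`, `pos`, `ref`, `alt`,
#'   `z`, `n`, `R`, `A`), `truth` (data.frame of planted signals), `peaks`,
#'   `annotation` (genes + exons), `eqtl`, `loops`, `abc`, `mpra`.
#' @export
simulate_two_traits <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  lineages <- names(config$enrichment_log_odds)
  blocks_A <- list()
  blocks_B <- list()
  truth_rows <- list()
  peak_rows <- list()
  for (b in seq_len(config$n_blocks)) {
    p <- config$snps_per_block
    block_id <- sprintf("block%02d", b)
    chrom <- paste0("chr", b)
    pos <- 10000L + (seq_len(p) - 1L) * config$spacing
    snp_id <- sprintf("rs%d_%03d", b, seq_len(p))
    R <- simulate_ld(p, config$rho)
    dimnames(R) <- list(snp_id, snp_id)
    n_sig <- if (is.null(config$n_signals)) {
      1L + stats::rbinom(1L, 1L, config$prob_two_signals)
    } else {
      as.integer(config$n_signals)
    }
    pl <- plant_annotations_and_causals(p, config, n_sig)
    lambda_A <- numeric(p)
    lambda_B <- numeric(p)
    for (s in seq_len(n_sig)) {
      j <- pl$causal[s]
      shared <- runif(1) < config$fraction_shared
      trait <- if (shared) "both" else sample(c("A", "B"), 1L)
      sgn <- sample(c(-1, 1), 1L)
      mag_A <- sgn * (config$effect_size + rnorm(1, 0, 0.5))
      mag_B <- sgn * (config$effect_size + rnorm(1, 0, 0.5))
      if (trait %in% c("A", "both")) lambda_A[j] <- mag_A
      if (trait %in% c("B", "both")) lambda_B[j] <- mag_B
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        block_id = block_id, signal = s, trait = trait, snp_id = snp_id[j],
        snp_index = j, chrom = chrom, pos = pos[j],
        lambda_A = if (trait %in% c("A", "both")) mag_A else 0,
        lambda_B = if (trait %in% c("B", "both")) mag_B else 0,
        shared = shared,
        lineages = paste(lineages[pl$A[j, ] == 1L], collapse = ","),
        stringsAsFactors = FALSE)
    }
    z_A <- simulate_z(R, lambda_A)
    z_B <- simulate_z(R, lambda_B)
    ref <- sample(c("A", "C", "G", "T"), p, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                          1L), character(1))
    mk_block <- function(z) list(block_id = block_id,
                                 chrom = rep(chrom, p),
                                 snp_id = snp_id, pos = pos, ref = ref,
                                 alt = unname(alt), z = z, n = config$n,
                                 R = R, A = pl$A)
    blocks_A[[block_id]] <- mk_block(z_A)
    blocks_B[[block_id]] <- mk_block(z_B)
    for (lin in lineages) {
      peak_rows[[length(peak_rows) + 1L]] <-
        peaks_for_lineage(chrom, pos, pl$A[, lin], lin,
                          config$peak_halfwidth)
    }
  }
  truth <- do.call(rbind, truth_rows)
  peaks <- do.call(rbind, peak_rows)
  rownames(peaks) <- NULL
  all_snps <- do.call(rbind, lapply(blocks_A, function(b) {
    data.frame(block_id = b$block_id, chrom = b$chrom, pos = b$pos,
               snp_id = b$snp_id, stringsAsFactors = FALSE)
  }))
  evidence <- plant_evidence(truth, peaks, config, snps = all_snps)
  structure(c(list(config = config, blocks_A = blocks_A, blocks_B = blocks_B,
                   truth = truth, peaks = peaks), evidence),
            class = "sim_data")
}

#' Plant gene annotations, evidence tables and MPRA labels
#'
#' For each planted signal, an effector gene is created with its TSS close
#' to the causal SNP (so it is also the nearest gene) and linked to the
#' causal element by eQTL, PCHi-C and ABC evidence in a lineage-matched
#' context — at least two supporting categories by construction. Decoy
#' links to non-effector genes are added per category at `decoy_rate`.
#' MPRA-positive labels are preferentially placed on causal elements.
#'
#' Decoy links point at randomly chosen peaks of the block (regulatory
#' evidence scattered over the landscape rather than concentrated on causal
#' elements), so a decoy gene is only occasionally nominated for a causal
#' element.
#'
#' @param truth Ground-truth signal table from [simulate_two_traits()].
#' @param peaks Peak table (all lineages).
#' @param config `sim_config`.
#' @param snps Optional data.frame of all SNPs (`block_id`, `chrom`, `pos`,
#'   `snp_id`) used to anchor decoy eQTLs; without it decoy eQTLs are
#'   skipped.
#' @return list with `annotation` (list of `genes`, `exons`), `eqtl`,
#'   `loops`, `abc`, `mpra`, and `truth_genes` (signal to effector-gene
#'   map).
#' @export
plant_evidence <- function(truth, peaks, config, snps = NULL) {
  hw <- config$peak_halfwidth
  gene_rows <- list()
  exon_rows <- list()
  eqtl_rows <- list()
  loop_rows <- list()
  abc_rows <- list()
  mpra_rows <- list()
  effector <- character(nrow(truth))
  add_gene <- function(gene, chrom, tss, biotype) {
    gene_rows[[length(gene_rows) + 1L]] <<- data.frame(
      gene = gene, chrom = chrom, tss = tss, strand = "+", biotype = biotype,
      stringsAsFactors = FALSE)
    exon_rows[[length(exon_rows) + 1L]] <<- data.frame(
      gene = gene, chrom = chrom, start = c(tss + 200L, tss + 1000L),
      end = c(tss + 500L, tss + 1400L), stringsAsFactors = FALSE)
  }
  for (blk in unique(truth$block_id)) {
    tb <- truth[truth$block_id == blk, , drop = FALSE]
    chrom <- tb$chrom[1L]
    causal_pos <- tb$pos
    # decoy genes well away from every causal element midpoint
    decoy_genes <- sprintf("GENE%s_D%d", sub("block", "", blk),
                           seq_len(config$n_decoy_genes))
    for (d in seq_along(decoy_genes)) {
      repeat {
        tss <- sample(3000:(20000 + config$snps_per_block *
                              config$spacing), 1L)
        if (all(abs(tss - causal_pos) > 8000L)) break
      }
      bio <- if (d == config$n_decoy_genes) "lincRNA" else "protein_coding"
      add_gene(decoy_genes[d], chrom, tss, bio)
    }
    for (i in seq_len(nrow(tb))) {
      s <- which(truth$block_id == blk)[i]
      gene <- sprintf("GENE%s_S%d", sub("block", "", blk), tb$signal[i])
      effector[s] <- gene
      tss <- tb$pos[i] + 1500L
      add_gene(gene, chrom, tss, "protein_coding")
      elem_start <- tb$pos[i] - 1L - hw
      elem_end <- tb$pos[i] + hw
      sig_lin <- strsplit(tb$lineages[i], ",", fixed = TRUE)[[1L]]
      if (length(sig_lin) == 0L) sig_lin <- "lymphoid"
      eqtl_rows[[length(eqtl_rows) + 1L]] <- data.frame(
        snp_id = tb$snp_id[i], gene = gene, tissue = sig_lin[1L],
        stringsAsFactors = FALSE)
      loop_rows[[length(loop_rows) + 1L]] <- data.frame(
        chromA = chrom, startA = tss - 500L, endA = tss + 500L,
        chromB = chrom, startB = elem_start, endB = elem_end, gene = gene,
        cell_type = sig_lin[1L], stringsAsFactors = FALSE)
      abc_rows[[length(abc_rows) + 1L]] <- data.frame(
        chrom = chrom, start = elem_start, end = elem_end, gene = gene,
        score = 1, cell_type = sig_lin[1L], stringsAsFactors = FALSE)
      # decoy links per category, anchored at random peaks of the block
      pc_decoys <- decoy_genes[-length(decoy_genes)]
      blk_peaks <- peaks[peaks$chrom == chrom, , drop = FALSE]
      rand_peak <- function() blk_peaks[sample.int(nrow(blk_peaks), 1L), ,
                                        drop = FALSE]
      if (nrow(blk_peaks) > 0L) {
        if (runif(1) < config$decoy_rate && !is.null(snps)) {
          pk <- rand_peak()
          in_pk <- snps[snps$chrom == chrom & snps$pos > pk$start &
                          snps$pos <= pk$end, , drop = FALSE]
          if (nrow(in_pk) > 0L) {
            eqtl_rows[[length(eqtl_rows) + 1L]] <- data.frame(
              snp_id = in_pk$snp_id[1L], gene = sample(pc_decoys, 1L),
              tissue = pk$lineage, stringsAsFactors = FALSE)
          }
        }
        if (runif(1) < config$decoy_rate) {
          pk <- rand_peak()
          loop_rows[[length(loop_rows) + 1L]] <- data.frame(
            chromA = chrom, startA = 1000L, endA = 2000L, chromB = chrom,
            startB = pk$start, endB = pk$end, gene = sample(pc_decoys, 1L),
            cell_type = pk$lineage, stringsAsFactors = FALSE)
        }
        if (runif(1) < config$decoy_rate) {
          pk <- rand_peak()
          abc_rows[[length(abc_rows) + 1L]] <- data.frame(
            chrom = chrom, start = pk$start, end = pk$end,
            gene = sample(pc_decoys, 1L), score = 0.6,
            cell_type = pk$lineage, stringsAsFactors = FALSE)
        }
      }
      if (runif(1) < config$mpra_pos_rate) {
        mpra_rows[[length(mpra_rows) + 1L]] <- data.frame(
          chrom = chrom, start = elem_start, end = elem_end, label = "+",
          stringsAsFactors = FALSE)
      }
    }
    # background MPRA sequences on non-causal peaks of this block
    bg <- peaks[peaks$chrom == chrom, , drop = FALSE]
    if (nrow(bg) > 0L) {
      covers_causal <- vapply(seq_len(nrow(bg)), function(r) {
        any(bg$start[r] < causal_pos & causal_pos <= bg$end[r])
      }, logical(1))
      bg <- bg[!covers_causal, , drop = FALSE]
    }
    n_bg <- min(2L, nrow(bg))
    if (n_bg > 0L) {
      pick <- sample.int(nrow(bg), n_bg)
      lab <- ifelse(runif(n_bg) < config$mpra_bg_pos_rate, "+", "-")
      mpra_rows[[length(mpra_rows) + 1L]] <- data.frame(
        chrom = bg$chrom[pick], start = bg$start[pick], end = bg$end[pick],
        label = lab, stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, gene_rows)
  missing_eff <- setdiff(effector, genes$gene)
  if (length(missing_eff) > 0L) {
    stop("effector gene absent from annotation: ", missing_eff[1L])
  }
  truth_genes <- cbind(truth[, c("block_id", "signal", "snp_id", "trait")],
                       effector_gene = effector)
  list(annotation = list(genes = genes, exons = do.call(rbind, exon_rows)),
       eqtl = do.call(rbind, eqtl_rows),
       loops = {
         l <- do.call(rbind, loop_rows)
         l$trans <- l$chromA != l$chromB
         l
       },
       abc = do.call(rbind, abc_rows),
       mpra = do.call(rbind, mpra_rows),
       truth_genes = truth_genes)
}

#' Simulate summary-statistic blocks for enrichment-model recovery
#'
#' Generates blocks where each SNP is independently causal with probability
#' `logistic(alpha0 + sum_k alpha_k a_jk)`; causal SNPs receive effects of
#' magnitude `effect_size` with random sign, and z-scores follow the RSS
#' model. This is the clean generative match for [fit_enrichment()]
#' parameter recovery.
#'
#' @param n_blocks Number of blocks.
#' @param config `sim_config` (uses `snps_per_block`, `rho`, `n`,
#'   `annotation_density`, `enrichment_log_odds`, `alpha0`, `effect_size`).
#' @return list of blocks, each with `z`, `n`, `A`, `causal`.
#' @export
simulate_enrichment_blocks <- function(n_blocks, config = sim_config()) {
  lineages <- names(config$enrichment_log_odds)
  lapply(seq_len(n_blocks), function(b) {
    p <- config$snps_per_block
    A <- matrix(stats::rbinom(p * length(lineages), 1L,
                              config$annotation_density),
                p, length(lineages), dimnames = list(NULL, lineages))
    pi_j <- plogis(config$alpha0 + drop(A %*% config$enrichment_log_odds))
    causal <- which(stats::rbinom(p, 1L, pi_j) == 1L)
    lambda <- numeric(p)
    lambda[causal] <- sample(c(-1, 1), length(causal), replace = TRUE) *
      config$effect_size
    R <- simulate_ld(p, config$rho)
    list(z = simulate_z(R, lambda), n = config$n, A = A, causal = causal,
         R = R)
  })
}

#' Write a simulated dataset to a directory
#'
#' Emits the full plain-text layout consumed by the pipeline readers:
#' per-trait sumstats TSVs (with a `block_id` column), per-block LD matrices
#' with id sidecars, per-lineage peak BEDs (cell type in the name column),
#' gene annotation, eQTL, ABC, loops, MPRA labels and the ground truth.
#' Output is byte-for-byte deterministic given the simulation seed.
#'
#' @param sim `sim_data` from [simulate_two_traits()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ld"), showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  for (trait in c("A", "B")) {
    blocks <- sim[[paste0("blocks_", trait)]]
    ss <- do.call(rbind, lapply(blocks, function(b) {
      data.frame(snp_id = b$snp_id, chrom = b$chrom, pos = b$pos,
                 ref = b$ref, alt = b$alt, z = b$z, n = b$n,
                 block_id = b$block_id, stringsAsFactors = FALSE)
    }))
    ss$z <- formatC(ss$z, digits = 10, format = "g")
    write_sumstats(ss, file.path(dir, paste0("sumstats_", trait, ".tsv")))
  }
  for (b in sim$blocks_A) {
    write_ld(b$R, file.path(dir, "ld", paste0(b$block_id, ".ld")))
  }
  for (lin in unique(sim$peaks$lineage)) {
    pk <- sim$peaks[sim$peaks$lineage == lin, , drop = FALSE]
    write_bed(pk[, c("chrom", "start", "end", "cell_type")],
              file.path(dir, "peaks", paste0(lin, ".bed")))
  }
  write_gene_annotation(sim$annotation$genes, sim$annotation$exons,
                        file.path(dir, "genes.tsv"))
  utils::write.table(sim$eqtl, file.path(dir, "eqtl.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$abc, file.path(dir, "abc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_loops(sim$loops, file.path(dir, "loops.bedpe"))
  write_bed(sim$mpra, file.path(dir, "mpra.bed"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth_genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a simulated dataset back from a directory
#'
#' Inverse of [write_dataset()] for everything the pipeline needs.
#'
#' @param dir Dataset directory.
#' @return list resembling `sim_data` (without `config`).
#' @export
read_dataset <- function(dir) {
  read_trait <- function(trait) {
    ss <- utils::read.table(file.path(dir,
                                      paste0("sumstats_", trait, ".tsv")),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    lapply(split(ss, ss$block_id), function(s) {
      R <- load_and_regularize_ld(file.path(dir, "ld",
                                            paste0(s$block_id[1L], ".ld")))
      stopifnot(identical(rownames(R), s$snp_id))
      list(block_id = s$block_id[1L], chrom = s$chrom, snp_id = s$snp_id,
           pos = s$pos, ref = s$ref, alt = s$alt, z = s$z, n = s$n[1L],
           R = R)
    })
  }
  peak_files <- list.files(file.path(dir, "peaks"), full.names = TRUE)
  peaks <- do.call(rbind, lapply(peak_files, function(f) {
    bed <- read_bed(f)
    bed$cell_type <- bed$name
    bed$lineage <- sub("\\.bed$", "", basename(f))
    bed[, c("chrom", "start", "end", "cell_type", "lineage")]
  }))
  mpra <- read_bed(file.path(dir, "mpra.bed"))
  names(mpra)[names(mpra) == "name"] <- "label"
  list(blocks_A = read_trait("A"), blocks_B = read_trait("B"),
       peaks = peaks,
       annotation = read_gene_annotation(file.path(dir, "genes.tsv")),
       eqtl = read_eqtl(file.path(dir, "eqtl.tsv")),
       loops = read_loops(file.path(dir, "loops.bedpe")),
       abc = read_abc(file.path(dir, "abc.tsv")),
       mpra = mpra,
       truth = utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE),
       truth_genes = utils::read.table(file.path(dir, "truth_genes.tsv"),
                                       header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE))
}
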