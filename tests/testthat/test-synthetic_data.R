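test_that("simulate_ld builds the AR(1) correlation structure", {
  expect_equal(simulate_ld(5, 0), diag(5))
  R <- simulate_ld(10, 0.9)
  expect_equal(R[1, 3], 0.81)
  expect_equal(R[4, 9], 0.9^5)
  expect_equal(R, t(R))
  expect_equal(diag(R), rep(1, 10))
  expect_gte(min(eigen(R, symmetric = TRUE)$values), 0)
  expect_error(simulate_ld(5, 1), "rho")
})

test_that("plant_annotations_and_causals enriches causal picks as the
           logistic model dictates", {
  cfg <- sim_config(enrichment_log_odds = c(lymphoid = 3),
                    annotation_density = 0.1, snps_per_block = 50,
                    ensure_peak_at_causal = FALSE)
  expect_error(plant_annotations_and_causals(5, cfg, n_signals = 6),
               "more signals")
  set.seed(31)
  out <- plant_annotations_and_causals(50, cfg, n_signals = 2)
  expect_length(out$causal, 2L)
  expect_true(all(out$causal %in% 1:50))

  # Monte-Carlo vs the logistic closed form: among causals the annotated
  # fraction is d*o1 / (d*o1 + (1-d)*o0) with o = plogis(alpha0 + alpha*a)
  set.seed(32)
  hits <- ann <- 0
  for (rep in 1:2000) {
    out <- plant_annotations_and_causals(50, cfg, n_signals = 1L)
    ann <- ann + sum(out$A[, 1])
    hits <- hits + out$A[out$causal, 1]
  }
  d <- 0.1
  o1 <- plogis(cfg$alpha0 + 3); o0 <- plogis(cfg$alpha0)
  expected <- d * o1 / (d * o1 + (1 - d) * o0)
  expect_lt(abs(unname(hits) / 2000 - expected), 0.05)
  expect_gt(unname(hits) / 2000, 3 * d) # far above the 10% annotation density

  # alpha = 0 everywhere: causal picks are uniform over the block
  cfg0 <- sim_config(enrichment_log_odds = c(lymphoid = 0),
                     ensure_peak_at_causal = FALSE)
  set.seed(33)
  picks <- replicate(3000, plant_annotations_and_causals(10, cfg0, 1)$causal)
  expect_gt(stats::chisq.test(table(factor(picks, 1:10)))$p.value, 0.01)
})

test_that("simulate_z follows the RSS model z ~ MVN(R lambda, R)", {
  # null model: marginally standard normal
  set.seed(41)
  R <- simulate_ld(100, 0.9)
  z <- replicate(100, simulate_z(R, numeric(100)))
  expect_lt(abs(mean(abs(z) > 1.96) - 0.05), 0.01)

  # isolated causal: mean of z_j matches the non-centrality
  set.seed(42)
  lam <- c(5, rep(0, 4))
  zz <- replicate(1000, simulate_z(diag(5), lam))
  expect_lt(abs(mean(zz[1, ]) - 5), 0.1)

  # correlated neighbor picks up rho * lambda
  set.seed(43)
  R2 <- simulate_ld(5, 0.9)
  lam2 <- c(0, 0, 5, 0, 0)
  zz2 <- replicate(1000, simulate_z(R2, lam2))
  expect_lt(abs(mean(zz2[2, ]) - 4.5), 0.12)

  expect_error(simulate_z(matrix(c(1, 2, 2, 1), 2), c(0, 0)),
               "positive definite")
})

test_that("empirical covariance of simulated z converges to R", {
  set.seed(44)
  R <- simulate_ld(8, 0.8)
  z <- replicate(5000, simulate_z(R, numeric(8)))
  emp <- stats::cov(t(z))
  expect_lt(max(abs(emp - R)), 0.05)
})

test_that("simulate_two_traits respects the sharing fraction", {
  sim1 <- simulate_two_traits(sim_config(n_blocks = 6, fraction_shared = 1,
                                         seed = 51))
  expect_true(all(sim1$truth$shared))
  expect_true(all(sim1$truth$trait == "both"))
  expect_true(all(sim1$truth$lambda_A != 0 & sim1$truth$lambda_B != 0))

  sim0 <- simulate_two_traits(sim_config(n_blocks = 6, fraction_shared = 0,
                                         seed = 52))
  expect_false(any(sim0$truth$shared))
  expect_true(all(xor(sim0$truth$lambda_A != 0, sim0$truth$lambda_B != 0)))
})

test_that("a written dataset is byte-for-byte deterministic and loads back", {
  cfg <- sim_config(n_blocks = 3, seed = 61)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(simulate_two_traits(cfg), d1)
  write_dataset(simulate_two_traits(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  back <- read_dataset(d1)
  expect_length(back$blocks_A, 3L)
  expect_equal(back$blocks_A$block01$snp_id,
               simulate_two_traits(cfg)$blocks_A$block01$snp_id)
  expect_true(all(c("chrom", "start", "end", "cell_type", "lineage") %in%
                    names(back$peaks)))
  expect_true(all(back$mpra$label %in% c("+", "-")))
})

test_that("plant_evidence links every planted effector by >= 2 categories
           and only true links at decoy rate 0", {
  cfg <- sim_config(n_blocks = 4, decoy_rate = 0, seed = 71)
  sim <- simulate_two_traits(cfg)
  eff <- sim$truth_genes$effector_gene
  expect_true(all(sim$eqtl$gene %in% eff))
  expect_true(all(sim$loops$gene %in% eff))
  expect_true(all(sim$abc$gene %in% eff))

  # the planted gene is nominated for its causal element, by construction
  cres <- merge_peaks(sim$peaks)
  for (k in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[k, ]
    cre <- cres[cres$chrom == tr$chrom & cres$start < tr$pos &
                  tr$pos <= cres$end, ]
    expect_equal(nrow(cre), 1L)
    nom <- nominate_genes(cre, data.frame(snp_id = tr$snp_id, pip = 1),
                          sim$annotation, eqtl = sim$eqtl,
                          loops = sim$loops, abc = sim$abc)
    expect_true(sim$truth_genes$effector_gene[k] %in% nom$gene)
    cats <- nom$category[nom$gene == sim$truth_genes$effector_gene[k]]
    expect_gte(length(unique(cats)), 2L)
  }
})

test_that("decoy links raise the nominated-genes-per-CRE average above 1", {
  cfg <- sim_config(n_blocks = 8, decoy_rate = 0.5, seed = 72)
  sim <- simulate_two_traits(cfg)
  cres <- merge_peaks(sim$peaks)
  # count nominations over CREs overlapping any evidence anchor (<= 100)
  anchors <- rbind(
    data.frame(chrom = sim$loops$chromB, start = sim$loops$startB,
               end = sim$loops$endB),
    data.frame(chrom = sim$abc$chrom, start = sim$abc$start,
               end = sim$abc$end))
  touched <- unique(unlist(lapply(seq_len(nrow(anchors)), function(i) {
    which(cres$chrom == anchors$chrom[i] & cres$start < anchors$end[i] &
            anchors$start[i] < cres$end)
  })))
  touched <- head(touched, 100)
  n_nom <- vapply(touched, function(j) {
    length(unique(nominate_genes(cres[j, ], data.frame(snp_id = character(),
                                                       pip = numeric()),
                                 sim$annotation, eqtl = sim$eqtl,
                                 loops = sim$loops, abc = sim$abc)$gene))
  }, numeric(1))
  expect_gt(mean(n_nom), 1)
})
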