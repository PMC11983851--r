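mk_cs <- function(ids, pips, block = "blk1", cs = "cs1") {
  data.frame(block_id = block, cs = cs, snp_id = ids, pip = pips,
             stringsAsFactors = FALSE)
}

test_that("classify_sharing applies the SNP-majority and PIP-majority rules", {
  # 2/3 of each set shared -> shared
  a <- mk_cs(c("a", "b", "c"), c(0.3, 0.3, 0.3))
  b <- mk_cs(c("a", "b", "d"), c(0.3, 0.3, 0.3))
  expect_equal(classify_sharing(a, b)$status, "shared")

  # PIP rule: shared PIP within A = 0.5/0.9 > 0.5 -> shared even though
  # the SNP overlap is only half of each set
  a2 <- mk_cs(c("a", "b"), c(0.5, 0.4))
  b2 <- mk_cs(c("a", "c"), c(0.5, 0.45))
  call <- classify_sharing(a2, b2)
  expect_equal(call$status, "shared")
  expect_gt(call$shared_pip_frac_a, 0.5)

  # disjoint -> specific
  expect_equal(classify_sharing(mk_cs("a", 0.9), mk_cs("b", 0.9))$status,
               "specific")

  # exactly half the SNPs and half the PIP does not fire (strict rule)
  a3 <- mk_cs(c("a", "b"), c(0.5, 0.5))
  b3 <- mk_cs(c("a", "c"), c(0.5, 0.5))
  expect_equal(classify_sharing(a3, b3)$status, "specific")

  expect_error(classify_sharing(a, b, "blk1", "blk2"), "different LD blocks")
})

test_that("classify_sharing is symmetric in shared/not-shared", {
  set.seed(101)
  for (rep in 1:20) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    univ <- paste0("s", 1:8)
    a <- mk_cs(sample(univ, na), runif(na))
    b <- mk_cs(sample(univ, nb), runif(nb))
    expect_equal(classify_sharing(a, b)$status, classify_sharing(b, a)$status)
  }
})

test_that("sharing_calls + summarize_sharing count each set once", {
  csA <- rbind(mk_cs(c("a", "b"), c(0.5, 0.4), "blk1", "cs1"),
               mk_cs("x", 0.9, "blk2", "cs2"))
  csB <- rbind(mk_cs(c("a", "b"), c(0.6, 0.3), "blk1", "cs1"),
               mk_cs("y", 0.9, "blk2", "cs2"))
  calls <- sharing_calls(csA, csB, "A", "B")
  sm <- summarize_sharing(calls)
  expect_equal(sm$n_shared_pairs, 1L)
  expect_equal(sm$n_shared_sets, 2L)
  # unit accounting: 1 shared unit among (4 - 1) units
  expect_equal(sm$fraction_shared_units, 1 / 3)
  expect_equal(sm$fraction_shared_sets, 0.5)
  st <- sm$set_status
  expect_equal(st$status[st$trait == "A" & st$cs == "cs2"], "A-specific")

  # no overlaps anywhere -> 0% shared
  calls0 <- sharing_calls(mk_cs("a", 1, "blk1", "cs1"),
                          mk_cs("b", 1, "blk1", "cs1"), "A", "B")
  expect_equal(summarize_sharing(calls0)$fraction_shared_units, 0)
})

test_that("attribute_lineages splits PIP across lineages and none", {
  peaks <- data.frame(
    chrom = "chr1", start = c(999, 999, 4999), end = c(1200, 1200, 5200),
    lineage = c("lymphoid", "epithelial", "epithelial"),
    stringsAsFactors = FALSE)
  # all SNPs only in lymphoid OCRs
  cs1 <- data.frame(chrom = "chr1", pos = c(1000, 1100), pip = c(0.5, 0.3))
  pr1 <- attribute_lineages(cs1, peaks[1, ], lineages = "lymphoid")
  expect_equal(unname(pr1["lymphoid"]), 1)

  # one SNP (0.8) in no OCR, one (0.2) in epithelial only
  cs2 <- data.frame(chrom = "chr1", pos = c(9000, 5000), pip = c(0.8, 0.2))
  pr2 <- attribute_lineages(cs2, peaks[3, ], lineages = "epithelial")
  expect_equal(unname(pr2), c(0.2, 0.8))      # epithelial, none

  # SNP overlapping OCRs of two lineages splits its PIP equally
  cs3 <- data.frame(chrom = "chr1", pos = 1000, pip = 0.6)
  pr3 <- attribute_lineages(cs3, peaks,
                            lineages = c("lymphoid", "epithelial"))
  expect_equal(unname(pr3[c("lymphoid", "epithelial")]), c(0.5, 0.5))

  expect_error(attribute_lineages(cs1[0, ], peaks), "empty")

  # proportions always sum to 1; removing all OCRs puts everything in none
  set.seed(102)
  cs4 <- data.frame(chrom = "chr1", pos = sample(1e4, 5), pip = runif(5))
  expect_equal(sum(attribute_lineages(cs4, peaks)), 1)
  pr_none <- attribute_lineages(cs4, peaks[0, ], lineages = "lymphoid")
  expect_equal(unname(pr_none["none"]), 1)
})

test_that("confidence_bins uses the half-open boundaries exactly", {
  bins <- confidence_bins(c(0.5, 0.8, 0.05, 0.1, 0.100001, 0.81, 0.5001))
  expect_equal(unname(bins["low"]), 2L)   # 0.5 and 0.100001
  expect_equal(unname(bins["mid"]), 2L)   # 0.8 and 0.5001
  expect_equal(unname(bins["high"]), 1L)  # 0.81
  expect_error(confidence_bins(c(0.5, 1.2)))
})

test_that("compare_prior_modes reports percent changes with NA on empty
           uniform bins", {
  expect_equal(compare_prior_modes(c(low = 13, mid = 5, high = 6),
                                   c(low = 10, mid = 5, high = 4)),
               c(low = 30, mid = 0, high = 50))
  expect_equal(compare_prior_modes(c(low = 2, mid = 2, high = 2),
                                   c(low = 2, mid = 2, high = 2)),
               c(low = 0, mid = 0, high = 0))
  out <- compare_prior_modes(c(low = 1, mid = 0, high = 3),
                             c(low = 1, mid = 0, high = 0))
  expect_true(is.na(out["high"]))
  expect_true(is.na(out["mid"]))
})

test_that("planted shared signals are recovered as shared on synthetic
           two-trait data", {
  set.seed(103)
  frac <- numeric(0)
  shared_ok <- 0; shared_tot <- 0
  for (rep in 1:8) {
    sim <- simulate_two_traits(sim_config(n_blocks = 8, n_signals = 1,
                                          fraction_shared = 0.5,
                                          seed = 7000 + rep))
    fA <- finemap_blocks(lapply(sim$blocks_A, function(b) {
      b$prior <- NULL; b
    }), trait = "A")
    fB <- finemap_blocks(lapply(sim$blocks_B, function(b) {
      b$prior <- NULL; b
    }), trait = "B")
    calls <- sharing_calls(fA$cs_snps, fB$cs_snps, "A", "B")
    sm <- summarize_sharing(calls)
    frac <- c(frac, sm$fraction_shared_units)
    for (k in which(sim$truth$shared)) {
      inA <- fA$cs_snps$cs[match(sim$truth$snp_id[k], fA$cs_snps$snp_id)]
      inB <- fB$cs_snps$cs[match(sim$truth$snp_id[k], fB$cs_snps$snp_id)]
      if (is.na(inA) || is.na(inB)) next     # not resolvable in both traits
      shared_tot <- shared_tot + 1
      pair <- calls[calls$cs_a == inA & calls$cs_b == inB, ]
      if (nrow(pair) == 1 && pair$status == "shared") {
        shared_ok <- shared_ok + 1
      }
    }
  }
  expect_lt(abs(median(frac) - 0.5), 0.15)
  expect_gte(shared_ok / shared_tot, 0.9)
})
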