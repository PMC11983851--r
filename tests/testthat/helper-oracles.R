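# Independent oracles used to freeze expected values. These deliberately do
# not share code paths with the package implementation.

# Wakefield ABF by numerical quadrature over the effect prior: the effect
# estimate is beta_hat = z * se with se = 1/sqrt(n); the marginal likelihood
# under association integrates N(beta_hat; b, se^2) against N(b; 0, W).
quad_log_abf <- function(z, n, W) {
  se <- 1 / sqrt(n)
  beta_hat <- z * se
  num <- stats::integrate(function(b) {
    stats::dnorm(beta_hat, mean = b, sd = se) *
      stats::dnorm(b, mean = 0, sd = sqrt(W))
  }, lower = -Inf, upper = Inf, rel.tol = 1e-12)$value
  log(num) - stats::dnorm(beta_hat, mean = 0, sd = se, log = TRUE)
}

# Exact one-causal posterior over a block by enumeration: per-SNP Bayes
# factor is the density ratio N(z; 0, 1 + s0) / N(z; 0, 1) on the
# non-centrality scale.
enum_single_causal <- function(z, prior, s0) {
  bf <- stats::dnorm(z, 0, sqrt(1 + s0)) / stats::dnorm(z, 0, 1)
  w <- prior * bf
  w / sum(w)
}

# Brute-force interval merging via the O(n^2) overlap graph + union-find;
# intervals merge iff they overlap by >= 1 bp (bookended stay apart).
brute_merge <- function(df) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && df$chrom[i] == df$chrom[j] &&
          df$start[i] < df$end[j] && df$start[j] < df$end[i]) {
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    data.frame(chrom = df$chrom[idx[1L]], start = min(df$start[idx]),
               end = max(df$end[idx]), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# convenience builder for a fine-mapping block
make_block <- function(z, R, id = "b1", chrom = "chr1",
                       pos = 10000L + seq_along(z) * 300L, prior = NULL) {
  list(block_id = id, chrom = rep(chrom, length(z)),
       snp_id = paste0(id, "_snp", seq_along(z)), pos = pos, z = z,
       n = 10000L, R = R, prior = prior)
}
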