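# Empirical-Bayes annotation enrichment: per-SNP causal priors are a logistic
# function of binary annotations; coefficients are estimated by EM under an
# at-most-one-causal-per-LD-block approximation with Wakefield Bayes factors
# summarizing the association evidence.

#' Wakefield log approximate Bayes factor
#'
#' Log Bayes factor of association vs null for a z-score, under a normal
#' effect prior with variance `W` on the standardized scale, where the
#' standard error of the standardized effect is `1/sqrt(n)`:
#' `logABF = 0.5 * log(se^2 / (se^2 + W)) + z^2 * W / (2 * (se^2 + W))`.
#' Symmetric in the sign of `z`. When `W` is a grid of length > 1, the grid
#' ABFs are averaged with equal weights (on the BF scale) and the log of the
#' average is returned.
#'
#' @param z Signed z-score(s).
#' @param n GWAS sample size.
#' @param W Effect-size prior variance, or a grid of variances.
#' @return log ABF, vectorized over `z`.
#' @export
wakefield_abf <- function(z, n, W = 0.04) {
  if (any(W <= 0)) stop("prior variance W must be > 0")
  if (n < 1) stop("n must be >= 1")
  se2 <- 1 / n
  labf <- vapply(W, function(w) {
    0.5 * log(se2 / (se2 + w)) + z^2 * w / (2 * (se2 + w))
  }, numeric(length(z)))
  labf <- matrix(labf, nrow = length(z))
  if (length(W) == 1L) return(drop(labf))
  # equal-weight model average over the grid, computed stably in log space
  m <- apply(labf, 1L, max)
  m + log(rowMeans(exp(labf - m)))
}

#' Fit the annotation enrichment model by EM
#'
#' Estimates log-odds enrichment coefficients for binary annotations from
#' GWAS z-scores, assuming at most one causal variant per LD block. The
#' E-step computes, within each block, the posterior probability that SNP j
#' is the causal one: with prior odds `o_j = pi_j / (1 - pi_j)` and Wakefield
#' Bayes factor `ABF_j`, the block posterior is
#' `gamma_j = o_j ABF_j / (1 + sum_k o_k ABF_k)` (the exact one-causal form;
#' the leading 1 is the no-causal outcome with weight `prod(1 - pi)` shared
#' by all configurations). The M-step refits a weighted logistic regression
#' of `gamma` on the annotations. The marginal log-likelihood (up to a
#' constant) is non-decreasing over iterations.
#'
#' @param blocks List of blocks, each a list with elements `z` (z-scores),
#'   `n` (sample size) and `A` (SNPs x annotations binary matrix with named
#'   columns; may have zero columns for an intercept-only model).
#' @param W Effect prior variance (or grid) for [wakefield_abf()].
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return Object of class `enrichment_model`: list with `coef` (named,
#'   includes `(Intercept)`), `se`, `zval`, `pval`, `loglik_trace`,
#'   `converged`, `dropped` (zero-variance annotation columns), and
#'   `annotations` (column names used).
#' @export
fit_enrichment <- function(blocks, W = 0.04, tol = 1e-5, max_iter = 200L) {
  stopifnot(length(blocks) >= 1L)
  A_list <- lapply(blocks, function(b) {
    A <- b$A
    if (is.null(A)) A <- matrix(0, length(b$z), 0L)
    A
  })
  ann_names <- colnames(A_list[[1L]])
  A <- do.call(rbind, A_list)
  block_id <- rep(seq_along(blocks), vapply(blocks, function(b) length(b$z),
                                            integer(1)))
  labf <- unlist(lapply(blocks, function(b) wakefield_abf(b$z, b$n, W)))

  dropped <- character(0)
  if (ncol(A) > 0L) {
    keep <- apply(A, 2L, function(col) stats::var(col) > 0)
    if (any(!keep)) {
      dropped <- colnames(A)[!keep]
      warning("annotation column(s) without variation dropped: ",
              paste(dropped, collapse = ", "))
      A <- A[, keep, drop = FALSE]
    }
  }

  coef <- c(`(Intercept)` = qlogis(min(0.5, 1 / max(table(block_id)))),
            setNames(rep(0, ncol(A)), colnames(A)))
  X <- cbind(`(Intercept)` = 1, A)
  ll_trace <- numeric(0)
  converged <- FALSE
  fit <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% coef)
    pi_j <- pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
    log_w <- log(pi_j) - log1p(-pi_j) + labf
    # block-wise posterior over {no causal, SNP j causal}
    gamma <- numeric(length(log_w))
    ll <- 0
    for (b in split(seq_along(log_w), block_id)) {
      m <- max(0, log_w[b])
      denom <- exp(-m) + sum(exp(log_w[b] - m))
      gamma[b] <- exp(log_w[b] - m) / denom
      ll <- ll + sum(log1p(-pi_j[b])) + m + log(denom)
    }
    ll_trace <- c(ll_trace, ll)
    if (it > 1L) {
      rel <- abs(ll - ll_trace[it - 1L]) / (abs(ll_trace[it - 1L]) + 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
    # M-step: fractional-response logistic fit of gamma on annotations
    dat <- data.frame(gamma = gamma, A, check.names = FALSE)
    form <- if (ncol(A) > 0L) {
      stats::as.formula(paste("gamma ~",
                              paste(sprintf("`%s`", colnames(A)),
                                    collapse = " + ")))
    } else {
      gamma ~ 1
    }
    fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                       data = dat))
    coef <- setNames(stats::coef(fit), c("(Intercept)", colnames(A)))
  }
  if (!converged) warning("enrichment EM did not converge in ", max_iter,
                          " iterations")
  if (is.null(fit)) { # converged at iteration 1 (degenerate input)
    dat <- data.frame(gamma = gamma, A, check.names = FALSE)
    fit <- suppressWarnings(stats::glm(gamma ~ 1, family = stats::binomial(),
                                       data = dat))
  }
  sm <- suppressWarnings(summary(fit)$coefficients)
  se <- setNames(rep(NA_real_, length(coef)), names(coef))
  se[rownames(sm) == "(Intercept)"] <- sm["(Intercept)", "Std. Error"]
  for (nm in names(coef)[-1L]) {
    rn <- intersect(c(nm, sprintf("`%s`", nm)), rownames(sm))
    if (length(rn) > 0L) se[nm] <- sm[rn[1L], "Std. Error"]
  }
  zval <- coef / se
  structure(list(coef = coef, se = se, zval = zval,
                 pval = 2 * pnorm(-abs(zval)),
                 loglik_trace = ll_trace, converged = converged,
                 n_iter = length(ll_trace), dropped = dropped,
                 annotations = names(coef)[-1L]),
            class = "enrichment_model")
}

#' @export
print.enrichment_model <- function(x, ...) {
  cat("Annotation enrichment model (", x$n_iter, " EM iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  print(data.frame(log_odds = x$coef, se = x$se, z = x$zval, p = x$pval))
  invisible(x)
}

#' Convert an enrichment model into per-SNP functional priors
#'
#' `pi_j = logistic(alpha0 + sum_k alpha_k a_jk)`, clipped to
#' `[1e-6, 1 - 1e-6]`.
#'
#' @param model `enrichment_model` from [fit_enrichment()].
#' @param A Binary annotation matrix (SNPs x annotations) whose columns match
#'   the model's annotations (dropped columns are ignored).
#' @return Numeric vector of per-SNP prior probabilities.
#' @export
compute_priors <- function(model, A) {
  if (is.null(A)) A <- matrix(0, 1L, 0L)
  anns <- model$annotations
  if (length(anns) > 0L) {
    if (!all(anns %in% colnames(A))) {
      stop("annotation matrix lacks model column(s): ",
           paste(setdiff(anns, colnames(A)), collapse = ", "))
    }
    A <- A[, anns, drop = FALSE]
  } else {
    A <- matrix(0, nrow(A), 0L)
  }
  eta <- rep(unname(model$coef[1L]), nrow(A)) +
    if (ncol(A) > 0L) drop(A %*% model$coef[-1L]) else 0
  pmin(pmax(plogis(eta), 1e-6), 1 - 1e-6)
}

#' Uniform priors over a block
#' @param p Number of SNPs in the block.
#' @return Vector of `1/p` repeated `p` times.
#' @export
uniform_priors <- function(p) rep(1 / p, p)

#' Screen annotations by the enrichment model's Wald test
#'
#' Returns the annotation names with positive log-odds and Wald p < `alpha`,
#' i.e. the lineages considered significantly enriched and passed on to the
#' functional priors.
#'
#' @param model `enrichment_model`.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of enriched annotation names.
#' @export
enriched_annotations <- function(model, alpha = 0.05) {
  k <- model$annotations
  k[!is.na(model$pval[k]) & model$pval[k] < alpha & model$coef[k] > 0]
}
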