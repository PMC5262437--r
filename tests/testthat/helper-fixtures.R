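# Shared fixtures, built in code and memoised per test session.

.fixtures <- new.env(parent = emptyenv())

# A small analysis-ready cohort used by several module tests.
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- sim_config(
      n_target = 300, n_discovery = 2000, m_snps = 800, block_size = 20,
      rho = 0.5, n_genes = 40, gene_span_snps = 10,
      pathways = stats::setNames(rep(4L, 8),
        c("causal_pathway", sprintf("null_%02d", 1:7))),
      h2_pathway = 0.12, h2_background = 0.15,
      case_fraction = 0.5, seed = 314L)
    .fixtures$small <- simulate_cohort(cfg)
  }
  .fixtures$small
}

# Tiny genotype matrix with known content for I/O tests.
toy_genotypes <- function(n = 5, m = 10, seed = 9, missing = 0) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 2, 0.4), n, m)
  if (missing > 0) X[sample(length(X), missing)] <- NA
  ids <- sprintf("ind%02d", seq_len(n))
  rownames(X) <- ids
  snps <- data.frame(snp_id = sprintf("rs%03d", seq_len(m)), chr = 1L,
                     pos = seq_len(m) * 1000L, a1 = "A", a2 = "G",
                     maf = pmin(colMeans(X, na.rm = TRUE) / 2,
                                1 - colMeans(X, na.rm = TRUE) / 2),
                     info = 1, stringsAsFactors = FALSE)
  colnames(X) <- snps$snp_id
  structure(list(dosage = X, snps = snps, ids = ids), class = "genotypes")
}

# Restricted log-likelihood oracle: dense profiled grid search over the
# heritability ratio for a single-GRM model (intercept-only fixed effects),
# matching reml_fit's likelihood constant.  Independent of the AI-REML path.
grid_reml_loglik <- function(y, A, h_grid = NULL) {
  n <- length(y)
  X <- matrix(1, n, 1)
  prof <- function(h) {
    V0 <- h * A + (1 - h) * diag(n)
    ch <- chol(V0)
    Vi <- chol2inv(ch)
    XtVX <- crossprod(X, Vi %*% X)
    P0 <- Vi - (Vi %*% X) %*% solve(XtVX) %*% crossprod(X, Vi)
    q <- sum(y * (P0 %*% y))
    s2 <- q / (n - 1)
    -0.5 * (2 * sum(log(diag(ch))) + n * log(s2) +
            log(XtVX[1, 1]) - log(s2) + (n - 1))
  }
  coarse <- h_grid
  if (is.null(coarse)) coarse <- seq(0.001, 0.999, length.out = 200)
  ll <- vapply(coarse, prof, 0)
  i <- which.max(ll)
  lo <- coarse[max(1, i - 1)]; hi <- coarse[min(length(coarse), i + 1)]
  fine <- seq(lo, hi, length.out = 400)
  max(vapply(fine, prof, 0))
}
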