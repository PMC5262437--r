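# Stage 1 pathway association.
#
# Two engines: a summary-statistic engine (gene min-p scores corrected for
# gene size confounders, 95th-percentile enrichment against random gene
# sets) and a genotype engine (per-gene eigenSNPs entering a
# ridge-penalised logistic regression, tested by phenotype permutation).

#' Per-gene minimum SNP p-value scores
#'
#' Raw gene score = the minimum summary p over the gene's SNPs.  Genes
#' mapping to no SNP with a p-value are dropped (count reported as an
#' attribute).
#'
#' @param summary data.frame of summary statistics with columns `SNP`, `P`.
#' @param gene_map named list gene_id -> SNP row indices into `summary`
#'   (from [map_snps_to_genes()]).
#' @param genes optional gene table supplying `start`/`end` for the gene
#'   length covariate; lengths default to the SNP bp span.
#' @return data.frame: gene_id, min_p, n_snps, gene_kb.
#' @export
gene_min_p <- function(summary, gene_map, genes = NULL) {
  keep <- vapply(gene_map, function(i) length(i) > 0 && any(!is.na(summary$P[i])),
                 TRUE)
  if (!any(keep)) stop_param("every gene is empty: nothing to score")
  gm <- gene_map[keep]
  min_p <- vapply(gm, function(i) min(summary$P[i], na.rm = TRUE), 0)
  n_snps <- vapply(gm, function(i) sum(!is.na(summary$P[i])), 0L)
  if (!is.null(genes)) {
    gi <- match(names(gm), genes$gene_id)
    gene_kb <- (genes$end[gi] - genes$start[gi] + 1) / 1000
  } else if (!is.null(summary$BP)) {
    gene_kb <- vapply(gm, function(i)
      (max(summary$BP[i]) - min(summary$BP[i]) + 1) / 1000, 0)
  } else gene_kb <- n_snps / 1
  out <- data.frame(gene_id = names(gm), min_p = min_p, n_snps = n_snps,
                    gene_kb = gene_kb, stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Confounder-corrected gene scores
#'
#' Min-p gene scores are biased by gene size: more SNPs give smaller
#' minima.  -log10(min p) is regressed on SNP count and gene length (kb);
#' the residual is ranked and mapped to an adjusted p = rank / (n + 1)
#' (rank 1 = largest residual = most associated).  With degenerate
#' (constant) regressors the unadjusted ranks are used with a warning.
#'
#' @param gene_table output of [gene_min_p()].
#' @return the table with `residual` and `adj_p` columns appended.
#' @export
adjust_gene_scores <- function(gene_table) {
  n <- nrow(gene_table)
  if (n < 30) warning("fewer than 30 genes: confounder fit may be unstable")
  score <- -log10(pmax(gene_table$min_p, 1e-300))
  dx <- stats::sd(gene_table$n_snps) > 0 || stats::sd(gene_table$gene_kb) > 0
  if (!dx) {
    warning("degenerate regressors: falling back to unadjusted ranks")
    resid <- score
  } else {
    fit <- stats::lm(score ~ n_snps + gene_kb, data = gene_table)
    resid <- stats::residuals(fit)
  }
  r <- rank(-resid, ties.method = "first")
  gene_table$residual <- resid
  gene_table$adj_p <- r / (n + 1)
  gene_table
}

#' Percentile-cutoff pathway enrichment from gene scores
#'
#' For each pathway: observed = number of member genes with adjusted p at
#' or below the (100 - cutoff_pct)th percentile of all genes' adjusted
#' p-values; expected = effective size x (1 - cutoff_pct / 100).  The
#' nominal p is the probability that a random same-size gene set attains
#' a count >= observed; random sets drawn without replacement make that
#' count hypergeometric, so the `n_null` null draws are taken with
#' `rhyper` (distributionally identical to materialising the sets),
#' p = (r + 1) / (n_null + 1).
#'
#' @param adjusted output of [adjust_gene_scores()].
#' @param pathway_db named list pathway -> gene ids.
#' @param cutoff_pct enrichment percentile (default 95).
#' @param n_null number of null gene-set draws (>= 1000).
#' @param seed RNG seed for the null draws.
#' @return data.frame: pathway, p, eff_gene_size, exp_count, obs_count.
#' @export
magenta_enrichment <- function(adjusted, pathway_db, cutoff_pct = 95,
                               n_null = 10000, seed = 1L) {
  if (n_null < 1000) stop_param("n_null must be >= 1000")
  cut_q <- stats::quantile(adjusted$adj_p, 1 - cutoff_pct / 100, names = FALSE)
  above <- adjusted$adj_p <= cut_q        # "exceeds the 95th percentile cutoff"
  N <- nrow(adjusted); Ktop <- sum(above)
  rows <- with_seed(seed, lapply(names(pathway_db), function(pw) {
    gi <- match(pathway_db[[pw]], adjusted$gene_id)
    gi <- gi[!is.na(gi)]
    if (!length(gi)) {
      warning(sprintf("pathway '%s' maps to no scored genes: skipped", pw))
      return(NULL)
    }
    eff <- length(gi)
    obs <- sum(above[gi])
    nulls <- stats::rhyper(n_null, Ktop, N - Ktop, eff)
    r <- sum(nulls >= obs)
    data.frame(pathway = pw, p = (r + 1) / (n_null + 1),
               eff_gene_size = eff,
               exp_count = round(eff * (1 - cutoff_pct / 100), 1),
               obs_count = obs, stringsAsFactors = FALSE)
  }))
  do.call(rbind, rows)
}

#' Gene eigenSNPs: principal components of a gene's genotypes
#'
#' Columns of the returned matrix are PC scores of the gene's
#' standardized dosages, keeping the smallest number of components whose
#' cumulative variance reaches `var_explained` (default 0.95).
#'
#' @param genotypes `genotypes` object or dosage matrix.
#' @param snp_idx SNP column indices of the gene.
#' @param var_explained fraction of genotypic variance to retain.
#' @return n x k score matrix with attribute `var_explained`, or NULL if
#'   every SNP is monomorphic (gene dropped with a warning).
#' @export
grass_gene_eigensnps <- function(genotypes, snp_idx, var_explained = 0.95) {
  X <- if (inherits(genotypes, "genotypes")) genotypes$dosage else genotypes
  X <- impute_mean(X[, snp_idx, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  if (all(sds == 0)) {
    warning("all SNPs monomorphic: gene dropped")
    return(NULL)
  }
  Z <- scale(X[, sds > 0, drop = FALSE])
  sv <- svd(Z)
  var_frac <- cumsum(sv$d^2) / sum(sv$d^2)
  k <- which(var_frac >= var_explained)[1]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("eigenSNP", seq_len(k))
  attr(scores, "var_explained") <- var_frac[k]
  scores
}

# Ridge-penalised logistic regression by IRLS; `penalty` is a per-column
# vector (0 = unpenalised, e.g. intercept and covariates).  Returns the
# *unpenalised* deviance of the fitted probabilities.
ridge_logistic <- function(X, y, lambda, penalty, max_iter = 50L, tol = 1e-8) {
  p <- ncol(X)
  D <- diag(lambda * penalty, p)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X, X * w) + D
    bnew <- tryCatch(solve(H, crossprod(X, w * z)),
                     error = function(e) beta)
    if (max(abs(bnew - beta)) < tol) { beta <- bnew; break }
    beta <- bnew
  }
  eta <- as.numeric(X %*% beta)
  mu <- stats::plogis(eta)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(beta = as.numeric(beta), deviance = dev)
}

# 5-fold cross-validated deviance over a lambda grid (unpermuted data only;
# the chosen penalty is then fixed for every permutation).
cv_ridge_lambda <- function(X, y, penalty, grid, folds = 5L) {
  n <- length(y)
  fold <- rep_len(seq_len(folds), n)[sample.int(n)]
  cvdev <- vapply(grid, function(lam) {
    tot <- 0
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- ridge_logistic(X[tr, , drop = FALSE], y[tr], lam, penalty)
      mu <- stats::plogis(as.numeric(X[!tr, , drop = FALSE] %*% fit$beta))
      mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      tot <- tot - 2 * sum(y[!tr] * log(mu) + (1 - y[!tr]) * log(1 - mu))
    }
    tot
  }, 0)
  grid[which.min(cvdev)]
}

#' Genotype-based pathway association test (eigenSNP ridge + permutation)
#'
#' Builds eigenSNPs for every gene in the pathway, fits a ridge-penalised
#' logistic regression of the phenotype on all pathway eigenSNPs plus
#' covariates, and takes the deviance reduction relative to the
#' covariates-only model as the test statistic.  The ridge penalty is
#' chosen once by 5-fold cross-validated deviance on the unpermuted data
#' and held fixed; significance comes from phenotype permutations,
#' p = (r + 1) / (n_perm + 1).
#'
#' @param genotypes `genotypes` object or dosage matrix.
#' @param phenotype 0/1 vector (both classes required).
#' @param covariates data.frame/matrix or NULL.
#' @param gene_snp_sets named list gene -> SNP column indices (the
#'   pathway's genes).
#' @param n_perm number of phenotype permutations (>= 999 recommended;
#'   >= 99 accepted for calibration studies).
#' @param seed RNG seed (CV folds + permutations).
#' @param var_explained eigenSNP variance threshold per gene.
#' @param lambda optional fixed ridge penalty (skips CV).
#' @return list(statistic, p, lambda, n_components, n_perm).
#' @export
grass_pathway_test <- function(genotypes, phenotype, covariates, gene_snp_sets,
                               n_perm = 999, seed = 1L, var_explained = 0.95,
                               lambda = NULL) {
  y <- as.numeric(phenotype)
  if (length(unique(y)) < 2) stop_param("phenotype has a single class")
  comps <- Filter(Negate(is.null), lapply(gene_snp_sets, function(idx)
    grass_gene_eigensnps(genotypes, idx, var_explained)))
  if (!length(comps)) stop_param("pathway maps to no polymorphic SNPs")
  E <- scale(do.call(cbind, comps))
  C <- if (!is.null(covariates)) scale(as.matrix(covariates)) else NULL
  X0 <- cbind(rep(1, length(y)), C)
  X1 <- cbind(X0, E)
  penalty <- c(rep(0, ncol(X0)), rep(1, ncol(E)))
  with_seed(seed, {
    if (is.null(lambda)) {
      grid <- 2^seq(-4, 8, by = 2)
      lambda <- cv_ridge_lambda(X1, y, penalty, grid)
    }
    dev0 <- ridge_logistic(X0, y, 0, rep(0, ncol(X0)))$deviance
    stat <- dev0 - ridge_logistic(X1, y, lambda, penalty)$deviance
    perm_stats <- vapply(seq_len(n_perm), function(b) {
      yp <- sample(y)
      d0 <- ridge_logistic(X0, yp, 0, rep(0, ncol(X0)))$deviance
      d0 - ridge_logistic(X1, yp, lambda, penalty)$deviance
    }, 0)
    r <- sum(perm_stats >= stat)
    list(statistic = stat, p = (r + 1) / (n_perm + 1), lambda = lambda,
         n_components = ncol(E), n_perm = n_perm)
  })
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values via `stats::p.adjust(method = "BH")` (the referent
#' implementation), monotone and capped at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of adjusted values.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment
#'
#' @param p p-value(s).
#' @param n_tests family size (>= 1).
#' @return min(1, p * n_tests).
#' @export
bonferroni <- function(p, n_tests) {
  if (n_tests < 1) stop_param("n_tests must be >= 1")
  pmin(1, p * n_tests)
}
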