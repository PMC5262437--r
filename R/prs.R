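# Polygenic risk profiling: LD clumping, p-value-thresholded scores,
# fixed-effect evaluation (logistic regression, Nagelkerke delta-R2,
# Mann-Whitney AUC) and the PRS-bin-relationship-matrix random-effect
# model fitted by REML.

#' Greedy LD clumping of summary statistics
#'
#' Sort by discovery p ascending; keep the best unclaimed SNP and remove
#' every SNP within `window_kb` whose squared correlation with it (in the
#' target genotypes) exceeds `r2_threshold`; repeat.
#'
#' @param summary summary-statistics data.frame (`SNP`, `P`, `CHR`, `BP`).
#' @param genotypes target-panel `genotypes` (LD source), SNP columns
#'   matched to `summary$SNP` by name.
#' @param r2_threshold clumping r2 (default 0.25).
#' @param window_kb physical window in kb (default 250).
#' @return character vector of kept SNP ids.
#' @export
clump <- function(summary, genotypes, r2_threshold = 0.25, window_kb = 250) {
  X <- impute_mean(genotypes$dosage)
  keep_cols <- match(summary$SNP, colnames(X))
  ord <- order(summary$P)
  claimed <- rep(FALSE, nrow(summary))
  kept <- logical(nrow(summary))
  w <- window_kb * 1000
  for (i in ord) {
    if (claimed[i]) next
    kept[i] <- TRUE
    claimed[i] <- TRUE
    near <- which(!claimed & summary$CHR == summary$CHR[i] &
                  abs(summary$BP - summary$BP[i]) <= w)
    if (!length(near)) next
    xi <- X[, keep_cols[i]]
    if (stats::sd(xi) == 0) next
    r <- suppressWarnings(stats::cor(xi, X[, keep_cols[near], drop = FALSE]))
    r[is.na(r)] <- 0
    claimed[near[r[1, ]^2 > r2_threshold]] <- TRUE
  }
  summary$SNP[kept]
}

#' Compute a polygenic risk score
#'
#' score_i = sum over SNPs with discovery p <= cutoff of
#' dosage_is x weight_s, weight = log(OR) from the discovery summary.
#' Dosages are flipped (2 - x) when the panel's effect allele is the
#' summary's other allele; SNPs whose alleles cannot be reconciled are
#' dropped (count recorded in the `n_dropped` attribute).
#'
#' @param genotypes target `genotypes` object.
#' @param weights data.frame with `SNP`, `A1`, `A2` (optional), `OR` (or
#'   `BETA`), `P`.
#' @param p_cutoff discovery p-value inclusion threshold in (0, 1].
#' @param snp_subset optional character vector restricting the score to a
#'   SNP set (e.g. a pathway or a clumped set).
#' @return numeric score per individual with attributes `n_snps_used`,
#'   `n_dropped`.
#' @export
compute_prs <- function(genotypes, weights, p_cutoff = 1, snp_subset = NULL) {
  w <- weights
  if (is.null(w$BETA)) w$BETA <- log(w$OR)
  w <- w[is.finite(w$BETA) & !is.na(w$P) & w$P <= p_cutoff, , drop = FALSE]
  if (!is.null(snp_subset)) w <- w[w$SNP %in% snp_subset, , drop = FALSE]
  snps <- genotypes$snps
  j <- match(w$SNP, snps$snp_id)
  ok <- !is.na(j)
  w <- w[ok, , drop = FALSE]; j <- j[ok]
  same <- w$A1 == snps$a1[j]
  flipped <- !same & (is.null(w$A2) | w$A1 == snps$a2[j])
  usable <- same | flipped
  n_dropped <- sum(!usable)
  w <- w[usable, , drop = FALSE]; j <- j[usable]
  flipped <- flipped[usable]
  X <- impute_mean(genotypes$dosage[, j, drop = FALSE])
  if (any(flipped)) X[, flipped] <- 2 - X[, flipped]
  score <- if (nrow(w)) as.numeric(X %*% w$BETA) else numeric(nrow(genotypes$dosage))
  attr(score, "n_snps_used") <- nrow(w)
  attr(score, "n_dropped") <- n_dropped
  score
}

#' Nagelkerke pseudo-R2 of a fitted binary model
#'
#' R2_N = (1 - (L0/L1)^(2/n)) / (1 - L0^(2/n)), L0 the intercept-only
#' likelihood and L1 the model likelihood.
#'
#' @param loglik1,loglik0 model and intercept-only log-likelihoods.
#' @param n sample size.
#' @return scalar in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(loglik1, loglik0, n) {
  cs <- 1 - exp(2 * (loglik0 - loglik1) / n)
  maxr2 <- 1 - exp(2 * loglik0 / n)
  cs / maxr2
}

#' Fixed-effect PRS evaluation by logistic regression
#'
#' Delta Nagelkerke R2 = R2_N(covariates + PRS) - R2_N(covariates only),
#' both against the intercept-only null, with the association p from the
#' PRS Wald test.  Complete separation triggers a ridge-stabilised
#' refit (flagged in the result).
#'
#' @param y 0/1 phenotype (both classes required).
#' @param prs numeric score vector.
#' @param covariates data.frame/matrix or NULL.
#' @return list(delta_r2, r2_full, r2_cov, p, beta_prs, separation).
#' @export
logistic_eval <- function(y, prs, covariates = NULL) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop_param("phenotype has a single class")
  C <- if (!is.null(covariates)) as.matrix(covariates) else NULL
  df <- data.frame(y = y, prs = as.numeric(prs))
  if (!is.null(C)) df <- cbind(df, as.data.frame(C))
  f_cov <- if (is.null(C)) y ~ 1 else
    stats::as.formula(paste("y ~", paste(colnames(C), collapse = " + ")))
  f_full <- stats::update(f_cov, . ~ . + prs)
  fit0 <- stats::glm(y ~ 1, family = stats::binomial(), data = df)
  fitc <- stats::glm(f_cov, family = stats::binomial(), data = df)
  fitf <- suppressWarnings(stats::glm(f_full, family = stats::binomial(), data = df))
  separation <- any(fitf$fitted.values < 1e-8 | fitf$fitted.values > 1 - 1e-8)
  if (separation || !fitf$converged) {
    # ridge-stabilised fallback: tiny L2 penalty on the PRS coefficient
    X <- cbind(1, C, prs = df$prs)
    pen <- c(rep(0, ncol(X) - 1), 1e-4)
    rf <- ridge_logistic(X, y, 1, pen)
    ll_full <- -rf$deviance / 2
    beta_prs <- rf$beta[length(rf$beta)]
    p_prs <- NA_real_
  } else {
    ll_full <- as.numeric(stats::logLik(fitf))
    sm <- summary(fitf)$coefficients
    if ("prs" %in% rownames(sm)) {
      beta_prs <- sm["prs", 1]
      p_prs <- sm["prs", 4]
    } else {                      # constant score dropped by aliasing
      beta_prs <- 0
      p_prs <- NA_real_
    }
  }
  n <- length(y)
  ll0 <- as.numeric(stats::logLik(fit0))
  r2_cov <- nagelkerke_r2(as.numeric(stats::logLik(fitc)), ll0, n)
  r2_full <- nagelkerke_r2(ll_full, ll0, n)
  list(delta_r2 = r2_full - r2_cov, r2_full = r2_full, r2_cov = r2_cov,
       p = p_prs, beta_prs = beta_prs, separation = separation)
}

#' Mann-Whitney AUC of a score against case/control status
#'
#' Probability that a uniformly random case outscores a uniformly random
#' control, ties counting one half.
#'
#' @param prs numeric scores.
#' @param y 0/1 status (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(prs, y) {
  y <- as.integer(y > 0)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop_param("both classes must be present")
  r <- rank(prs)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PRS-bin relationship matrix
#'
#' Individuals are ranked by PRS (stable ties) and cut into B equal-count
#' quantile bins; S_ij = 1 if i and j fall in the same bin, else 0.  The
#' block-of-ones structure is positive semidefinite, i.e. a bin-level
#' random-intercept covariance.
#'
#' @param prs numeric scores.
#' @param B number of bins, `2 <= B <= n/2`.
#' @return n x n 0/1 matrix with attribute `bins` (assignments).
#' @export
build_bin_matrix <- function(prs, B) {
  n <- length(prs)
  if (B < 2) stop_param("B = 1 is confounded with the intercept")
  if (B > n / 2) stop_param("B must be <= n/2")
  ord <- rank(prs, ties.method = "first")
  bins <- ceiling(ord * B / n)
  S <- outer(bins, bins, "==") + 0
  attr(S, "bins") <- bins
  S
}

#' PRS-bin random-effect model
#'
#' Fits the phenotype on one or more PRS-bin relationship matrices
#' (optionally jointly with a GRM) by REML; each bin matrix's variance
#' proportion is tested by dropping it (boundary LRT).
#'
#' @param y 0/1 phenotype (observed scale).
#' @param covariates fixed covariates or NULL.
#' @param bin_matrices named list of matrices from [build_bin_matrix()].
#' @param grm optional `grm` fitted jointly.
#' @param ... passed to [reml_fit()].
#' @return data.frame: component, proportion, se, p_lrt (one row per bin
#'   matrix, plus the GRM row with NA p when present); attribute `fit`.
#' @export
prs_bin_lmm <- function(y, covariates, bin_matrices, grm = NULL, ...) {
  mats <- lapply(bin_matrices, function(m) if (inherits(m, "grm")) m$A else m)
  if (!is.null(grm)) mats$GRM <- if (inherits(grm, "grm")) grm$A else grm
  full <- reml_fit(y, covariates, mats, ...)
  rows <- lapply(names(bin_matrices), function(nm) {
    null_m <- mats[setdiff(names(mats), nm)]
    p <- if (length(null_m)) {
      nul <- reml_fit(y, covariates, null_m, ...)
      lrt_p(full$loglik, nul$loglik)$p
    } else {
      # single-component model: null is covariates-only linear model
      X <- cbind(rep(1, length(y)), if (!is.null(covariates)) as.matrix(covariates))
      res <- stats::lm.fit(X, as.numeric(y))$residuals
      n <- length(y); pr <- ncol(X)
      ll0 <- -0.5 * ((n - pr) * log(sum(res^2) / (n - pr)) + (n - pr) +
                     determinant(crossprod(X), logarithm = TRUE)$modulus[1])
      lrt_p(full$loglik, ll0)$p
    }
    data.frame(component = nm, proportion = unname(full$proportions[nm]),
               se = unname(full$proportion_se[nm]), p_lrt = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(grm))
    out <- rbind(out, data.frame(component = "GRM",
                                 proportion = unname(full$proportions["GRM"]),
                                 se = unname(full$proportion_se["GRM"]),
                                 p_lrt = NA_real_))
  attr(out, "fit") <- full
  out
}
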