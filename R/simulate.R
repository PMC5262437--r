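# Synthetic cohort generator: LD-blocked genotypes, liability-threshold
# phenotype with a heritability-enriched causal pathway, ascertained
# case/control sampling, and an independent discovery cohort from which
# per-SNP summary statistics are produced.

#' Simulation configuration
#'
#' Describes the synthetic world every downstream stage is exercised on:
#' a panel of `m_snps` SNPs in LD blocks of `block_size` with latent
#' within-block correlation `rho`; `n_genes` genes of `gene_span_snps`
#' consecutive SNPs each; named pathways (gene counts) of which
#' `causal_pathway` carries liability-scale heritability `h2_pathway`,
#' with `h2_background` spread over all SNPs outside the causal pathway's
#' genes; a liability-threshold binary phenotype with population prevalence
#' `prevalence_K`; and case/control ascertainment to `case_fraction`.
#'
#' @param n_target number of individuals in the ascertained target cohort.
#' @param n_discovery number of individuals in the independent discovery
#'   cohort used only to produce per-SNP summary statistics.
#' @param m_snps number of SNPs in the panel.
#' @param block_size SNPs per LD block.
#' @param rho latent within-block correlation, in `[0, 1)`.
#' @param maf_range length-2 vector of allele-frequency bounds in `(0, 0.5]`.
#' @param n_genes,gene_span_snps gene layout: `n_genes` genes, each spanning
#'   `gene_span_snps` consecutive SNPs, tiled across the panel.
#' @param pathways named integer vector of pathway sizes (genes per pathway).
#' @param causal_pathway name of the pathway whose SNPs carry `h2_pathway`.
#' @param h2_pathway,h2_background liability-scale variance fractions;
#'   their sum must be `< 1`.
#' @param prevalence_K population prevalence of the binary trait in `(0, 1)`.
#'   The paper-scale referent trait (major depressive disorder) has no
#'   stated prevalence; 0.15 is the conventional lifetime figure.
#' @param case_fraction case proportion after ascertainment, or `NULL` for
#'   an unascertained random sample of size `n_target`.
#' @param covariate_effects named numeric, liability effects of `age` and
#'   `sex` (standardized), default both 0.
#' @param seed integer RNG seed; every `simulate_*` output is a pure
#'   function of (config, seed).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_target = 1000, n_discovery = 6000, m_snps = 2000,
                       block_size = 50, rho = 0.7, maf_range = c(0.05, 0.5),
                       n_genes = 100, gene_span_snps = 15,
                       pathways = stats::setNames(rep(8L, 10),
                         c("causal_pathway", sprintf("null_pathway_%02d", 1:9))),
                       causal_pathway = "causal_pathway",
                       h2_pathway = 0.05, h2_background = 0.20,
                       prevalence_K = 0.15, case_fraction = 0.5,
                       covariate_effects = c(age = 0, sex = 0),
                       seed = 1L) {
  pathways <- unlist(pathways)            # tolerate YAML-parsed lists
  maf_range <- unlist(maf_range)
  if (rho < 0 || rho >= 1) stop_param("rho must be in [0, 1), got %g", rho)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_param("maf_range must lie within (0, 0.5]")
  if (block_size > m_snps) stop_param("block_size must be <= m_snps")
  if (h2_pathway < 0 || h2_background < 0 || h2_pathway + h2_background >= 1)
    stop_param("need h2_pathway + h2_background < 1 and both >= 0")
  if (prevalence_K <= 0 || prevalence_K >= 1)
    stop_param("prevalence_K must be in (0, 1)")
  if (!is.null(case_fraction) && (case_fraction <= 0 || case_fraction >= 1))
    stop_param("case_fraction must be in (0, 1) or NULL")
  if (!causal_pathway %in% names(pathways))
    stop_param("causal_pathway '%s' not among pathway names", causal_pathway)
  if (sum(pathways) > n_genes)
    stop_param("pathways ask for %d genes but only %d exist", sum(pathways), n_genes)
  if (n_genes * 1L > m_snps) stop_param("more genes than SNPs")
  structure(list(
    n_target = as.integer(n_target), n_discovery = as.integer(n_discovery),
    m_snps = as.integer(m_snps), block_size = as.integer(block_size),
    rho = rho, maf_range = maf_range, n_genes = as.integer(n_genes),
    gene_span_snps = as.integer(gene_span_snps), pathways = pathways,
    causal_pathway = causal_pathway, h2_pathway = h2_pathway,
    h2_background = h2_background, prevalence_K = prevalence_K,
    case_fraction = case_fraction, covariate_effects = covariate_effects,
    seed = as.integer(seed)), class = "sim_config")
}

#' SNP panel implied by a simulation configuration
#'
#' Deterministic given `config$seed`: SNP ids, a single-chromosome layout
#' with strictly increasing positions (spacing ~ U(500, 1500) bp), per-SNP
#' allele frequencies drawn uniformly from `maf_range`, LD-block ids, and
#' alleles A (effect) / G.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns snp_id, chr, pos, a1, a2, maf, info, block.
#' @export
simulate_snp_panel <- function(config) {
  m <- config$m_snps
  with_seed(derive_seed(config$seed, "panel"), {
    spacing <- sample(500:1500, m, replace = TRUE)
    data.frame(
      snp_id = sprintf("snp%06d", seq_len(m)),
      chr = 1L,
      pos = cumsum(spacing),
      a1 = "A", a2 = "G",
      maf = stats::runif(m, config$maf_range[1], config$maf_range[2]),
      info = 1,
      block = ((seq_len(m) - 1L) %/% config$block_size) + 1L,
      stringsAsFactors = FALSE)
  })
}

#' Gene table and pathway database implied by a configuration
#'
#' Genes tile the panel (`gene_span_snps` consecutive SNPs each, evenly
#' strided); pathway membership is a seeded random assignment of genes so
#' pathway SNP sets are scattered across the genome.
#'
#' @param config a [sim_config()].
#' @param panel SNP panel from [simulate_snp_panel()]; regenerated if NULL.
#' @return list with `genes` (gene_id, chr, start, end, 1-based inclusive),
#'   `pathways` (named list of gene_id vectors), `gene_snps` (named list of
#'   SNP column indices per gene) and `causal_pathway`.
#' @export
simulate_annotation <- function(config, panel = NULL) {
  if (is.null(panel)) panel <- simulate_snp_panel(config)
  stride <- config$m_snps %/% config$n_genes
  span <- min(config$gene_span_snps, stride)
  first <- (seq_len(config$n_genes) - 1L) * stride + 1L
  gene_snps <- lapply(first, function(s) seq.int(s, s + span - 1L))
  gene_id <- sprintf("gene%04d", seq_len(config$n_genes))
  names(gene_snps) <- gene_id
  genes <- data.frame(
    gene_id = gene_id, chr = 1L,
    start = panel$pos[vapply(gene_snps, min, 1L)],
    end = panel$pos[vapply(gene_snps, max, 1L)],
    stringsAsFactors = FALSE)
  pw <- with_seed(derive_seed(config$seed, "pathways"), {
    shuffled <- sample(gene_id)
    splits <- rep(names(config$pathways), config$pathways)
    split(shuffled[seq_along(splits)], factor(splits, levels = names(config$pathways)))
  })
  list(genes = genes, pathways = lapply(pw, sort), gene_snps = gene_snps,
       causal_pathway = config$causal_pathway)
}

#' Simulate LD-blocked genotype dosages
#'
#' Two independent haplotypes per individual; each haplotype is a latent
#' Gaussian with exchangeable within-block correlation `rho`, thresholded
#' at the allele-frequency quantile, so dosages are 0/1/2 with the panel's
#' MAF and tunable blockwise LD without a coalescent simulator.
#'
#' @param config a [sim_config()].
#' @param n number of individuals (>= 2).
#' @param stream character label decorrelating draws for different cohorts
#'   sharing one panel ("target", "discovery", ...).
#' @return a `genotypes` object: list with `dosage` (n x m integer-valued
#'   matrix), `snps` (the panel), `ids`.
#' @export
simulate_genotypes <- function(config, n, stream = "target") {
  if (n < 2) stop_param("n must be >= 2")
  panel <- simulate_snp_panel(config)
  m <- config$m_snps
  X <- matrix(0L, n, m)
  with_seed(derive_seed(config$seed, paste0("geno-", stream)), {
    thr <- stats::qnorm(panel$maf)      # latent below threshold => effect allele
    sr <- sqrt(config$rho); se <- sqrt(1 - config$rho)
    for (b in unique(panel$block)) {
      j <- which(panel$block == b)
      k <- length(j)
      for (h in 1:2) {
        z <- sr * stats::rnorm(n) + se * matrix(stats::rnorm(n * k), n, k)
        X[, j] <- X[, j] + (z < rep(thr[j], each = n))
      }
    }
  })
  ids <- sprintf("%s_id%06d", stream, seq_len(n))
  rownames(X) <- ids
  colnames(X) <- panel$snp_id
  structure(list(dosage = X, snps = panel, ids = ids), class = "genotypes")
}

#' Simulate a liability-threshold phenotype and ascertain a cohort
#'
#' Liability = G_path + G_bg + (optional covariate effects) + e, where
#' G_path is built from Normal effects at the causal pathway's SNPs scaled
#' to explain exactly `h2_pathway` of the in-sample liability variance,
#' G_bg likewise over all SNPs outside the causal pathway's genes, and
#' e ~ N(0, 1 - h2_pathway - h2_background).  Cases are individuals whose
#' liability exceeds the prevalence threshold qnorm(1 - K); the returned
#' cohort is resampled to `case_fraction` cases (or a random subset when
#' `case_fraction` is NULL).
#'
#' @param genotypes a `genotypes` object (the pool to ascertain from).
#' @param annotation output of [simulate_annotation()].
#' @param config a [sim_config()].
#' @return a `cohort` object: genotypes (subset), phenotype (0/1),
#'   liability, covariates (age, age2, sex, PC1..PC4), true_effects
#'   (length-m liability effects), threshold, case ids.
#' @export
simulate_phenotype <- function(genotypes, annotation, config) {
  path_genes <- annotation$pathways[[config$causal_pathway]]
  if (is.null(path_genes) || !length(path_genes))
    stop_param("causal pathway '%s' is empty", config$causal_pathway)
  path_idx <- sort(unique(unlist(annotation$gene_snps[path_genes])))
  if (!length(path_idx)) stop_param("causal pathway maps to no SNPs")
  X <- genotypes$dosage
  n_pool <- nrow(X); m <- ncol(X)
  maf <- genotypes$snps$maf
  bg_idx <- setdiff(seq_len(m), path_idx)

  with_seed(derive_seed(config$seed, "phenotype"), {
    beta <- numeric(m)
    mk_component <- function(idx, h2) {
      if (h2 <= 0 || !length(idx))
        return(list(g = numeric(n_pool), b = numeric(length(idx))))
      b <- stats::rnorm(length(idx),
                        sd = sqrt(h2 / length(idx) / (2 * maf[idx] * (1 - maf[idx]))))
      g <- as.numeric(X[, idx, drop = FALSE] %*% b)
      g <- g - mean(g)   # centred so realized prevalence tracks K
      v <- stats::var(g)
      sc <- if (v > 0) sqrt(h2 / v) else 0   # exact in-sample variance bookkeeping
      list(g = g * sc, b = b * sc)
    }
    cp <- mk_component(path_idx, config$h2_pathway)
    cb <- mk_component(bg_idx, config$h2_background)
    beta[path_idx] <- cp$b
    beta[bg_idx] <- cb$b
    e <- stats::rnorm(n_pool, sd = sqrt(1 - config$h2_pathway - config$h2_background))
    age <- stats::runif(n_pool, 18, 65)
    sex <- stats::rbinom(n_pool, 1, 0.5)
    ce <- config$covariate_effects
    cov_part <- (ce[["age"]] %||% 0) * scale(age)[, 1] + (ce[["sex"]] %||% 0) * sex
    liab <- cp$g + cb$g + cov_part + e
    thr <- stats::qnorm(1 - config$prevalence_K)
    case <- liab > thr

    n_t <- min(config$n_target, n_pool)
    if (is.null(config$case_fraction)) {
      keep <- sort(sample(n_pool, n_t))
    } else {
      n_case <- round(config$case_fraction * n_t)
      n_ctrl <- n_t - n_case
      ic <- which(case); iu <- which(!case)
      if (length(ic) < n_case) {
        warning(sprintf("pool has %d cases, %d requested; keeping all cases",
                        length(ic), n_case))
        n_case <- length(ic)
      }
      if (length(iu) < n_ctrl) n_ctrl <- length(iu)
      keep <- sort(c(sample(ic, n_case), sample(iu, n_ctrl)))
    }

    Xs <- X[keep, , drop = FALSE]
    geno_sub <- structure(list(dosage = Xs, snps = genotypes$snps,
                               ids = genotypes$ids[keep]), class = "genotypes")
    pcs <- genotype_pcs(Xs, 4L)
    covariates <- data.frame(age = age[keep], age2 = age[keep]^2,
                             sex = sex[keep], pcs)
    structure(list(
      genotypes = geno_sub,
      phenotype = as.integer(case[keep]),
      liability = liab[keep],
      covariates = covariates,
      true_effects = beta,
      threshold = thr,
      causal_snps = path_idx,
      config = config), class = "cohort")
  })
}

# Top principal components of the standardized genotype matrix, via the
# eigendecomposition of the GRM (n x n), which is cheaper than an n x m SVD.
genotype_pcs <- function(X, k = 4L) {
  Z <- standardize_dosages(X)
  A <- tcrossprod(Z) / ncol(Z)
  ev <- eigen(A, symmetric = TRUE)
  pcs <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(k)], 0)), k)
  colnames(pcs) <- paste0("PC", seq_len(k))
  pcs
}

#' Simulate discovery-cohort GWAS summary statistics
#'
#' Draws an independent discovery cohort on the same SNP panel, constructs
#' its liability from the supplied per-SNP effects, dichotomises at the
#' prevalence threshold, and fits a single-SNP logistic regression per SNP
#' (vectorised Newton iterations, equivalent to `glm(family = binomial)`).
#' Imputation info scores are drawn U(0.6, 1) so that QC filtering has
#' something to remove.
#'
#' @param config a [sim_config()].
#' @param true_effects length-m liability effect vector (e.g. from a
#'   [simulate_phenotype()] cohort); zero vector gives a null GWAS.
#' @param seed optional override of the config-derived seed.
#' @return data.frame with columns SNP, CHR, BP, A1, A2, OR, P, INFO, MAF.
#' @export
simulate_discovery_summary <- function(config, true_effects, seed = NULL) {
  if (config$n_discovery < 50)
    stop_param("n_discovery must be >= 50 for stable logistic fits")
  if (length(true_effects) != config$m_snps)
    stop_param("true_effects must have length m_snps")
  geno <- simulate_genotypes(config, config$n_discovery, stream = "discovery")
  X <- geno$dosage
  h2 <- config$h2_pathway + config$h2_background
  sd_e <- sqrt(max(1 - h2, .Machine$double.eps))
  res <- with_seed(seed %||% derive_seed(config$seed, "discovery-summary"), {
    g <- as.numeric(X %*% true_effects)
    g <- g - mean(g)
    y <- (g + stats::rnorm(nrow(X), sd = sd_e)) > stats::qnorm(1 - config$prevalence_K)
    fit <- logistic_scan(X, as.integer(y))
    info <- stats::runif(ncol(X), 0.6, 1.0)
    list(fit = fit, info = info)
  })
  p_freq <- colMeans(X) / 2
  data.frame(
    SNP = geno$snps$snp_id, CHR = geno$snps$chr, BP = geno$snps$pos,
    A1 = geno$snps$a1, A2 = geno$snps$a2,
    OR = exp(res$fit$beta), P = res$fit$p,
    INFO = res$info, MAF = pmin(p_freq, 1 - p_freq),
    stringsAsFactors = FALSE)
}

# Single-SNP logistic regression for every column of X at once.
# Newton-Raphson on (intercept, slope); all moment sums are colSums, so the
# whole scan is a handful of dense matrix passes.  Chunked to bound memory.
logistic_scan <- function(X, y, max_iter = 25L, tol = 1e-8, chunk = 512L) {
  n <- nrow(X); m <- ncol(X)
  beta <- numeric(m); pval <- rep(1, m)
  ybar <- mean(y)
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    Xc <- X[, lo:hi, drop = FALSE]
    k <- ncol(Xc)
    b0 <- rep(stats::qlogis(ybar), k); b1 <- numeric(k)
    active <- apply(Xc, 2L, stats::sd) > 0
    for (it in seq_len(max_iter)) {
      eta <- sweep(Xc * rep(b1, each = n), 2L, b0, "+")
      mu <- stats::plogis(eta)
      w <- mu * (1 - mu)
      r <- y - mu
      S0 <- colSums(w); S1 <- colSums(w * Xc); S2 <- colSums(w * Xc * Xc)
      g0 <- colSums(r);  g1 <- colSums(r * Xc)
      det <- S0 * S2 - S1 * S1
      ok <- active & det > 1e-12
      d0 <- ifelse(ok, (S2 * g0 - S1 * g1) / det, 0)
      d1 <- ifelse(ok, (S0 * g1 - S1 * g0) / det, 0)
      b0 <- b0 + d0; b1 <- b1 + d1
      if (max(abs(d0), abs(d1)) < tol) break
    }
    se1 <- ifelse(active & det > 1e-12, sqrt(S0 / det), NA_real_)
    beta[lo:hi] <- b1
    pval[lo:hi] <- ifelse(is.na(se1), 1, 2 * stats::pnorm(-abs(b1) / se1))
  }
  list(beta = beta, p = pval)
}

#' Simulate a complete analysis-ready cohort
#'
#' Convenience wrapper: panel + annotation + an oversampled genotype pool +
#' ascertained liability-threshold phenotype + independent discovery
#' summary statistics, all from one config and seed.
#'
#' @param config a [sim_config()].
#' @param discovery logical; also simulate discovery summary statistics.
#' @return list with `cohort`, `annotation`, `summary` (or NULL).
#' @export
simulate_cohort <- function(config, discovery = TRUE) {
  K <- config$prevalence_K
  over <- if (is.null(config$case_fraction)) 1 else
    max(config$case_fraction / K, (1 - config$case_fraction) / (1 - K))
  n_pool <- ceiling(config$n_target * over * 1.25)
  pool <- simulate_genotypes(config, n_pool, stream = "target")
  ann <- simulate_annotation(config, pool$snps)
  cohort <- simulate_phenotype(pool, ann, config)
  summ <- if (discovery)
    simulate_discovery_summary(config, cohort$true_effects) else NULL
  list(cohort = cohort, annotation = ann, summary = summ)
}
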