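# Synthetic cohort generator: seed determinism, LD structure, liability
# bookkeeping, ascertainment, discovery summary statistics.

test_that("sim_config validates its invariants", {
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(h2_pathway = 0.6, h2_background = 0.5), "h2")
  expect_error(sim_config(prevalence_K = 0), "prevalence")
  expect_error(sim_config(block_size = 5000, m_snps = 100), "block_size")
})

test_that("genotype simulation is a pure function of (config, seed)", {
  cfg <- sim_config(m_snps = 200, seed = 5)
  g1 <- simulate_genotypes(cfg, 50)
  g2 <- simulate_genotypes(cfg, 50)
  expect_identical(g1$dosage, g2$dosage)
  g3 <- simulate_genotypes(sim_config(m_snps = 200, seed = 6), 50)
  expect_false(identical(g1$dosage, g3$dosage))
})

test_that("rho = 0 gives independent SNPs; positive rho gives blockwise LD", {
  cfg0 <- sim_config(m_snps = 300, block_size = 20, rho = 0, seed = 21)
  X0 <- simulate_genotypes(cfg0, 800)$dosage
  C0 <- abs(cor(X0))
  expect_lt(mean(C0[upper.tri(C0)]), 0.05)

  cfg1 <- sim_config(m_snps = 200, block_size = 50, rho = 0.9, seed = 22)
  g1 <- simulate_genotypes(cfg1, 1200)
  # oracle: direct brute-force correlation pass over the dosage matrix
  C1 <- cor(g1$dosage)
  blk <- g1$snps$block
  same <- outer(blk, blk, "==") & upper.tri(C1)
  diff <- (!outer(blk, blk, "==")) & upper.tri(C1)
  adj <- cbind(1:(ncol(C1) - 1), 2:ncol(C1))
  adj_same <- adj[blk[adj[, 1]] == blk[adj[, 2]], , drop = FALSE]
  expect_gt(mean(C1[adj_same]), mean(C1[diff]))
  expect_gt(mean(C1[same]), 0.1)
})

test_that("empirical MAFs track the panel and positions strictly increase", {
  cfg <- sim_config(m_snps = 400, seed = 8)
  g <- simulate_genotypes(cfg, 1000)
  expect_true(all(diff(g$snps$pos) > 0))
  emp <- colMeans(g$dosage) / 2
  expect_lt(max(abs(emp - g$snps$maf)), 0.06)
  expect_true(all(g$dosage %in% 0:2))
})

test_that("null phenotype model shows no per-SNP association", {
  cfg <- sim_config(n_target = 400, m_snps = 100, h2_pathway = 0,
                    h2_background = 0, case_fraction = NULL, seed = 17)
  pool <- simulate_genotypes(cfg, 400)
  ann <- simulate_annotation(cfg)
  ch <- simulate_phenotype(pool, ann, cfg)
  tstats <- apply(ch$genotypes$dosage, 2, function(x) {
    if (sd(x) == 0) return(0)
    unname(summary(lm(ch$liability ~ x))$coefficients[2, 3])
  })
  # ~1 of 100 expected beyond the 99th-percentile null bound
  expect_lte(sum(abs(tstats) > qnorm(0.995)), 6)
})

test_that("constructed genetic variance components match their targets", {
  # oracle: recompute G from true_effects and the genotype matrix directly
  for (seed in c(1, 2, 3, 4, 5)) {
    # rho = 0 so the pathway and background components are built from
    # independent SNPs (the additivity premise of the bookkeeping check)
    cfg <- sim_config(n_target = 1000, m_snps = 400, rho = 0,
                      h2_pathway = 0.05,
                      h2_background = 0.20, case_fraction = NULL, seed = seed)
    pool <- simulate_genotypes(cfg, 1000)
    ann <- simulate_annotation(cfg)
    ch <- simulate_phenotype(pool, ann, cfg)
    beta_p <- ch$true_effects
    beta_p[-ch$causal_snps] <- 0
    g_path <- as.numeric(ch$genotypes$dosage %*% beta_p)
    expect_lt(abs(var(g_path) - 0.05), 0.2 * 0.05)
    beta_b <- ch$true_effects
    beta_b[ch$causal_snps] <- 0
    g_bg <- as.numeric(ch$genotypes$dosage %*% beta_b)
    expect_lt(abs(var(g_bg) - 0.20), 0.2 * 0.20)
    # additive bookkeeping: component variances sum to the liability
    # variance up to empirical cross-covariances of independent draws
    # (4 sigma of their sampling distribution at n = 1000 is ~0.11)
    e <- ch$liability - g_path - g_bg
    expect_lt(abs(var(ch$liability) - (var(g_path) + var(g_bg) + var(e))), 0.12)
  }
})

test_that("prevalence 0.5 puts the liability threshold at exactly 0", {
  cfg <- sim_config(n_target = 100, m_snps = 100, prevalence_K = 0.5,
                    case_fraction = NULL, seed = 3)
  ch <- simulate_phenotype(simulate_genotypes(cfg, 100), simulate_annotation(cfg), cfg)
  expect_identical(ch$threshold, 0)
  expect_identical(ch$phenotype, as.integer(ch$liability > 0))
})

test_that("ascertainment hits the requested case fraction", {
  d <- small_cohort()
  expect_equal(mean(d$cohort$phenotype), 0.5, tolerance = 0.01)
  expect_equal(nrow(d$cohort$covariates), length(d$cohort$phenotype))
  expect_named(d$cohort$covariates, c("age", "age2", "sex", paste0("PC", 1:4)))
})

test_that("ascertainment leaves null-SNP dosage frequencies unbiased", {
  shifts <- vapply(1:8, function(seed) {
    cfg <- sim_config(n_target = 300, m_snps = 300, h2_pathway = 0.3,
                      h2_background = 0, case_fraction = 0.5, seed = seed)
    pool <- simulate_genotypes(cfg, 1200)
    ann <- simulate_annotation(cfg)
    ch <- simulate_phenotype(pool, ann, cfg)
    null_snps <- setdiff(seq_len(300), ch$causal_snps)
    mean(colMeans(ch$genotypes$dosage[, null_snps]) -
         colMeans(pool$dosage[, null_snps]))
  }, 0)
  expect_lt(abs(mean(shifts)), 0.01)
})

test_that("discovery summary statistics are null-calibrated and reproducible", {
  cfg <- sim_config(n_discovery = 2000, m_snps = 1000, seed = 77)
  s1 <- simulate_discovery_summary(cfg, numeric(1000))
  s2 <- simulate_discovery_summary(cfg, numeric(1000))
  expect_identical(s1$OR, s2$OR)
  expect_identical(s1$P, s2$P)
  expect_true(all(c("SNP", "CHR", "BP", "A1", "A2", "OR", "P", "INFO", "MAF")
                  %in% names(s1)))
  frac <- mean(s1$P < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
  expect_true(all(s1$INFO >= 0.6 & s1$INFO <= 1))
  expect_error(simulate_discovery_summary(
    sim_config(n_discovery = 10, m_snps = 100), numeric(100)), "n_discovery")
})

test_that("a large-effect SNP reaches genome-wide significance in discovery", {
  cfg <- sim_config(n_discovery = 20000, m_snps = 50, block_size = 10,
                    n_genes = 10, gene_span_snps = 2,
                    pathways = c(causal_pathway = 2L),
                    rho = 0, h2_pathway = 0, h2_background = 0, seed = 12)
  panel <- simulate_snp_panel(cfg)
  beta <- numeric(50)
  j <- 25
  beta[j] <- sqrt(0.05 / (2 * panel$maf[j] * (1 - panel$maf[j])))  # 5% of liability
  s <- simulate_discovery_summary(cfg, beta)
  expect_lt(s$P[j], 1e-8)
  # oracle: the vectorised scan must agree with a direct glm fit
  g <- simulate_genotypes(cfg, 20000, stream = "discovery")
  h2 <- 0
  y <- local({
    set.seed(pathrha:::derive_seed(cfg$seed, "discovery-summary"))
    gv <- as.numeric(g$dosage %*% beta)
    gv <- gv - mean(gv)
    as.integer((gv + rnorm(20000, sd = sqrt(1 - h2))) >
               qnorm(1 - cfg$prevalence_K))
  })
  fit <- glm(y ~ g$dosage[, j], family = binomial())
  expect_equal(unname(log(s$OR[j])), unname(coef(fit)[2]), tolerance = 1e-5)
})
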