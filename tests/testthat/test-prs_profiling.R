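# Polygenic scores: clumping, thresholded scores, Nagelkerke / AUC
# evaluation, bin matrices and the PRS-bin LMM.

mk_geno <- function(X, pos = seq_len(ncol(X)) * 1000L) {
  ids <- sprintf("i%03d", seq_len(nrow(X)))
  rownames(X) <- ids
  snps <- data.frame(snp_id = paste0("s", seq_len(ncol(X))), chr = 1L,
                     pos = pos, a1 = "A", a2 = "G",
                     maf = 0.3, info = 1, stringsAsFactors = FALSE)
  colnames(X) <- snps$snp_id
  structure(list(dosage = X, snps = snps, ids = ids), class = "genotypes")
}

test_that("clumping keeps the most associated SNP per LD neighbourhood", {
  set.seed(5)
  x1 <- rbinom(200, 2, 0.4); x3 <- rbinom(200, 2, 0.4)
  # s2 is a perfect proxy of s1; s4 a perfect proxy of s3
  g <- mk_geno(cbind(x1, x1, x3, x3))
  summ <- data.frame(SNP = paste0("s", 1:4), P = c(0.02, 0.001, 0.5, 0.03),
                     CHR = 1L, BP = g$snps$pos)
  kept <- clump(summ, g, r2_threshold = 0.25, window_kb = 250)
  # oracle (hand-executed greedy): keep s2 (best p, claims s1),
  # then s4 (claims s3)
  expect_identical(sort(kept), c("s2", "s4"))
  # uncorrelated SNPs are all kept
  set.seed(6)
  g2 <- mk_geno(matrix(rbinom(200 * 4, 2, 0.4), 200, 4))
  expect_identical(sort(clump(summ, g2, 0.25, 250)), paste0("s", 1:4))
  # outside the physical window nothing is clumped even at r2 = 1
  g3 <- mk_geno(cbind(x1, x1), pos = c(1000L, 500000L))
  summ3 <- summ[1:2, ]; summ3$BP <- c(1000L, 500000L)
  expect_identical(sort(clump(summ3, g3, 0.25, 250)), c("s1", "s2"))
})

test_that("PRS computation matches hand arithmetic and aligns alleles", {
  g <- mk_geno(matrix(c(2, 1, 0), 1, 3))
  w <- data.frame(SNP = paste0("s", 1:3), A1 = "A", A2 = "G",
                  OR = c(1.2, 0.8, 1.5), P = c(0.1, 0.3, 0.6))
  s <- compute_prs(g, w, p_cutoff = 0.2)
  expect_equal(as.numeric(s), 2 * log(1.2), tolerance = 1e-12)
  expect_identical(attr(s, "n_snps_used"), 1L)
  # cutoff 1: full weighted dosage product (matrix-vector oracle)
  s1 <- compute_prs(g, w, p_cutoff = 1)
  expect_equal(as.numeric(s1), sum(c(2, 1, 0) * log(c(1.2, 0.8, 1.5))),
               tolerance = 1e-12)
  # zero weights give zero scores
  w0 <- w; w0$OR <- 1
  expect_equal(as.numeric(compute_prs(g, w0, 1)), 0)
  # swapped effect allele flips the dosage
  wf <- w; wf$A1 <- "G"; wf$A2 <- "A"
  sf <- compute_prs(g, wf, p_cutoff = 0.2)
  expect_equal(as.numeric(sf), (2 - 2) * log(1.2), tolerance = 1e-12)
  # unresolvable alleles are dropped and counted
  wx <- w; wx$A1[2] <- "T"; wx$A2[2] <- "C"
  sx <- compute_prs(g, wx, 1)
  expect_identical(attr(sx, "n_dropped"), 1L)
  expect_identical(attr(sx, "n_snps_used"), 2L)
})

test_that("nested cutoffs differ by exactly the in-between SNP contribution", {
  set.seed(9)
  g <- mk_geno(matrix(rbinom(50 * 20, 2, 0.3), 50, 20))
  w <- data.frame(SNP = paste0("s", 1:20), A1 = "A", A2 = "G",
                  OR = exp(rnorm(20, 0, 0.1)), P = runif(20))
  s_lo <- compute_prs(g, w, 0.3)
  s_hi <- compute_prs(g, w, 0.8)
  between <- w$P > 0.3 & w$P <= 0.8
  direct <- as.numeric(impute_mean(g$dosage[, between, drop = FALSE]) %*%
                       log(w$OR[between]))
  expect_equal(as.numeric(s_hi) - as.numeric(s_lo), direct, tolerance = 1e-10)
  expect_gte(attr(s_hi, "n_snps_used"), attr(s_lo, "n_snps_used"))
})

test_that("Nagelkerke R2 matches the hand-computed four-observation case", {
  # y = (1,1,0,0), fitted p = (.9,.8,.2,.1), null p = .5:
  # L1 = .9*.8*.8*.9 = 0.5184, L0 = 0.0625 -> R2_N = 0.8704
  ll1 <- log(0.5184); ll0 <- log(0.0625)
  expect_equal(nagelkerke_r2(ll1, ll0, 4), 0.8703704, tolerance = 1e-6)
})

test_that("logistic evaluation is exact for degenerate and affine cases", {
  set.seed(13)
  n <- 300
  cov <- data.frame(age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5))
  prs <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 * scale(prs)[, 1]))
  # constant PRS explains nothing
  e0 <- logistic_eval(y, rep(1.7, n), cov)
  expect_equal(e0$delta_r2, 0, tolerance = 1e-10)
  # delta-R2 invariant under affine transformation of the score
  e1 <- logistic_eval(y, prs, cov)
  e2 <- logistic_eval(y, 3 * prs - 7, cov)
  expect_equal(e1$delta_r2, e2$delta_r2, tolerance = 1e-8)
  expect_equal(e1$p, e2$p, tolerance = 1e-8)
  expect_gt(e1$delta_r2, 0)
  expect_lt(e1$p, 0.01)
})

test_that("AUC is the Mann-Whitney probability with half-ties", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(2, 6), rep(c(0, 1), 3)), 0.5)
  # oracle: enumeration of the four case-control pairs
  expect_equal(auc(c(1, 2.5, 2, 3), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(1:4, rep(1, 4)), "both classes")
  # complement symmetry for tie-free scores
  set.seed(2)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  expect_equal(auc(s, y) + auc(-s, y), 1, tolerance = 1e-12)
})

test_that("bin matrices are quantile blocks, equivariant and PSD", {
  S <- build_bin_matrix(c(1, 2, 3, 4), 2)
  expect_equal(unname(S), rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                                c(0, 0, 1, 1), c(0, 0, 1, 1)),
               ignore_attr = TRUE)
  expect_error(build_bin_matrix(1:10, 1), "confounded")
  expect_error(build_bin_matrix(1:10, 6), "n/2")
  set.seed(3)
  prs <- rnorm(30)
  S1 <- build_bin_matrix(prs, 5)
  perm <- sample(30)
  S2 <- build_bin_matrix(prs[perm], 5)
  expect_equal(S2, S1[perm, perm], ignore_attr = TRUE)
  expect_gte(min(eigen(S1, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("PRS-bin LMM recovers a planted bin-level variance share", {
  ok <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    n <- 600; B <- 20
    prs <- rnorm(n)
    S <- build_bin_matrix(prs, B)
    b_eff <- rnorm(B, sd = sqrt(0.05))
    y <- b_eff[attr(S, "bins")] + rnorm(n, sd = sqrt(0.95))
    res <- prs_bin_lmm(y, NULL, list(prs_bin = S))
    if (abs(res$proportion - 0.05) < 2 * res$se) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("joint bin + GRM fit separates independently constructed effects", {
  cfg <- sim_config(m_snps = 500, rho = 0, seed = 91)
  g <- simulate_genotypes(cfg, 500)
  grm <- compute_grm(g)
  set.seed(91)
  u <- as.numeric(t(chol(grm$A + diag(500) * 1e-6)) %*% rnorm(500)) * sqrt(0.3)
  prs <- rnorm(500)
  S <- build_bin_matrix(prs, 20)
  b_eff <- rnorm(20, sd = sqrt(0.08))
  y <- u + b_eff[attr(S, "bins")] + rnorm(500, sd = sqrt(0.62))
  res <- prs_bin_lmm(y, NULL, list(prs_bin = S), grm = grm)
  pb <- res[res$component == "prs_bin", ]
  pg <- res[res$component == "GRM", ]
  expect_lt(abs(pb$proportion - 0.08), 2.5 * pb$se)
  expect_lt(abs(pg$proportion - 0.30), 2.5 * pg$se)
  expect_lt(pb$p_lrt, 0.05)
})

test_that("null PRS-bin variance shares sit near the boundary", {
  set.seed(17)
  n <- 400
  prs <- rnorm(n)
  S <- build_bin_matrix(prs, 10)
  props <- ps <- numeric(6)
  for (r in 1:6) {
    y <- rnorm(n)
    res <- suppressWarnings(prs_bin_lmm(y, NULL, list(prs_bin = S)))
    props[r] <- res$proportion; ps[r] <- res$p_lrt
  }
  expect_lt(mean(props), 0.05)
  expect_gt(median(ps), 0.1)
})
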