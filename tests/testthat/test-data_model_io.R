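# PLINK codec, GMT/gene-table/GRM formats, QC filter, SNP-gene mapping,
# relatedness pruning.

test_that("PLINK triplet round-trips hard calls exactly", {
  g <- toy_genotypes(5, 10)
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_plink(g, prefix)
  r <- read_plink(prefix)
  expect_equal(unname(r$dosage), unname(g$dosage), ignore_attr = TRUE)
  expect_identical(r$ids, g$ids)
  expect_identical(r$snps$snp_id, g$snps$snp_id)
  expect_identical(r$snps$pos, g$snps$pos)
  # read_genotypes dispatches on the path form
  r2 <- read_genotypes(prefix)
  expect_identical(r2$dosage, r$dosage)
})

test_that("PLINK bed bytes match a hand encoding of the 2-bit scheme", {
  # 4 individuals, 1 SNP, dosages 2,1,0,NA ->
  # codes 00,10,11,01 packed LSB-first: 01 11 10 00 = 0x78
  X <- matrix(c(2, 1, 0, NA), 4, 1)
  rownames(X) <- paste0("i", 1:4)
  g <- structure(list(
    dosage = X,
    snps = data.frame(snp_id = "rs1", chr = 1L, pos = 100L, a1 = "A",
                      a2 = "G", maf = 0.5, info = 1),
    ids = paste0("i", 1:4)), class = "genotypes")
  prefix <- file.path(withr::local_tempdir(), "hand")
  write_plink(g, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", 10)
  expect_identical(raw, as.raw(c(0x6c, 0x1b, 0x01, 0x78)))
  r <- read_plink(prefix)
  expect_identical(as.numeric(r$dosage), c(2, 1, 0, NA))
})

test_that("missing genotypes are flagged and mean-imputed to the column mean", {
  g <- toy_genotypes(6, 4, seed = 2)
  g$dosage[3, 2] <- NA
  prefix <- file.path(withr::local_tempdir(), "miss")
  write_plink(g, prefix)
  r <- read_plink(prefix)
  expect_true(is.na(r$dosage[3, 2]))
  imp <- impute_mean(r$dosage)
  expect_equal(imp[3, 2], mean(r$dosage[-3, 2]))
})

test_that("malformed bed files are rejected", {
  dir <- withr::local_tempdir()
  g <- toy_genotypes(4, 3)
  write_plink(g, file.path(dir, "ok"))
  # corrupt magic
  raw <- readBin(file.path(dir, "ok.bed"), "raw", file.size(file.path(dir, "ok.bed")))
  raw[1] <- as.raw(0)
  writeBin(raw, file.path(dir, "bad.bed"))
  file.copy(file.path(dir, "ok.bim"), file.path(dir, "bad.bim"))
  file.copy(file.path(dir, "ok.fam"), file.path(dir, "bad.fam"))
  expect_error(read_plink(file.path(dir, "bad")), "magic")
  # truncated body vs bim/fam counts
  writeBin(readBin(file.path(dir, "ok.bed"), "raw", 5), file.path(dir, "trunc.bed"))
  file.copy(file.path(dir, "ok.bim"), file.path(dir, "trunc.bim"))
  file.copy(file.path(dir, "ok.fam"), file.path(dir, "trunc.fam"))
  expect_error(read_plink(file.path(dir, "trunc")), "does not match")
})

test_that("dosage TSV round-trips", {
  g <- toy_genotypes(5, 6)
  path <- file.path(withr::local_tempdir(), "dos.tsv")
  write_dosage_tsv(g, path)
  r <- read_dosage_tsv(path)
  expect_equal(unname(r$dosage), unname(g$dosage))
})

test_that("qc_filter applies inclusive thresholds row by row", {
  # paper thresholds are inclusive: a SNP exactly at (0.01, 0.8) is kept
  snps <- data.frame(maf = c(0.01, 0.005), info = c(0.8, 0.95))
  expect_identical(qc_filter(snps, 0.01, 0.8), 1L)
  # six-SNP table: row-by-row oracle gives exactly SNPs 3 and 4
  tab <- data.frame(maf = c(.005, .01, .02, .3, .5, .009),
                    info = c(.9, .79, .8, 1, .6, .95))
  expect_identical(qc_filter(tab, 0.01, 0.8), c(3L, 4L))
  expect_error(qc_filter(tab, -0.1, 0.8), "thresholds")
})

test_that("qc_filter is idempotent and monotone in its thresholds", {
  set.seed(4)
  snps <- data.frame(maf = runif(200, 0, 0.5), info = runif(200))
  k1 <- qc_filter(snps, 0.01, 0.8)
  expect_identical(qc_filter(snps[k1, ], 0.01, 0.8), seq_along(k1))
  for (mm in c(0.02, 0.05)) for (ii in c(0.85, 0.95)) {
    expect_true(all(qc_filter(snps, mm, ii) %in% k1))
  }
})

test_that("SNP-gene mapping uses 1-based inclusive bounds", {
  snps <- data.frame(chr = 1L, pos = c(100L, 150L, 200L, 250L, 300L))
  genes <- data.frame(gene_id = "g1", chr = 1L, start = 140L, end = 260L)
  expect_identical(map_snps_to_genes(snps, genes, 0)$g1, c(2L, 3L, 4L))
  genes2 <- data.frame(gene_id = "g", chr = 1L, start = 100L, end = 120L)
  expect_identical(map_snps_to_genes(snps, genes2, 0)$g, 1L)     # pos == start
  genes3 <- data.frame(gene_id = "g", chr = 1L, start = 101L, end = 120L)
  expect_identical(map_snps_to_genes(snps, genes3, 0)$g, integer(0))
  # zero-window map is a subset of any positive-window map
  m0 <- map_snps_to_genes(snps, genes, 0)$g1
  m1 <- map_snps_to_genes(snps, genes, 1)$g1
  expect_true(all(m0 %in% m1))
  # chromosome mismatch excludes
  genes4 <- data.frame(gene_id = "g", chr = 2L, start = 1L, end = 1e6)
  expect_identical(map_snps_to_genes(snps, genes4, 0)$g, integer(0))
})

test_that("prune_related handles trivial and single-pair cases", {
  A <- diag(4) ; A[upper.tri(A)] <- 0.01; A[lower.tri(A)] <- 0.01
  expect_identical(prune_related(A, 0.025), 1:4)
  A[1, 2] <- A[2, 1] <- 0.5
  kept <- prune_related(A, 0.025)
  expect_identical(length(kept), 3L)
  expect_true(sum(c(1, 2) %in% kept) == 1)
  expect_error(prune_related(A, 0), "cutoff")
})

test_that("greedy pruning matches exhaustive search on the 5-node example", {
  A <- matrix(0.001, 5, 5); diag(A) <- 1
  for (j in c(1, 2, 4)) A[3, j] <- A[j, 3] <- 0.1
  kept <- prune_related(A, 0.025)
  expect_identical(kept, c(1L, 2L, 4L, 5L))
  # oracle: brute-force maximum independent set over all keep-subsets
  best <- 0
  for (s in 0:(2^5 - 1)) {
    keep <- which(bitwAnd(s, 2^(0:4)) > 0)
    sub <- A[keep, keep, drop = FALSE]; diag(sub) <- 0
    if (all(sub <= 0.025)) best <- max(best, length(keep))
  }
  expect_identical(length(kept), as.integer(best))
})

test_that("pruning invariant: no kept pair exceeds the cutoff", {
  set.seed(6)
  for (rep in 1:5) {
    A <- matrix(runif(100, 0, 0.06), 10, 10)
    A <- (A + t(A)) / 2; diag(A) <- 1
    kept <- prune_related(A, 0.05)
    sub <- A[kept, kept, drop = FALSE]; diag(sub) <- 0
    expect_lte(max(sub), 0.05)
  }
})

test_that("GMT and gene tables round-trip", {
  dir <- withr::local_tempdir()
  sets <- list(pwA = c("g1", "g2", "g3"), pwB = c("g2", "g9"))
  write_gmt(sets, file.path(dir, "sets.gmt"))
  expect_identical(read_gmt(file.path(dir, "sets.gmt")), sets)
  genes <- data.frame(gene_id = c("g1", "g2"), chr = c(1L, 2L),
                      start = c(10L, 50L), end = c(20L, 80L))
  data.table::fwrite(genes, file.path(dir, "genes.tsv"), sep = "\t")
  expect_equal(read_gene_table(file.path(dir, "genes.tsv")), genes)
})

test_that("GCTA GRM text format round-trips", {
  g <- toy_genotypes(8, 30, seed = 5)
  grm <- compute_grm(g)
  prefix <- file.path(withr::local_tempdir(), "test")
  write_grm_gcta(grm, prefix)
  r <- read_grm_gcta(prefix)
  expect_equal(r$A, unname(grm$A), tolerance = 1e-6)
  expect_identical(r$ids, grm$ids)
  expect_identical(r$n_snps, grm$n_snps)
})
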