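# Stage 2: multilevel regional heritability.
#
# Pathway level: partition the panel into (pathway SNPs, remainder), fit
# both GRMs jointly by REML, test the region component with the boundary
# LRT.  Gene level: same with region = one gene.  Subregion level: a
# fixed-size window scan across a gene.  Circular genomic permutation
# supplies empirical enrichment p-values that respect set size and LD.

#' Partition the SNP panel by a pathway
#'
#' @param m_panel total number of panel SNPs.
#' @param annotation annotation list with `pathways` and `gene_snps`
#'   (see [simulate_annotation()]), or NULL if `region_idx` given.
#' @param pathway pathway name.
#' @param region_idx directly supplied region indices (overrides pathway).
#' @return a `partition`: list(region, complement, degenerate).
#' @export
partition_by_pathway <- function(m_panel, annotation = NULL, pathway = NULL,
                                 region_idx = NULL) {
  if (is.null(region_idx)) {
    genes <- annotation$pathways[[pathway]]
    region_idx <- sort(unique(unlist(annotation$gene_snps[genes])))
  }
  region_idx <- sort(unique(as.integer(region_idx)))
  if (!length(region_idx)) stop_param("pathway maps to no panel SNPs")
  complement <- setdiff(seq_len(m_panel), region_idx)
  degenerate <- length(complement) == 0L
  if (degenerate) warning("pathway covers the whole panel: degenerate partition")
  structure(list(region = region_idx, complement = complement,
                 degenerate = degenerate), class = "partition")
}

#' Two-component regional heritability fit
#'
#' Joint REML with a region GRM and a complement GRM; the region
#' component is tested by dropping it (boundary-mixture LRT).  Reported
#' ratios follow the printed-table conventions: \%SNP = 100 x
#' n_region / n_panel, \%h2 = 100 x hR2 / (hR2 + hC2), enrichment =
#' \%h2 / \%SNP.
#'
#' @param genotypes `genotypes` object or dosage matrix.
#' @param y response (0/1 observed scale, or quantitative liability).
#' @param covariates fixed covariates or NULL.
#' @param partition a `partition` from [partition_by_pathway()].
#' @param grms optional precomputed list(region =, complement =) `grm`s.
#' @param ... passed to [reml_fit()].
#' @return a `regional_result` data.frame row: hR2, se_R, hC2, se_C,
#'   lrt_stat, p_lrt, n_region_snps, pct_snp, pct_h2, enrichment,
#'   loglik_full, loglik_null, converged.
#' @export
fit_region_h2 <- function(genotypes, y, covariates, partition, grms = NULL, ...) {
  if (is.null(grms)) {
    grms <- list(region = compute_grm(genotypes, partition$region),
                 complement = compute_grm(genotypes, partition$complement))
  }
  full <- reml_fit(y, covariates, list(region = grms$region, complement = grms$complement), ...)
  null <- reml_fit(y, covariates, list(complement = grms$complement), ...)
  lrt <- lrt_p(full$loglik, null$loglik)
  n_region <- length(partition$region)
  n_panel <- n_region + length(partition$complement)
  hR2 <- unname(full$proportions["region"])
  hC2 <- unname(full$proportions["complement"])
  pct_snp <- 100 * n_region / n_panel
  pct_h2 <- if (hR2 + hC2 > 0) 100 * hR2 / (hR2 + hC2) else 0
  structure(data.frame(
    hR2 = hR2, se_R = unname(full$proportion_se["region"]),
    hC2 = hC2, se_C = unname(full$proportion_se["complement"]),
    lrt_stat = lrt$statistic, p_lrt = lrt$p,
    n_region_snps = n_region, pct_snp = pct_snp, pct_h2 = pct_h2,
    enrichment = if (pct_snp > 0) pct_h2 / pct_snp else NA_real_,
    loglik_full = full$loglik, loglik_null = null$loglik,
    converged = full$converged && null$converged),
    class = c("regional_result", "data.frame"))
}

#' Cut a gene's SNPs into fixed-size scan blocks
#'
#' Consecutive non-overlapping windows of `window_n` SNPs in genomic
#' order; any remainder (>= 1 SNP) forms the final block.  1700 SNPs at
#' window 200 therefore give 9 blocks, the last of size 100.
#'
#' @param snp_idx SNP indices of the gene, in genomic order.
#' @param window_n SNPs per block (>= 2).
#' @param stride block start spacing; default `window_n` (disjoint
#'   blocks); smaller values give a true sliding overlap.
#' @return list of integer index vectors (one per block).
#' @export
make_blocks <- function(snp_idx, window_n = 200, stride = window_n) {
  if (!length(snp_idx)) stop_param("gene has no SNPs")
  if (window_n < 2) stop_param("window_n must be >= 2")
  starts <- seq(1L, length(snp_idx), by = stride)
  blocks <- lapply(starts, function(s)
    snp_idx[s:min(s + window_n - 1L, length(snp_idx))])
  # drop trailing windows fully contained in the previous one (overlap mode)
  blocks[!duplicated(vapply(blocks, function(b) paste(range(b), collapse = "-"), ""))]
}

#' Block scan of regional heritability across a gene
#'
#' For each block: joint REML with region = block SNPs and complement =
#' every other panel SNP, LRT p for the block component, Bonferroni
#' across the scan's blocks.  The complement GRM for each block is
#' obtained by subtracting the block's contribution from the whole-panel
#' relationship sum, so the panel is standardized once.
#'
#' @param genotypes `genotypes` object or dosage matrix (the full panel).
#' @param y,covariates as in [fit_region_h2()].
#' @param blocks list of SNP index vectors from [make_blocks()].
#' @param ... passed to [reml_fit()].
#' @return a `block_scan` data.frame: block, start_idx, end_idx, n_snps,
#'   h2, se, p_lrt, p_bonf (+ bp extents when positions are available).
#' @export
scan_gene <- function(genotypes, y, covariates, blocks, ...) {
  X <- if (inherits(genotypes, "genotypes")) genotypes$dosage else genotypes
  snps <- if (inherits(genotypes, "genotypes")) genotypes$snps else NULL
  if (!length(blocks)) stop_param("no blocks to scan")
  Z <- standardize_dosages(X)
  poly <- attr(Z, "polymorphic")
  S_total <- tcrossprod(Z)            # sum over polymorphic SNPs (others are 0)
  m_total <- sum(poly)
  n_panel <- ncol(X)
  rows <- lapply(seq_along(blocks), function(b) {
    idx <- blocks[[b]]
    mp <- sum(poly[idx])
    row <- tryCatch({
      if (mp == 0) stop_param("block %d entirely monomorphic", b)
      Sb <- tcrossprod(Z[, idx, drop = FALSE])
      Ab <- Sb / mp
      Ac <- (S_total - Sb) / (m_total - mp)
      part <- partition_by_pathway(n_panel, region_idx = idx)
      grms <- list(region = structure(list(A = Ab, ids = rownames(X), n_snps = mp),
                                      class = "grm"),
                   complement = structure(list(A = Ac, ids = rownames(X),
                                               n_snps = m_total - mp), class = "grm"))
      fit_region_h2(X, y, covariates, part, grms = grms, ...)
    }, error = function(e) {
      warning(sprintf("block %d failed: %s", b, conditionMessage(e)))
      data.frame(hR2 = NA, se_R = NA, hC2 = NA, se_C = NA, lrt_stat = NA,
                 p_lrt = NA, n_region_snps = length(idx), pct_snp = NA,
                 pct_h2 = NA, enrichment = NA, loglik_full = NA,
                 loglik_null = NA, converged = FALSE)
    })
    cbind(data.frame(block = b,
                     start_idx = min(idx), end_idx = max(idx),
                     start_bp = if (!is.null(snps)) snps$pos[min(idx)] else NA,
                     end_bp = if (!is.null(snps)) snps$pos[max(idx)] else NA),
          row)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- bonferroni(out$p_lrt, length(blocks))
  class(out) <- c("block_scan", "data.frame")
  out
}

#' Circular genomic permutation null for a SNP-set statistic
#'
#' Each permutation rotates every index of the observed region by one
#' shared uniform offset k in {1, ..., m - 1} modulo m along the
#' position-ordered panel, preserving set size and inter-SNP spacing
#' (hence the local LD structure of the permuted sets).
#' p_perm = (r + 1) / (n_perm + 1) with r the number of null statistics
#' >= the observed one.
#'
#' @param m_panel number of panel SNPs (panel assumed ordered by
#'   chromosome then position).
#' @param region_idx observed SNP index set.
#' @param statistic_fn function(integer index set) -> scalar statistic.
#' @param n_perm number of rotations (>= 100).
#' @param seed RNG seed for the offsets.
#' @return a `circular_null`: list(observed, null_stats, offsets, p_perm,
#'   n_perm).
#' @export
circular_null <- function(m_panel, region_idx, statistic_fn, n_perm = 1000,
                          seed = 1L) {
  if (n_perm < 100) stop_param("n_perm must be >= 100")
  region_idx <- sort(unique(as.integer(region_idx)))
  if (length(region_idx) >= m_panel)
    stop_param("region equals the whole panel: no rotation null exists")
  observed <- statistic_fn(region_idx)
  with_seed(seed, {
    offsets <- sample.int(m_panel - 1L, n_perm, replace = TRUE)
    null_stats <- vapply(offsets, function(k)
      statistic_fn(((region_idx - 1L + k) %% m_panel) + 1L), 0)
    r <- sum(null_stats >= observed)
    structure(list(observed = observed, null_stats = null_stats,
                   offsets = offsets, p_perm = (r + 1) / (n_perm + 1),
                   n_perm = n_perm), class = "circular_null")
  })
}
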