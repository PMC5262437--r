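# Pipeline orchestration: stage-1 pathway association, stage-2 multilevel
# regional heritability gated on stage-1 significance, PRS profiling, and
# TSV report emission with a structured filter ledger.

#' Build / validate a pipeline configuration
#'
#' Accepts a nested list (e.g. parsed from YAML) and fills defaults:
#' QC thresholds (maf >= 0.01, info >= 0.8), GRM relatedness cutoff 0.025,
#' FDR level 0.05, SNP-to-gene window 0 kb, stage-1 engine, permutation
#' counts, block-scan window (200 SNPs), PRS sweep (cutoffs 0.2/0.5/1,
#' clumping on+off, bins 10/20/50), and the replication Bonferroni ledger
#' (pathways_forward x datasets + pathways_reverse).
#'
#' @param x list of overrides (possibly nested under the same names).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(x = list()) {
  defaults <- list(
    engine = "grass",                 # or "magenta"
    maf_min = 0.01, info_min = 0.8,
    grm_cutoff = 0.025,
    fdr_level = 0.05,
    window_kb = 0,
    n_perm_stage1 = 999,
    n_perm_circular = 1000,
    block_window = 200,
    prs_cutoffs = c(0.2, 0.5, 1),
    prs_clumping = c(FALSE, TRUE),
    prs_bins = c(10, 20, 50),
    clump_r2 = 0.25, clump_window_kb = 250,
    ledger = list(pathways_forward = 4, datasets = 1, pathways_reverse = 1),
    seed = 1L,
    sim = NULL)
  cfg <- utils::modifyList(defaults, x)
  stopifnot(cfg$fdr_level > 0, cfg$fdr_level <= 1, cfg$grm_cutoff > 0,
            all(cfg$prs_cutoffs > 0), all(cfg$prs_cutoffs <= 1))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Replication-mode Bonferroni family size
#'
#' n_bonf = pathways_forward x datasets + pathways_reverse, the declared
#' test ledger for cross-sample replication (forward tests of each
#' discovered pathway in every replication dataset, plus
#' reverse-direction tests).
#'
#' @param pathways_forward,datasets,pathways_reverse nonnegative counts.
#' @return integer family size.
#' @export
replication_bonf_n <- function(pathways_forward, datasets, pathways_reverse) {
  n <- pathways_forward * datasets + pathways_reverse
  if (n < 1) stop_param("ledger gives an empty test family")
  as.integer(n)
}

#' Stage 1: pathway association over all pathways
#'
#' Engine "grass" (genotype-based eigenSNP ridge + permutation) or
#' "magenta" (summary-statistic percentile enrichment).  An FDR column is
#' appended; the significant set is FDR <= `fdr_level`.
#'
#' @param cfg `pipeline_config`.
#' @param data list with `cohort` (genotypes/phenotype/covariates),
#'   `annotation` (genes/pathways/gene_snps) and, for the summary engine,
#'   `summary`.
#' @return data.frame (rank, database, pathway, p, p_fdr, eff_gene_size,
#'   exp_count, obs_count, significant).
#' @export
run_stage1 <- function(cfg, data) {
  ann <- data$annotation
  if (cfg$engine == "magenta") {
    if (is.null(data$summary))
      stop_param("summary engine requested but no summary statistics supplied")
    keep <- qc_filter(data.frame(maf = data$summary$MAF, info = data$summary$INFO),
                      cfg$maf_min, cfg$info_min)
    summ <- data$summary[keep, , drop = FALSE]
    gene_map <- lapply(ann$gene_snps, function(i)
      which(summ$SNP %in% data$summary$SNP[i]))
    gt <- adjust_gene_scores(gene_min_p(summ, gene_map, ann$genes))
    res <- magenta_enrichment(gt, ann$pathways, n_null = max(1000, cfg$n_perm_stage1 + 1),
                              seed = derive_seed(cfg$seed, "stage1"))
  } else {
    cohort <- data$cohort
    res <- do.call(rbind, lapply(names(ann$pathways), function(pw) {
      sets <- ann$gene_snps[ann$pathways[[pw]]]
      t <- grass_pathway_test(cohort$genotypes, cohort$phenotype,
                              cohort$covariates, sets,
                              n_perm = cfg$n_perm_stage1,
                              seed = derive_seed(cfg$seed, paste0("stage1-", pw)))
      data.frame(pathway = pw, p = t$p, eff_gene_size = length(sets),
                 exp_count = NA_real_, obs_count = NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  res$p_fdr <- bh_fdr(res$p)
  res$significant <- res$p_fdr <= cfg$fdr_level
  res <- res[order(res$p), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res$database <- "synthetic"
  rownames(res) <- NULL
  res[, c("rank", "database", "pathway", "p", "p_fdr", "eff_gene_size",
          "exp_count", "obs_count", "significant")]
}

#' Stage 2: multilevel regional heritability for significant pathways
#'
#' For each stage-1-significant pathway: two-GRM pathway-level fit with
#' FDR over the significant set and a circular-permutation p; for
#' pathways passing (FDR <= level), per-gene fits; for genes passing
#' (nominal p <= 0.05), a block scan.  Pathways failing individually do
#' not stop the others.
#'
#' @param cfg `pipeline_config`.
#' @param data as in [run_stage1()].
#' @param stage1 the stage-1 table.
#' @param y response override (defaults to the cohort phenotype; pass the
#'   liability for quantitative-scale fits).
#' @return list(pathway_table, gene_table, block_scans).
#' @export
run_stage2 <- function(cfg, data, stage1, y = NULL) {
  cohort <- data$cohort; ann <- data$annotation
  y <- y %||% cohort$phenotype
  sig <- stage1$pathway[stage1$significant]
  if (!length(sig))
    return(list(pathway_table = NULL, gene_table = NULL, block_scans = list()))
  m_panel <- ncol(cohort$genotypes$dosage)
  # one standardization pass serves every rotation of the circular null
  Z <- standardize_dosages(cohort$genotypes$dosage)
  poly <- attr(Z, "polymorphic")
  S_total <- tcrossprod(Z)
  m_poly <- sum(poly)
  region_h2_stat <- function(idx) {
    mp <- sum(poly[idx])
    if (mp == 0) return(0)
    Sb <- tcrossprod(Z[, idx, drop = FALSE])
    fit <- reml_fit(y, cohort$covariates,
                    list(region = Sb / mp,
                         complement = (S_total - Sb) / (m_poly - mp)))
    unname(fit$proportions["region"])
  }
  rows <- lapply(sig, function(pw) {
    tryCatch({
      part <- partition_by_pathway(m_panel, ann, pw)
      fit <- fit_region_h2(cohort$genotypes, y, cohort$covariates, part)
      cp <- circular_null(m_panel, part$region, region_h2_stat,
                          n_perm = max(100, min(cfg$n_perm_circular, 199)),
                          seed = derive_seed(cfg$seed, paste0("circ-", pw)))
      cbind(data.frame(pathway = pw), fit, p_perm = cp$p_perm)
    }, error = function(e) {
      warning(sprintf("stage-2 pathway '%s' failed: %s", pw, conditionMessage(e)))
      NULL
    })
  })
  ptab <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(ptab))
    return(list(pathway_table = NULL, gene_table = NULL, block_scans = list()))
  ptab$p_lrt_fdr <- bh_fdr(ptab$p_lrt)

  gene_rows <- list(); scans <- list()
  for (pw in ptab$pathway[ptab$p_lrt_fdr <= cfg$fdr_level]) {
    for (g in ann$pathways[[pw]]) {
      idx <- ann$gene_snps[[g]]
      if (!length(idx)) next
      row <- tryCatch({
        part <- partition_by_pathway(m_panel, region_idx = idx)
        cbind(data.frame(pathway = pw, gene = g),
              fit_region_h2(cohort$genotypes, y, cohort$covariates, part))
      }, error = function(e) NULL)
      if (!is.null(row)) gene_rows[[paste(pw, g)]] <- row
    }
  }
  gtab <- if (length(gene_rows)) do.call(rbind, gene_rows) else NULL
  if (!is.null(gtab)) {
    rownames(gtab) <- NULL
    for (i in which(gtab$p_lrt <= 0.05)) {
      g <- gtab$gene[i]
      blocks <- make_blocks(ann$gene_snps[[g]],
                            window_n = min(cfg$block_window,
                                           max(2, length(ann$gene_snps[[g]]))))
      scans[[g]] <- scan_gene(cohort$genotypes, y, cohort$covariates, blocks)
    }
  }
  list(pathway_table = ptab, gene_table = gtab, block_scans = scans)
}

#' PRS profiling sweep
#'
#' Full sweep over p-value cutoffs x clumping x bin counts for the
#' whole-genome SNP set and the candidate-pathway SNP set: fixed-effect
#' logistic evaluation (delta Nagelkerke R2, AUC) per cutoff, and the
#' PRS-bin LMM per (cutoff, B).
#'
#' @param cfg `pipeline_config`.
#' @param data list with `cohort`, `annotation`, `summary`.
#' @param candidate_pathway pathway name for the restricted score.
#' @return list(fixed = data.frame, lmm = data.frame).
#' @export
run_prs <- function(cfg, data, candidate_pathway) {
  if (is.null(data$summary)) stop_param("PRS profiling needs discovery summary statistics")
  if (is.null(candidate_pathway)) stop_param("candidate pathway unset")
  cohort <- data$cohort; ann <- data$annotation
  keep <- qc_filter(data.frame(maf = data$summary$MAF, info = data$summary$INFO),
                    cfg$maf_min, cfg$info_min)
  summ <- data$summary[keep, , drop = FALSE]
  gene_map <- map_snps_to_genes(cohort$genotypes$snps, ann$genes, cfg$window_kb)
  path_set <- cohort$genotypes$snps$snp_id[
    pathway_snps(ann$pathways[[candidate_pathway]], gene_map)]
  grm <- compute_grm(cohort$genotypes)
  fixed <- list(); lmm <- list()
  for (cl in cfg$prs_clumping) {
    snp_pool <- if (cl) clump(summ, cohort$genotypes, cfg$clump_r2,
                              cfg$clump_window_kb) else summ$SNP
    for (set_name in c("whole_genome", "pathway")) {
      set_snps <- if (set_name == "pathway") intersect(snp_pool, path_set) else snp_pool
      for (cut in cfg$prs_cutoffs) {
        prs <- compute_prs(cohort$genotypes, summ, cut, set_snps)
        if (attr(prs, "n_snps_used") == 0 || stats::sd(prs) == 0) next
        ev <- logistic_eval(cohort$phenotype, prs, cohort$covariates)
        fixed[[length(fixed) + 1L]] <- data.frame(
          set = set_name, clumping = cl, cutoff = cut,
          n_snps = attr(prs, "n_snps_used"),
          delta_r2_pct = 100 * ev$delta_r2, p = ev$p,
          auc = auc(prs, cohort$phenotype))
        for (B in cfg$prs_bins) {
          if (B > length(prs) / 2) next
          S <- build_bin_matrix(prs, B)
          fitb <- tryCatch(
            prs_bin_lmm(cohort$phenotype, cohort$covariates,
                        stats::setNames(list(S), "prs_bin"), grm = grm),
            error = function(e) NULL)
          if (is.null(fitb)) next
          lmm[[length(lmm) + 1L]] <- data.frame(
            set = set_name, clumping = cl, cutoff = cut, B = B,
            proportion_pct = 100 * fitb$proportion[fitb$component == "prs_bin"],
            se = fitb$se[fitb$component == "prs_bin"],
            p_lrt = fitb$p_lrt[fitb$component == "prs_bin"])
        }
      }
    }
  }
  list(fixed = do.call(rbind, fixed), lmm = do.call(rbind, lmm))
}

#' Run the whole pipeline on a simulated cohort
#'
#' simulate -> QC/pruning ledger -> stage 1 -> gated stage 2 -> PRS sweep.
#'
#' @param cfg `pipeline_config`; `cfg$sim` holds [sim_config()] arguments.
#' @return a `report_bundle` list: stage1, stage2, prs, log.
#' @export
run_pipeline <- function(cfg) {
  cfg <- pipeline_config(unclass(cfg))
  sim_args <- cfg$sim %||% list()
  sim_args$seed <- sim_args$seed %||% cfg$seed
  sc <- do.call(sim_config, sim_args)
  data <- simulate_cohort(sc)
  log <- list(seed = cfg$seed, n_target = nrow(data$cohort$genotypes$dosage),
              m_snps = ncol(data$cohort$genotypes$dosage))
  # relatedness pruning ledger (synthetic cohorts are unrelated; counts recorded)
  grm <- compute_grm(data$cohort$genotypes)
  kept <- prune_related(grm, cfg$grm_cutoff)
  log$individuals_input <- length(grm$ids)
  log$individuals_kept <- length(kept)
  log$individuals_removed <- log$individuals_input - log$individuals_kept
  if (log$individuals_removed > 0) {
    ch <- data$cohort
    ch$genotypes$dosage <- ch$genotypes$dosage[kept, , drop = FALSE]
    ch$genotypes$ids <- ch$genotypes$ids[kept]
    ch$phenotype <- ch$phenotype[kept]
    ch$liability <- ch$liability[kept]
    ch$covariates <- ch$covariates[kept, , drop = FALSE]
    data$cohort <- ch
  }
  qc_keep <- qc_filter(data.frame(maf = data$summary$MAF, info = data$summary$INFO),
                       cfg$maf_min, cfg$info_min)
  log$snps_input <- nrow(data$summary)
  log$snps_post_qc <- length(qc_keep)
  stage1 <- run_stage1(cfg, data)
  stage2 <- run_stage2(cfg, data, stage1)
  prs <- tryCatch(run_prs(cfg, data, data$annotation$causal_pathway),
                  error = function(e) { warning(conditionMessage(e)); NULL })
  structure(list(stage1 = stage1, stage2 = stage2, prs = prs, log = log,
                 config = cfg), class = "report_bundle")
}

#' Write a report bundle as TSV files
#'
#' Fixed schemas mirroring the pipeline's printed tables, plus a run log
#' with every filter count.  Re-running on the same bundle rewrites
#' identical bytes.
#'
#' @param bundle `report_bundle` from [run_pipeline()] (or a compatible
#'   list).
#' @param outdir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_reports <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    data.table::fwrite(df, p, sep = "\t")
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$stage1)) wr(bundle$stage1, "stage1_pathways.tsv")
  if (!is.null(bundle$stage2$pathway_table))
    wr(bundle$stage2$pathway_table, "stage2_pathway_h2.tsv")
  if (!is.null(bundle$stage2$gene_table))
    wr(bundle$stage2$gene_table, "stage2_gene_h2.tsv")
  for (g in names(bundle$stage2$block_scans))
    wr(bundle$stage2$block_scans[[g]], sprintf("stage2_scan_%s.tsv", g))
  if (!is.null(bundle$prs$fixed)) wr(bundle$prs$fixed, "prs_fixed.tsv")
  if (!is.null(bundle$prs$lmm)) wr(bundle$prs$lmm, "prs_lmm.tsv")
  log_df <- data.frame(key = names(bundle$log),
                       value = vapply(bundle$log, function(v)
                         paste(format(v, scientific = FALSE), collapse = ","), ""))
  wr(log_df, "run_log.tsv")
  invisible(paths)
}
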