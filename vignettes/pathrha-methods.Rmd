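---
title: "Pathway association, regional heritability and polygenic risk profiling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway association, regional heritability and polygenic risk profiling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

Genome-wide association studies of highly polygenic case/control traits
often detect no individual locus, while twin and SNP heritability make
clear that genetic signal exists.  `pathrha` implements a two-stage
strategy for such traits: first test whether association signal
*aggregates* in curated biological pathways, then quantify and localize
the heritability those pathways carry, and finally ask whether a
polygenic risk score (PRS) restricted to the implicated pathway predicts
case status.

The pipeline is:

1. **Stage 1 — pathway association.**  Either a genotype-based engine
   (per-gene eigenSNPs entering a ridge-penalised logistic regression,
   significance by phenotype permutation) or a summary-statistic engine
   (gene min-p scores, confounder-corrected, tested for enrichment above
   the 95th percentile against random gene sets).  Pathway p-values are
   FDR-adjusted across the full pathway collection.
2. **Stage 2 — multilevel regional heritability**, gated on stage-1
   significance.  For each significant pathway the SNP panel is
   partitioned into (pathway SNPs, remaining SNPs), two genomic
   relationship matrices (GRMs) are fitted jointly by restricted maximum
   likelihood (REML), and the pathway component is tested with a
   boundary-corrected likelihood-ratio test (LRT).  Signal is then
   narrowed to genes and, inside associated genes, to fixed-size SNP
   blocks by a window scan.  A circular genomic permutation null checks
   that enrichment is not an artefact of set size or local LD.
3. **PRS profiling.**  Scores built from discovery-sample effect sizes
   (log odds ratios) under p-value thresholds, with or without LD
   clumping, for the whole genome and for the candidate pathway;
   evaluated as a fixed effect (Nagelkerke \(\Delta R^2\), Mann–Whitney
   AUC) and as a random effect through a PRS-bin relationship matrix.

# Models and statistics

## GREML and regional heritability

For phenotype vector \(y\) (a binary trait is analysed 0/1 on the
observed scale, as GCTA does), covariates \(X\) and SNP sets
\(S_1, \dots, S_K\),

\[ y = X\beta + \sum_k u_k + e, \qquad u_k \sim N(0, \sigma^2_k A_k),
   \quad e \sim N(0, \sigma^2_e I), \]

where \(A_k\) is the GRM of SNP set \(k\):
\(A_{jl} = \tfrac1m \sum_i (x_{ij} - 2p_i)(x_{il} - 2p_i) / (2p_i(1-p_i))\)
with sample allele frequencies \(p_i\); monomorphic SNPs are excluded
from \(m\) and missing dosages are mean-imputed per SNP.

`reml_fit()` maximises the restricted likelihood by average-information
(AI) iterations with an EM fallback for the first three steps and
GCTA-style nonnegativity (components truncated at \(10^{-6}\hat V_p\)).
Two numerical safeguards matter in practice and are part of the design:

* the AI Newton step is solved in the *free* coordinates only —
  components pinned at the floor with negative score are excluded, which
  prevents the coupled step from turning into a persistent descent
  direction at the boundary;
* after the AI loop, a projected Newton decrement is computed from the
  analytic score and the AI matrix; if it indicates likelihood is
  still available (more than \(10\times\) the convergence tolerance),
  a bounded L-BFGS-B polish with the analytic gradient finishes the
  fit.  Without this, null fits can stall a few \(10^{-1}\) log-units
  short of the constrained optimum and the LRT can go negative.

Convergence is declared at \(|\Delta \ell_R| < 10^{-4}\).  Standard
errors come from the inverse AI matrix; proportion SEs by the delta
method.  The regional fit reports
\(h^2_R = \sigma^2_R / (\sigma^2_R + \sigma^2_C + \sigma^2_e)\),
\(\%SNP = 100\, m_R / m\), \(\%h^2 = 100\, h^2_R/(h^2_R + h^2_C)\) and
the enrichment ratio \(\%h^2 / \%SNP\).

The LRT for one nonnegativity-constrained component uses the boundary
mixture \(\tfrac12\chi^2_0 + \tfrac12\chi^2_1\): `lrt_p()` returns
\(p = 0.5\) at statistic 0 and \(0.5\,\Pr(\chi^2_1 \ge T)\) otherwise.
The reference distribution is a design choice (the referent literature
does not state one); the truncation-at-zero constraint handling is what
makes this mixture the appropriate null.

A binary trait's observed-scale estimate can be converted with
`observed_to_liability()` (Robertson transformation
\(h^2_{liab} = h^2_{obs}\, K^2(1-K)^2 / (P(1-P)\,z^2)\)); it is off by
default because no population prevalence is asserted by the pipeline.

## Stage-1 engines

**Genotype engine.**  Each gene's standardized genotypes are compressed
to eigenSNPs (principal component scores retaining \(\ge 95\%\)
variance).  All pathway eigenSNPs plus covariates enter a logistic
regression with a ridge penalty on the eigenSNP block; the statistic is
the deviance reduction relative to the covariates-only model.  The
penalty is chosen once by 5-fold cross-validated deviance on the
observed phenotype and then held fixed while the phenotype is permuted;
\(p = (r+1)/(B+1)\).  The permutation null keeps the test exact
regardless of the statistic's internals, which is why a deviance-based
ridge statistic can stand in for the original group-penalised
formulation without changing validity.

**Summary-statistic engine.**  The gene score is the minimum SNP
p-value, which is biased by gene size; \(-\log_{10}(\min p)\) is
regressed on SNP count and gene length (kb) and the residual rank maps
to an adjusted \(p = \mathrm{rank}/(n_{genes}+1)\).  A pathway's
observed count is its number of genes at or below the 5th percentile of
adjusted p-values; the expected count is \(0.05 \times\) effective
size.  Because random same-size gene sets drawn without replacement
give a hypergeometric null count, the Monte Carlo null is sampled with
`rhyper()` — distributionally identical to materialising random sets,
and fast.  The reduced confounder set \{SNP count, gene kb\} (the
original tool also corrects for LD-pruned SNP count and recombination
hotspots) and the Benjamini–Hochberg FDR over nominal pathway p-values
are documented deviations chosen for reproducibility.

## Circular genomic permutation

`circular_null()` rotates the observed SNP index set along the
position-ordered panel by a shared uniform offset
\(k \in \{1, \dots, m-1\}\), preserving set size and inter-SNP spacing,
hence local LD structure.  \(p_{perm} = (r+1)/(B+1)\).  This is the null
used for pathway-level regional heritability and for pathway PRS.

## PRS profiling

Scores are \(s_i = \sum_{p_s \le c} x_{is} w_s\) with \(w = \log OR\)
from the discovery sample, alleles aligned to the target panel (dosage
flipped when the effect allele is the panel's other allele, SNP dropped
when irreconcilable).  Optional greedy clumping keeps the best p-value
per LD neighbourhood (default \(r^2 > 0.25\) within 250 kb — the
referent analysis states clumping was used but no parameters, so
conventional defaults are used and exposed).  Fixed-effect evaluation
reports \(\Delta R^2_N\) (Nagelkerke, observed scale, covariates age,
age\(^2\), sex and four ancestry PCs) and Mann–Whitney AUC with
half-ties.

The **PRS-bin relationship matrix** treats PRS similarity as a random
effect: individuals are ranked by PRS and cut into \(B\) equal-count
bins; \(S_{ij} = 1\) if \(i, j\) share a bin.  This block-of-ones
matrix is the covariance of a bin-level random intercept — the simplest
positive-semidefinite "PRS similarity" for which the random-effect
model is well-posed and sweepable over \(B\).  The referent
construction lives in an unavailable supplement, so this indicator form
is an explicit interpretation, stated prominently rather than presented
as a reconstruction.  `prs_bin_lmm()` fits one or more bin matrices,
optionally jointly with a GRM, via `reml_fit()` and tests each bin
matrix by the boundary LRT.

# The synthetic cohort

Every stage is exercised on simulated data with the statistical
structure the analyses assume:

* **Genotypes** — two independent haplotypes per individual, each a
  latent Gaussian with exchangeable within-block correlation \(\rho\)
  (default 0.7, blocks of 50 SNPs) thresholded at the allele-frequency
  quantile.  This gives tunable blockwise LD without a coalescent
  simulator.  MAFs are uniform on \([0.05, 0.5]\) by default.
* **Annotation** — genes tile the panel; pathway membership is a seeded
  random assignment of genes, so pathway SNP sets are genomically
  scattered, as real pathways are.
* **Phenotype** — liability \(= G_{path} + G_{bg} + e\); effects
  \(\beta \sim N(0,\, h^2/m_c/(2p(1-p)))\) at causal SNPs (equal
  expected variance per causal SNP, the standard GCTA-compatible
  architecture), each genetic component centred (so the realized
  prevalence tracks \(K\) rather than drifting with the random sign of
  \(\sum_j 2p_j\beta_j\)) and rescaled to explain exactly its target
  in-sample variance; cases are liabilities above
  \(\Phi^{-1}(1-K)\).  Default \(K = 0.15\): the referent trait (major
  depressive disorder) has no stated prevalence anywhere in the source
  analysis, so this is a configuration choice — the conventional
  lifetime-prevalence figure — not a reproduced value.  Background
  heritability is spread over all SNPs outside the causal pathway's
  genes.
* **Ascertainment** — the cohort is resampled from an oversampled pool
  to the requested case fraction (default 0.5); `case_fraction = NULL`
  gives an unascertained sample for liability-scale work.
* **Discovery summary statistics** — an independent cohort on the same
  panel, dichotomised at the same threshold, one logistic regression
  per SNP (vectorised Newton solver, verified against `glm`), with
  imputation info scores drawn U(0.6, 1) so QC has something to remove.

What the generator does *not* emulate: realistic demography or
recombination-map LD, genotyping error, chromosome structure beyond a
single ordered panel, population stratification, or case
misclassification.  A green test therefore establishes internal
statistical correctness (calibration, recovery, localization) — not
robustness to the confounders of real cohort data.

# Numerical and design choices

* REML start values split the phenotypic variance equally across
  components; EM for 3 iterations, then free-coordinate AI steps with
  step-halving, then the KKT-gated L-BFGS-B polish.
* Identity-proportional component matrices are rejected up front
  (not separable from the residual).
* Permutation p-values are \((r+1)/(B+1)\) everywhere — never zero.
* The window scan uses non-overlapping consecutive blocks by default
  (stride = window); a true sliding overlap is available via `stride`.
  Window 200 SNPs by default, with the half-density 100-SNP choice
  available for sparser panels.
* Gene-level and block-level fits keep the complement GRM in the model
  (two-component fits throughout), matching the pathway-level design.
* Replication-mode Bonferroni counts come from a declared test ledger
  (`replication_bonf_n(forward, datasets, reverse)`), reproducing
  \(4 + 1 = 5\) and \(2\times(1+3)+1 = 9\), rather than hard-coded
  family sizes.
* `prune_related()` is greedy (drop the individual in most offending
  pairs; ties by mean relatedness, then later ID) — the exact
  maximum-independent-set objective is NP-hard; the greedy rule matches
  the referent tool's stated goal and is verified against brute force
  on small instances.
* SNP-to-gene mapping uses strict genic coordinates (window 0 kb) by
  default since no flanking window is stated by the referent analysis;
  the window is configurable.

# Testing and scale

The acceptance suite checks (1) printed-table arithmetic exactly,
(2) the AI-REML optimum against a dense profiled grid search at
\(n = 60\) within \(10^{-4}\) log-units, (3) two-GRM parameter recovery
within 2 reported SEs in \(\ge 90\%\) of 20 replicates,
(4) Kolmogorov–Smirnov uniformity of permutation p-values under the
null (200 replicates), (5) the 50:50 boundary mixture of the LRT,
(6) hand-arithmetic PRS/AUC/Nagelkerke oracles, and (7) localization of
injected variance to the correct scan block in \(\ge 80\%\) of 20
replicates.  Criteria 3, 5 and 7 run at reduced sizes
(\(n = 1000/500/600\) rather than 2000) purely to fit a one-CPU test
budget; replicate counts and thresholds are unchanged and the
quantities tested (SE coverage, mixture mass, minimum-p localization)
are size-invariant because SEs are computed at the size actually run.
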