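# GREML core: GRM construction, multi-component average-information REML
# with EM fallback, boundary-corrected LRT, observed<->liability conversion.

#' Compute a genomic relationship matrix
#'
#' GCTA-style estimator: A_jk = (1/m) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) /
#' (2 p_i (1 - p_i)) with p_i the sample allele frequency of SNP i.
#' Missing dosages are mean-imputed; monomorphic SNPs are excluded from m.
#'
#' @param genotypes a `genotypes` object or a plain dosage matrix.
#' @param snp_idx optional integer subset of SNP columns.
#' @return a `grm` object: list(A, ids, n_snps).
#' @export
compute_grm <- function(genotypes, snp_idx = NULL) {
  X <- if (inherits(genotypes, "genotypes")) genotypes$dosage else genotypes
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  if (!is.null(snp_idx)) X <- X[, snp_idx, drop = FALSE]
  Z <- standardize_dosages(X)
  m <- sum(attr(Z, "polymorphic"))
  if (m == 0) stop_param("all SNPs in the subset are monomorphic")
  A <- tcrossprod(Z[, attr(Z, "polymorphic"), drop = FALSE]) / m
  structure(list(A = A, ids = ids, n_snps = m), class = "grm")
}

#' Multi-component REML fit (average information with EM fallback)
#'
#' Fits y = Xb + sum_k u_k + e with u_k ~ N(0, sigma2_k A_k),
#' e ~ N(0, sigma2_e I) by restricted maximum likelihood.  The first
#' `em_iters` iterations use EM updates (monotone in the restricted
#' likelihood), after which average-information Newton steps with
#' step-halving take over.  Components are constrained nonnegative by
#' truncation at a small floor (GCTA-style), which is the boundary
#' behaviour the 50:50 chi-square LRT mixture assumes.
#'
#' @param y numeric response (binary traits are analysed 0/1 on the
#'   observed scale).
#' @param covariates data.frame / matrix of fixed covariates or NULL; an
#'   intercept is always added.
#' @param K list of `grm` objects or symmetric matrices, one per genetic
#'   variance component.
#' @param max_iter,tol iteration cap and |delta log-likelihood|
#'   convergence tolerance.
#' @param em_iters number of initial EM iterations.
#' @param verbose print per-iteration log-likelihoods.
#' @return a `vc_fit`: sigma2 (named, residual last), se, proportions and
#'   their SEs, loglik, converged, iterations, n.
#' @export
reml_fit <- function(y, covariates = NULL, K, max_iter = 100L, tol = 1e-4,
                     em_iters = 3L, verbose = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 50) stop_param("reml_fit needs n >= 50, got %d", n)
  if (inherits(K, "grm") || is.matrix(K)) K <- list(K)
  A <- lapply(K, function(k) if (inherits(k, "grm")) k$A else k)
  nc <- length(A)
  for (k in seq_len(nc)) {
    if (!is.matrix(A[[k]]) || nrow(A[[k]]) != n || ncol(A[[k]]) != n)
      stop_param("component %d is not an %d x %d matrix", k, n, n)
    if (max(abs(A[[k]] - diag(n))) < 1e-10)
      stop_param("component %d equals the identity: not separable from the residual", k)
  }
  if (nc > 1) {
    for (k in seq_len(nc - 1)) for (l in (k + 1):nc) {
      sc <- sum(A[[k]] * A[[l]]) / sqrt(sum(A[[k]]^2) * sum(A[[l]]^2))
      if (sc > 1 - 1e-10)
        stop_param("components %d and %d are proportional: not identifiable", k, l)
    }
  }
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  p <- ncol(X)

  vp <- stats::var(y)
  theta <- rep(vp / (nc + 1), nc + 1)          # components then residual
  floor_v <- 1e-6 * vp
  Ai <- c(A, list(diag(n)))

  loglik_at <- function(theta) {
    V <- matrix(0, n, n)
    for (k in seq_len(nc)) V <- V + theta[k] * A[[k]]
    diag(V) <- diag(V) + theta[nc + 1]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    VX <- Vi %*% X
    XtVX <- crossprod(X, VX)
    cx <- chol(XtVX)
    P <- Vi - VX %*% chol2inv(cx) %*% t(VX)
    Py <- as.numeric(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cx))) +
                  sum(y * Py))
    list(ll = ll, P = P, Py = Py)
  }

  # score and average-information pieces at the current state
  derivs_at <- function(st) {
    P <- st$P; Py <- st$Py
    trPA <- numeric(nc + 1); ytPAPy <- numeric(nc + 1)
    APy <- vector("list", nc + 1)
    for (k in seq_len(nc + 1)) {
      trPA[k] <- if (k <= nc) sum(P * A[[k]]) else sum(diag(P))
      APy[[k]] <- if (k <= nc) as.numeric(A[[k]] %*% Py) else Py
      ytPAPy[k] <- sum(Py * APy[[k]])
    }
    AImat <- matrix(0, nc + 1, nc + 1)
    for (k in seq_len(nc + 1)) for (l in k:(nc + 1)) {
      AImat[k, l] <- AImat[l, k] <- 0.5 * sum(APy[[k]] * (P %*% APy[[l]]))
    }
    list(score = 0.5 * (ytPAPy - trPA), AImat = AImat,
         trPA = trPA, ytPAPy = ytPAPy)
  }

  st <- loglik_at(theta)
  if (is.null(st)) stop_param("initial variance matrix not positive definite")
  ll_old <- st$ll
  converged <- FALSE
  dv <- NULL
  it <- 0L
  for (it in seq_len(max_iter)) {
    dv <- derivs_at(st)
    if (it <= em_iters) {
      theta_new <- (theta^2 * dv$ytPAPy + theta * n - theta^2 * dv$trPA) / n
    } else {
      # components pinned at the floor whose score is negative stay fixed;
      # Newton step is taken in the free coordinates only
      free <- !(theta <= floor_v * 1.01 & dv$score < 0)
      if (!any(free)) { converged <- TRUE; break }
      delta <- numeric(nc + 1)
      Af <- dv$AImat[free, free, drop = FALSE]
      df <- tryCatch(solve(Af, dv$score[free]), error = function(e) NULL)
      if (is.null(df)) df <- dv$score[free] / pmax(diag(Af), 1e-8)
      delta[free] <- df
      theta_new <- theta + delta
    }
    theta_new <- pmax(theta_new, floor_v)
    st_new <- loglik_at(theta_new)
    halvings <- 0L
    while ((is.null(st_new) || (it > em_iters && st_new$ll < ll_old - 1e-10)) &&
           halvings < 10L) {
      theta_new <- (theta + theta_new) / 2
      theta_new <- pmax(theta_new, floor_v)
      st_new <- loglik_at(theta_new)
      halvings <- halvings + 1L
    }
    if (is.null(st_new)) break
    if (it <= em_iters && st_new$ll < ll_old - 1e-8)
      warning("EM iteration decreased the restricted log-likelihood")
    dll <- st_new$ll - ll_old
    if (verbose) message(sprintf("iter %d  loglik %.6f  delta %.2e", it, st_new$ll, dll))
    theta <- theta_new
    st <- st_new
    if (abs(dll) < tol && it > 1L) { ll_old <- st$ll; converged <- TRUE; break }
    ll_old <- st$ll
  }

  # Boundary polish: truncation at the floor can stall the AI updates short
  # of the constrained optimum.  When the projected Newton decrement says
  # likelihood is still on the table, finish with a bounded quasi-Newton
  # pass using the analytic score as gradient.
  kkt_gain <- function(dv) {
    free <- theta > floor_v * 1.01 | dv$score > 0
    if (!any(free)) return(0)
    s <- dv$score[free]
    g <- tryCatch(0.5 * sum(s * solve(dv$AImat[free, free, drop = FALSE], s)),
                  error = function(e) Inf)
    if (!is.finite(g) || g < 0) Inf else g
  }
  if (!converged || kkt_gain(dv) > 10 * tol) {
    cache <- new.env(parent = emptyenv())
    eval_at <- function(th) {
      key <- paste(format(th, digits = 17), collapse = ",")
      if (!identical(cache$key, key)) {
        cache$key <- key
        cache$st <- loglik_at(th)
        cache$dv <- if (!is.null(cache$st)) derivs_at(cache$st) else NULL
      }
      invisible(NULL)
    }
    opt <- tryCatch(stats::optim(
      theta,
      fn = function(th) { eval_at(th); if (is.null(cache$st)) 1e10 else -cache$st$ll },
      gr = function(th) { eval_at(th); if (is.null(cache$dv)) numeric(nc + 1) else -cache$dv$score },
      method = "L-BFGS-B", lower = rep(floor_v, nc + 1),
      control = list(factr = 1e9, maxit = 50L)), error = function(e) NULL)
    if (!is.null(opt) && -opt$value > ll_old) {
      theta <- opt$par
      st <- loglik_at(theta)
      ll_old <- st$ll
      dv <- derivs_at(st)
    }
    if (!is.null(opt) && opt$convergence == 0) converged <- TRUE
  }
  if (!converged)
    warning(sprintf("REML did not converge in %d iterations", it))
  AImat <- dv$AImat

  se <- tryCatch(sqrt(pmax(diag(solve(AImat)), 0)),
                 error = function(e) rep(NA_real_, nc + 1))
  total <- sum(theta)
  props <- theta / total
  # delta-method SEs for proportions using the inverse AI covariance
  prop_se <- rep(NA_real_, nc + 1)
  covm <- tryCatch(solve(AImat), error = function(e) NULL)
  if (!is.null(covm)) {
    for (k in seq_len(nc + 1)) {
      g <- rep(-theta[k] / total^2, nc + 1)
      g[k] <- g[k] + 1 / total
      prop_se[k] <- sqrt(max(0, as.numeric(t(g) %*% covm %*% g)))
    }
  }
  comp_names <- c(names(K) %||% paste0("V", seq_len(nc)), "residual")
  if (length(comp_names) != nc + 1)
    comp_names <- c(paste0("V", seq_len(nc)), "residual")
  structure(list(sigma2 = stats::setNames(theta, comp_names),
                 se = stats::setNames(se, comp_names),
                 proportions = stats::setNames(props, comp_names),
                 proportion_se = stats::setNames(prop_se, comp_names),
                 loglik = ll_old, converged = converged, iterations = it,
                 n = n, n_fixed = p), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("REML fit (n = %d, %s, %d iterations)\n", x$n,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  tab <- data.frame(estimate = x$sigma2, se = x$se,
                    proportion = x$proportions, prop_se = x$proportion_se)
  print(round(tab, 5))
  cat(sprintf("restricted log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' Likelihood-ratio test for one variance component on the boundary
#'
#' statistic = max(0, 2 (ll_full - ll_null)); the null distribution is the
#' 50:50 mixture 0.5 chi2_0 + 0.5 chi2_1 appropriate for a single
#' nonnegativity-constrained component, so p = 0.5 when the statistic is 0
#' and 0.5 Pr(chi2_1 >= statistic) otherwise.
#'
#' @param loglik_full,loglik_null restricted log-likelihoods.
#' @param tolerance slack allowed for ll_full < ll_null before erroring.
#' @return list(statistic, p).
#' @export
lrt_p <- function(loglik_full, loglik_null, tolerance = 1e-3) {
  if (loglik_full < loglik_null - tolerance)
    stop_param("full-model log-likelihood below null (%.4f < %.4f): numerical failure",
               loglik_full, loglik_null)
  stat <- max(0, 2 * (loglik_full - loglik_null))
  p <- if (stat == 0) 0.5 else 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p = p)
}

#' Convert observed-scale to liability-scale heritability
#'
#' h2_liab = h2_obs * K^2 (1-K)^2 / (P (1-P) z^2) with K the population
#' prevalence, P the sample case proportion and z the standard normal
#' density at the liability threshold qnorm(1 - K).
#'
#' @param h2_obs observed-scale estimate (negative values pass through 0
#'   with a warning).
#' @param K population prevalence in (0, 1).
#' @param P sample case proportion in (0, 1).
#' @return liability-scale heritability.
#' @export
observed_to_liability <- function(h2_obs, K, P) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1)
    stop_param("K and P must be in (0, 1)")
  if (h2_obs < 0) {
    warning("h2_obs < 0 treated as 0")
    h2_obs <- 0
  }
  z <- stats::dnorm(stats::qnorm(1 - K))
  h2_obs * K^2 * (1 - K)^2 / (P * (1 - P) * z^2)
}
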