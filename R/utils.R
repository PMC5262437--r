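# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All simulate_* / permutation code
# goes through this so results are pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a child seed from a base seed and a stream label; keeps results
# decoupled across stages while remaining reproducible.  Always < 2^31.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

# Standardize dosage columns to mean 0, variance scaled by 2p(1-p) with p the
# sample allele frequency (the GCTA convention).  Missing values are
# mean-imputed first.  Monomorphic columns come back as all-zero.
standardize_dosages <- function(X) {
  X <- impute_mean(X)
  p <- colMeans(X) / 2
  s <- sqrt(2 * p * (1 - p))
  Z <- sweep(X, 2L, 2 * p, "-")
  keep <- s > 0 & colMeans(Z^2) > 0    # polymorphic in the sample
  Z[, keep] <- sweep(Z[, keep, drop = FALSE], 2L, s[keep], "/")
  Z[, !keep] <- 0
  attr(Z, "polymorphic") <- keep
  Z
}

#' Mean-impute missing dosages per SNP
#'
#' Missing entries (NA) in a dosage matrix are replaced by the column mean of
#' the observed dosages, the standard behaviour before any GRM / REML / PRS
#' matrix algebra.  Columns that are entirely missing become 0.
#'
#' @param X numeric dosage matrix (individuals x SNPs).
#' @return matrix of the same shape with no NAs.
#' @export
impute_mean <- function(X) {
  if (!anyNA(X)) return(X)
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- cm[idx[, 2L]]
  X
}
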