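# Spearman screening of features against a covariate (temperature),
# with exact permutation p-values at small n and BH-FDR control.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, order-preserving); a thin
#' surface over [stats::p.adjust()].
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Spearman rho via mid-rank Pearson correlation.
spearman_rho <- function(x, y) cor(rank(x), rank(y))

# permutation matrices are expensive to rebuild per feature; memoise
.perm_cache <- new.env(parent = emptyenv())
cached_permutations <- function(n) {
  key <- as.character(n)
  if (is.null(.perm_cache[[key]])) .perm_cache[[key]] <- permutations_of(n)
  .perm_cache[[key]]
}

# Exact (or sampled) two-sided permutation p-value for Spearman rho.
# Permuting y leaves the rank multiset fixed, so every permuted rho
# shares the observed means and standard deviations: the whole null is
# one matrix product over the permuted rank sums.
spearman_perm_p <- function(x, y, max_exact = 8, n_perm = 10000, seed = 1L) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  denom <- (n - 1) * sd(rx) * sd(ry)
  mu <- n * mean(rx) * mean(ry)
  if (n <= max_exact) {
    idx <- cached_permutations(n)
    sums <- matrix(ry[idx], nrow(idx), n) %*% rx
    rhos <- (sums - mu) / denom
    mean(abs(rhos) >= obs - 1e-9)
  } else {
    withr::local_seed(seed)
    rhos <- vapply(seq_len(n_perm), function(i) cor(rx, sample(ry)), numeric(1))
    mean(abs(rhos) >= obs - 1e-9)
  }
}

# All permutations of 1..n as a (n!) x n matrix.
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman correlation screen against a covariate
#'
#' Correlates each feature's per-sample abundance with a covariate by
#' Spearman's rank correlation (mid-ranks for ties). P-values are exact
#' two-sided permutation probabilities when the sample count is at most
#' `max_exact` (the study's n = 7 enumerates all 5040 orderings), and
#' seeded Monte Carlo otherwise. BH-FDR is applied across assessable
#' features; a feature passes when its adjusted p is at most
#' `fdr_alpha` and |rho| is at least `rho_min`. Constant features are
#' reported as not assessable.
#'
#' @param tbl Abundance tibble (features x samples).
#' @param metadata Metadata tibble with `sample_id` and the covariate
#'   column.
#' @param covariate Name of the covariate column (default
#'   `"temperature"`).
#' @param rho_min Effect-size floor on |rho| (default 0.7).
#' @param fdr_alpha FDR level (default 0.05).
#' @param max_exact Largest n for exhaustive permutation.
#' @param n_perm,seed Monte Carlo settings beyond `max_exact`.
#' @return Tibble: `feature_id`, `rho`, `p_value`, `fdr_p`, `passes`,
#'   `assessable`.
#' @export
spearman_screen <- function(tbl, metadata, covariate = "temperature",
                            rho_min = 0.7, fdr_alpha = 0.05,
                            max_exact = 8, n_perm = 10000, seed = 1L) {
  m <- abundance_matrix(tbl)
  if (ncol(m) < 3) abort("need at least three samples")
  if (!covariate %in% names(metadata)) {
    abort(paste0("covariate column '", covariate, "' missing from metadata"))
  }
  cov <- metadata[[covariate]][match(colnames(m), metadata$sample_id)]
  if (anyNA(cov)) abort("covariate undefined for some samples")
  res <- purrr::map_dfr(rownames(m), function(f) {
    x <- m[f, ]
    if (length(unique(x)) == 1L) {
      return(tibble::tibble(feature_id = f, rho = NA_real_, p_value = NA_real_,
                            assessable = FALSE))
    }
    tibble::tibble(feature_id = f, rho = spearman_rho(x, cov),
                   p_value = spearman_perm_p(x, cov, max_exact, n_perm,
                                             substream_seed(seed, f)),
                   assessable = TRUE)
  })
  res$fdr_p <- NA_real_
  res$fdr_p[res$assessable] <- bh_fdr(res$p_value[res$assessable])
  res$passes <- !is.na(res$fdr_p) & res$fdr_p <= fdr_alpha & abs(res$rho) >= rho_min
  res[c("feature_id", "rho", "p_value", "fdr_p", "passes", "assessable")]
}
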