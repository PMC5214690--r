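# Alpha and beta diversity plus the group-comparison statistics:
# rarefaction, observed species, Shannon, Pielou, Hellinger distance,
# unweighted UniFrac, principal-coordinates embedding, the exact
# rank-sum (Mann-Whitney) test, and Tukey multiple comparisons.

# Multivariate hypergeometric subsample (without replacement) of a
# count vector to a fixed depth, by sequential conditional draws.
subsample_counts <- function(x, depth) {
  total <- sum(x)
  stopifnot(depth <= total)
  out <- integer(length(x))
  remaining <- total
  left <- depth
  for (i in seq_along(x)) {
    if (left == 0L) break
    if (remaining == x[i]) { out[i] <- left; break }
    out[i] <- rhyper(1, x[i], remaining - x[i], left)
    left <- left - out[i]
    remaining <- remaining - x[i]
  }
  out
}

#' Rarefied observed-species curves
#'
#' For each sample and rarefaction depth, subsamples the count column
#' without replacement `n_iter` times and reports the mean number of
#' features observed (count >= 1). Depths exceeding a sample's total
#' yield `NA`. Each (sample, depth, iteration) uses its own
#' pseudo-random substream derived from `seed`.
#'
#' @param tbl Abundance tibble of integer counts.
#' @param depths Increasing vector of rarefaction depths. Default spans
#'   100 to 2.2 million sequences in steps of 0.1 million.
#' @param n_iter Subsampling iterations per depth (default 10).
#' @param seed Master seed for the subsampling streams.
#' @return Tibble: `depth`, `sample_id`, `observed_species` (mean over
#'   iterations).
#' @export
rarefy_observed_species <- function(tbl,
                                    depths = c(100, seq(1e5, 2.2e6, by = 1e5)),
                                    n_iter = 10, seed = 1L) {
  if (is.unsorted(depths, strictly = TRUE) || any(depths <= 0)) {
    abort("depths must be positive and strictly increasing")
  }
  m <- abundance_matrix(tbl)
  if (any(m != round(m))) abort("rarefaction requires integer counts")
  grid <- tidyr::expand_grid(depth = depths, sample_id = colnames(m))
  grid$observed_species <- purrr::pmap_dbl(grid, function(depth, sample_id) {
    x <- m[, sample_id]
    if (depth > sum(x)) return(NA_real_)
    obs <- vapply(seq_len(n_iter), function(it) {
      withr::local_seed(substream_seed(seed, paste(sample_id, depth, it)))
      sum(subsample_counts(x, depth) > 0)
    }, numeric(1))
    mean(obs)
  })
  grid
}

#' Shannon diversity of one abundance column
#'
#' H = -sum p_i log_base(p_i) over features with positive abundance.
#'
#' @param x Non-negative abundance vector with positive sum.
#' @param base Logarithm base (2 is the amplicon convention; use
#'   `exp(1)` for gene-level diversity).
#' @return Shannon index H.
#' @export
shannon <- function(x, base = 2) {
  if (any(x < 0) || sum(x) <= 0) abort("abundances must be non-negative with a positive sum")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p, base = base))
}

#' Pielou's evenness of one abundance column
#'
#' J = H / log_base(S) where S is the number of features present;
#' a single-feature community has J defined as 0.
#'
#' @inheritParams shannon
#' @return Evenness J in `[0, 1]`.
#' @export
pielou <- function(x, base = 2) {
  s <- sum(x > 0)
  if (s <= 1) return(0)
  shannon(x, base = base) / log(s, base = base)
}

#' Per-sample alpha-diversity summary
#'
#' @param tbl Abundance tibble.
#' @param base Logarithm base for Shannon/Pielou.
#' @return Tibble: `sample_id`, `richness`, `shannon`, `pielou`.
#' @export
alpha_diversity <- function(tbl, base = 2) {
  m <- abundance_matrix(tbl)
  tibble::tibble(
    sample_id = colnames(m),
    richness = apply(m, 2, function(x) sum(x > 0)),
    shannon = apply(m, 2, shannon, base = base),
    pielou = apply(m, 2, pielou, base = base)
  )
}

#' Hellinger distances between samples
#'
#' d(s, t) = sqrt(sum_i (sqrt(p_is) - sqrt(p_it))^2) with p the
#' per-sample relative abundances; bounded by sqrt(2).
#'
#' @param tbl Abundance tibble (counts or proportions; no all-zero
#'   sample).
#' @return A [stats::dist] object over samples.
#' @export
hellinger_distances <- function(tbl) {
  p <- abundance_matrix(normalize_abundance(tbl))
  stats::dist(t(sqrt(p)), method = "euclidean")
}

# tip presence per edge: logical edge x sample matrix
edge_presence <- function(tree, presence) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  node_pres <- matrix(FALSE, nnode, ncol(presence))
  node_pres[seq_len(ntip), ] <- presence[tr$tip.label, , drop = FALSE]
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    node_pres[par, ] <- node_pres[par, ] | node_pres[child, ]
  }
  list(tree = tr, pres = node_pres[tr$edge[, 2], , drop = FALSE])
}

#' Unweighted UniFrac distances
#'
#' For two communities, the fraction of branch length (over branches
#' leading to any leaf present in either community) that leads
#' exclusively to leaves of one of them.
#'
#' @param tbl Abundance tibble; any positive value marks a feature
#'   present. Every present feature must be a leaf of `tree`.
#' @param tree Rooted [ape::phylo] tree with branch lengths on all edges.
#' @return A [stats::dist] object over samples.
#' @export
unweighted_unifrac <- function(tbl, tree) {
  m <- abundance_matrix(tbl)
  missing <- setdiff(rownames(m)[rowSums(m) > 0], tree$tip.label)
  if (length(missing)) {
    abort(paste0("feature(s) absent from the tree: ", paste(head(missing, 5), collapse = ", ")))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge)) {
    abort("UniFrac requires branch lengths on every edge")
  }
  presence <- matrix(FALSE, length(tree$tip.label), ncol(m),
                     dimnames = list(tree$tip.label, colnames(m)))
  common <- intersect(rownames(m), tree$tip.label)
  presence[common, ] <- m[common, , drop = FALSE] > 0
  ep <- edge_presence(tree, presence)
  len <- ep$tree$edge.length
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- ep$pres[, i]; b <- ep$pres[, j]
      denom <- sum(len[a | b])
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else sum(len[xor(a, b)]) / denom
    }
  }
  stats::as.dist(d)
}

#' Principal-coordinates analysis (classical metric scaling)
#'
#' Double-centres the squared distance matrix and eigendecomposes it.
#' Negative eigenvalues (non-Euclidean input) are reported, never
#' silently clipped; explained proportions are relative to the sum of
#' positive eigenvalues.
#'
#' @param d A [stats::dist] object or symmetric distance matrix.
#' @param k Number of coordinate axes (at most n - 1).
#' @return Object of class `tp_pcoa`: `points` tibble (`sample_id` +
#'   `Axis1..k`), `eig` (all eigenvalues), `explained`.
#' @export
pcoa_ordination <- function(d, k = 2) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (k < 1 || k > n - 1) abort("k must be between 1 and n - 1")
  sc <- cmdscale(dm, k = k, eig = TRUE)
  pts <- sc$points
  if (ncol(pts) < k) {  # degenerate axes with non-positive eigenvalues
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  colnames(pts) <- paste0("Axis", seq_len(k))
  pos <- sum(pmax(sc$eig, 0))
  structure(list(
    points = dplyr::bind_cols(tibble::tibble(sample_id = rownames(dm)),
                              tibble::as_tibble(pts)),
    eig = sc$eig,
    explained = if (pos > 0) pmax(sc$eig, 0) / pos else rep(0, length(sc$eig))
  ), class = "tp_pcoa")
}

#' Exact rank-sum (Mann-Whitney) test
#'
#' Mid-ranks are used for ties. For combined sample sizes up to
#' `max_exact` the null is the full set of choose(n, n_a) group-label
#' assignments over the observed (tied) rank multiset; beyond that a
#' seeded random sample of assignments is used. The one-tailed p-value
#' is the smaller tail of group A's U statistic under that null, and
#' the two-sided p-value doubles it (capped at 1) — the convention that
#' reproduces standard exact Mann-Whitney results under ties.
#'
#' @param a,b Numeric vectors of observations per group (each non-empty).
#' @param max_exact Largest combined size for exhaustive enumeration.
#' @param n_perm Random assignments drawn when beyond `max_exact`.
#' @param seed Seed for the sampled null.
#' @return Object of class `tp_ranksum`: `U`, `p.value`, `method`,
#'   `n_a`, `n_b`.
#' @export
exact_rank_sum_test <- function(a, b, max_exact = 12, n_perm = 10000, seed = 1L) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  r <- rank(c(a, b))
  na <- length(a); nb <- length(b); n <- na + nb
  u_of <- function(ranks_a) sum(ranks_a) - na * (na + 1) / 2
  ua <- u_of(r[seq_len(na)])
  u_obs <- min(ua, na * nb - ua)
  eps <- 1e-9
  if (n <= max_exact) {
    idx <- combn(n, na)
    ua_null <- apply(idx, 2, function(i) u_of(r[i]))
    method <- "exact enumeration"
  } else {
    withr::local_seed(seed)
    ua_null <- vapply(seq_len(n_perm), function(i) u_of(sample(r, na)), numeric(1))
    method <- sprintf("sampled null (%d assignments)", n_perm)
  }
  one_tail <- min(mean(ua_null <= ua + eps), mean(ua_null >= ua - eps))
  structure(list(U = u_obs, p.value = min(1, 2 * one_tail),
                 method = method, n_a = na, n_b = nb),
            class = "tp_ranksum")
}

#' @export
print.tp_ranksum <- function(x, ...) {
  cat(sprintf("Exact rank-sum test (%s)\nU = %g, n = %d vs %d, two-sided p = %g\n",
              x$method, x$U, x$n_a, x$n_b, x$p.value))
  invisible(x)
}

#' Tukey multiple comparisons across groups
#'
#' One-way ANOVA pooled variance with studentized-range adjusted
#' pairwise p-values, as used for observed-species comparisons across
#' the three temperature classes.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (same length as `values`).
#' @return Tibble: `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_multiple_comparisons <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("need at least two groups")
  if (length(values) <= nlevels(groups)) abort("need residual degrees of freedom (n > number of groups)")
  fit <- aov(values ~ groups)
  if (sum(fit$residuals^2) < 1e-12) {
    means <- tapply(values, groups, mean)
    pairs <- combn(levels(groups), 2)
    diffs <- apply(pairs, 2, function(p) means[p[2]] - means[p[1]])
    warn("zero pooled variance; p reported as 0 for unequal means, 1 otherwise")
    return(tibble::tibble(
      comparison = apply(pairs, 2, function(p) paste(p[2], p[1], sep = "-")),
      diff = unname(diffs), lwr = NA_real_, upr = NA_real_,
      p_adj = ifelse(abs(diffs) < 1e-12, 1, 0)
    ))
  }
  th <- TukeyHSD(fit)$groups
  tibble::tibble(comparison = rownames(th), diff = unname(th[, "diff"]),
                 lwr = unname(th[, "lwr"]), upr = unname(th[, "upr"]),
                 p_adj = unname(th[, "p adj"]))
}
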