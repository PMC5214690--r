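quad_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("rarefied observed species hit exact values at exhaustive depths", {
  m <- matrix(c(5, 5, 0, 3, 2, 1), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  res <- rarefy_observed_species(as_abundance_tbl(m), depths = c(6, 10), n_iter = 3, seed = 5)
  # depth = column total draws everything
  expect_equal(res$observed_species[res$depth == 10 & res$sample_id == "s1"], 2)
  expect_equal(res$observed_species[res$depth == 6 & res$sample_id == "s2"], 3)
  # depth beyond the column total is missing
  expect_true(is.na(res$observed_species[res$depth == 10 & res$sample_id == "s2"]))
})

test_that("rarefaction matches the analytic expectation for a tiny community", {
  # {A:2, B:2} at depth 2: P(single species) = 1/3, so E[observed] = 5/3
  m <- matrix(c(2, 2), nrow = 2, dimnames = list(c("A", "B"), "s1"))
  n_iter <- 2000
  res <- rarefy_observed_species(as_abundance_tbl(m), depths = 2,
                                 n_iter = n_iter, seed = 99)
  se <- sqrt(2 / 9 / n_iter)
  expect_lt(abs(res$observed_species - 5 / 3), 3 * se)
})

test_that("rarefaction curves are non-decreasing in depth", {
  withr::local_seed(21)
  m <- matrix(rpois(40, 30), nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:4)))
  res <- rarefy_observed_species(as_abundance_tbl(m), depths = c(10, 40, 80),
                                 n_iter = 10, seed = 3)
  for (s in paste0("s", 1:4)) {
    v <- res$observed_species[res$sample_id == s]
    v <- v[!is.na(v)]
    expect_true(all(diff(v) >= 0))
  }
})

test_that("Shannon and Pielou match closed forms and vegan", {
  expect_equal(shannon(c(7, 0, 0)), 0)
  expect_equal(shannon(rep(3, 4), base = 2), 2)
  expect_equal(pielou(rep(3, 4), base = 2), 1)
  expect_equal(shannon(c(0.5, 0.25, 0.25), base = 2), 1.5)
  expect_equal(pielou(c(9, 0, 0)), 0)  # single-feature convention
  expect_error(shannon(c(0, 0)), "positive sum")
  withr::local_seed(8)
  x <- rpois(20, 10) + 1
  expect_equal(shannon(x, base = exp(1)), unname(vegan::diversity(x)))
})

test_that("Hellinger distances match the closed form and stay within bounds", {
  m <- matrix(c(1, 1, 2, 2, 5, 0, 0, 5), nrow = 2,
              dimnames = list(c("A", "B"), c("s1", "s2", "s3", "s4")))
  d <- as.matrix(hellinger_distances(as_abundance_tbl(m)))
  expect_equal(d["s1", "s2"], 0)                       # identical compositions
  expect_equal(d["s3", "s4"], sqrt(2))                 # disjoint single features
  expect_equal(d["s1", "s3"], sqrt((sqrt(0.5) - 1)^2 + 0.5), tolerance = 1e-12)
  withr::local_seed(13)
  m2 <- matrix(rpois(60, 8) + 1, nrow = 10,
               dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  got <- as.matrix(hellinger_distances(as_abundance_tbl(m2)))
  want <- as.matrix(stats::dist(vegan::decostand(t(m2), method = "hellinger")))
  expect_equal(got, want, tolerance = 1e-8)
  expect_true(all(got >= 0 & got <= sqrt(2) + 1e-12))
  expect_equal(unname(diag(got)), rep(0, 6))
})

test_that("unweighted UniFrac reproduces hand-computed four-leaf cases", {
  tree <- quad_tree()
  m <- matrix(c(1, 1, 0, 0,
                0, 0, 1, 1,
                1, 0, 1, 0,
                1, 0, 0, 1), ncol = 4,
              dimnames = list(c("A", "B", "C", "D"), c("ab", "cd", "ac", "ad")))
  d <- as.matrix(unweighted_unifrac(as_abundance_tbl(m), tree))
  expect_equal(d["ab", "cd"], 1)
  expect_equal(d["ac", "ad"], 0.4)
  expect_equal(d["ab", "ab"], 0)
})

test_that("UniFrac matches brute-force branch enumeration and picante on random instances", {
  withr::local_seed(31)
  for (rep in 1:8) {
    n_leaf <- sample(4:8, 1)
    tree <- ape::rcoal(n_leaf, tip.label = paste0("L", seq_len(n_leaf)))
    pres <- matrix(rbinom(n_leaf * 3, 1, 0.6), nrow = n_leaf,
                   dimnames = list(tree$tip.label, c("x", "y", "z")))
    pres[cbind(sample(n_leaf, 3, replace = TRUE), 1:3)] <- 1  # no empty sample
    d <- as.matrix(unweighted_unifrac(as_abundance_tbl(pres), tree))
    for (pair in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
      want <- oracle_unifrac_pair(tree, rownames(pres)[pres[, pair[1]] > 0],
                                  rownames(pres)[pres[, pair[2]] > 0])
      expect_equal(d[pair[1], pair[2]], want)
    }
    pic <- as.matrix(picante::unifrac(t(pres), tree))
    expect_equal(d[colnames(pres), colnames(pres)],
                 pic[colnames(pres), colnames(pres)], tolerance = 1e-12)
  }
})

test_that("UniFrac validates tree coverage and branch lengths", {
  tree <- quad_tree()
  m <- matrix(c(1, 1), nrow = 2, dimnames = list(c("A", "Zmissing"), "s1"))
  expect_error(unweighted_unifrac(as_abundance_tbl(m), tree), "Zmissing")
  tree$edge.length <- NULL
  m2 <- matrix(c(1, 1), nrow = 2, dimnames = list(c("A", "B"), "s1"))
  expect_error(unweighted_unifrac(as_abundance_tbl(m2), tree), "branch length")
})

test_that("PCoA embeds two samples symmetrically and reconstructs Euclidean input", {
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa_ordination(stats::as.dist(d2), k = 1)
  expect_equal(sort(ord$points$Axis1), c(-0.5, 0.5))

  withr::local_seed(17)
  pts <- matrix(rnorm(21), ncol = 3, dimnames = list(paste0("s", 1:7), NULL))
  d <- stats::dist(pts)
  ord <- pcoa_ordination(d, k = 6)
  emb <- as.matrix(ord$points[, -1])
  expect_equal(as.matrix(stats::dist(emb)), as.matrix(d),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pcoa_ordination(d, k = 7), "n - 1")
})

test_that("Hellinger distances are Euclidean-embeddable (eigenvalues >= -1e-9)", {
  withr::local_seed(19)
  for (rep in 1:5) {
    m <- matrix(rpois(48, 6) + 1, nrow = 8,
                dimnames = list(paste0("f", 1:8), paste0("s", 1:6)))
    ord <- pcoa_ordination(hellinger_distances(as_abundance_tbl(m)), k = 2)
    expect_true(all(ord$eig >= -1e-9))
  }
})

test_that("tidy and glance summarise ordinations and distance objects", {
  m <- matrix(c(5, 1, 1, 5, 3, 3), nrow = 2,
              dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  d <- hellinger_distances(as_abundance_tbl(m))
  td <- generics::tidy(d)
  expect_equal(nrow(td), 3)
  expect_named(td, c("sample_a", "sample_b", "distance"))
  ord <- pcoa_ordination(d, k = 2)
  expect_named(generics::tidy(ord), c("sample_id", "Axis1", "Axis2"))
  g <- generics::glance(ord)
  expect_equal(g$n_samples, 3)
})

test_that("exact rank-sum test reproduces the field-sample group comparisons", {
  expect_equal(round(exact_rank_sum_test(c(55, 43.5, 52.1), c(98, 61.5, 69, 67))$p.value, 3), 0.057)
  expect_equal(round(exact_rank_sum_test(c(7.8, 7.5, 7.8), c(7.5, 7.6, 7.0, 7.8))$p.value, 3), 0.571)
  expect_equal(round(exact_rank_sum_test(c(690, 590, 620), c(880, 600, 700, 700))$p.value, 3), 0.171)
})

test_that("exact rank-sum test agrees with enumeration and wilcox.test on tie-free data", {
  expect_equal(exact_rank_sum_test(c(3, 3), c(3, 3, 3))$p.value, 1)
  withr::local_seed(23)
  for (rep in 1:25) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1)
    a <- round(rnorm(na), 6); b <- round(rnorm(nb, 0.5), 6)
    got <- exact_rank_sum_test(a, b)$p.value
    expect_equal(got, oracle_ranksum_p(a, b))
    if (na >= 1 && nb >= 1) {
      w <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))$p.value
      expect_equal(got, w, tolerance = 1e-12)
    }
  }
  # tied data still matches the enumeration oracle
  for (rep in 1:10) {
    a <- sample(1:3, sample(2:4, 1), replace = TRUE)
    b <- sample(1:3, sample(2:4, 1), replace = TRUE)
    expect_equal(exact_rank_sum_test(a, b)$p.value, oracle_ranksum_p(a, b))
  }
  expect_error(exact_rank_sum_test(numeric(), 1), "non-empty")
})

test_that("the sampled null approximates the exact p beyond the enumeration limit", {
  withr::local_seed(29)
  a <- rnorm(4); b <- rnorm(4, 1)
  exact <- exact_rank_sum_test(a, b)$p.value
  approx <- exact_rank_sum_test(a, b, max_exact = 0, n_perm = 20000, seed = 12)$p.value
  expect_lt(abs(exact - approx), 0.02)
})

test_that("Tukey comparisons reduce to the pooled t-test for two groups", {
  withr::local_seed(37)
  x <- rnorm(6); y <- rnorm(6, 1)
  res <- tukey_multiple_comparisons(c(x, y), rep(c("a", "b"), each = 6))
  tt <- stats::t.test(y, x, var.equal = TRUE)
  expect_equal(res$p_adj, tt$p.value, tolerance = 1e-6)
})

test_that("Tukey ranks distant groups as more significant and handles degenerate input", {
  vals <- c(1, 2, 3, 1, 2, 3, 10, 11, 12)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  res <- tukey_multiple_comparisons(vals, grp)
  p_same <- res$p_adj[res$comparison == "g2-g1"]
  expect_true(all(res$p_adj[res$comparison != "g2-g1"] < p_same))
  expect_equal(p_same, 1)  # identical groups
  expect_warning(same <- tukey_multiple_comparisons(rep(1, 9), grp),
                 "zero pooled variance")
  expect_equal(same$p_adj, rep(1, 3))
})
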