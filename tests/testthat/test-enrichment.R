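two_group_meta <- function() {
  tibble::tibble(sample_id = paste0("s", 1:7),
                 group = c(rep("Anhoni", 3), rep("Tattapani", 4)))
}

test_that("KO odds ratios follow the group-mean odds formula", {
  m <- matrix(c(rep(0.2, 3), rep(0.1, 4),
                rep(0.3, 3), rep(0.3, 4),
                rep(0.5, 3), rep(0.6, 4)), nrow = 3, byrow = TRUE,
              dimnames = list(c("K1", "K2", "K3"), paste0("s", 1:7)))
  res <- ko_odds_ratios(as_abundance_tbl(m), two_group_meta())
  expect_equal(res$odds_ratio[res$ko_id == "K1"], (0.2 / 0.8) / (0.1 / 0.9))
  expect_equal(res$odds_ratio[res$ko_id == "K1"], 2.25)
  expect_equal(res$enriched_in[res$ko_id == "K1"], "Anhoni")
  expect_equal(res$odds_ratio[res$ko_id == "K2"], 1)
  expect_true(is.na(res$enriched_in[res$ko_id == "K2"]))
  expect_equal(res$enriched_in[res$ko_id == "K3"], "Tattapani")
})

test_that("a zero group mean yields a finite odds ratio via the pseudocount", {
  m <- matrix(c(rep(0.2, 3), rep(0, 4)), nrow = 1, byrow = TRUE,
              dimnames = list("K1", paste0("s", 1:7)))
  res <- ko_odds_ratios(as_abundance_tbl(m), two_group_meta())
  expect_true(is.finite(res$odds_ratio) && res$odds_ratio > 1)
})

test_that("odds ratios are invariant to sample order within groups", {
  withr::local_seed(41)
  m <- matrix(runif(21, 0, 0.3), nrow = 3,
              dimnames = list(c("K1", "K2", "K3"), paste0("s", 1:7)))
  meta <- two_group_meta()
  r1 <- ko_odds_ratios(as_abundance_tbl(m), meta)
  shuffled <- as_abundance_tbl(m[, c(3, 1, 2, 7, 5, 4, 6)])
  r2 <- ko_odds_ratios(shuffled, meta)
  expect_equal(r1, r2)
})

test_that("pathway Fisher tests match enumeration, with symmetric signed log odds", {
  ko_enr <- tibble::tibble(
    ko_id = paste0("K", 1:6),
    mean_a = 0.1, mean_b = 0.1,
    odds_ratio = c(2, 2, 2, 0.5, 0.5, 0.5),
    enriched_in = c(rep("A", 3), rep("B", 3)),
    p_value = 0.5
  )
  pm <- tibble::tibble(pathway_id = "pw1", ko = paste0("K", 1:3))
  res <- pathway_fisher(ko_enr, pm)
  expect_equal(res$fisher_p, 0.1)   # [[3,0],[0,3]] by full enumeration
  expect_gt(res$log_odds, 0)

  # swapping group labels flips the sign and preserves p
  flipped <- dplyr::mutate(ko_enr, enriched_in = ifelse(enriched_in == "A", "B", "A"))
  res2 <- pathway_fisher(flipped, pm)
  expect_equal(res2$fisher_p, res$fisher_p)
  expect_equal(res2$log_odds, -res$log_odds)

  # proportional table gives zero log odds
  ko_enr2 <- tibble::tibble(ko_id = paste0("K", 1:8), mean_a = 0.1, mean_b = 0.1,
                            odds_ratio = rep(c(2, 0.5), 4),
                            enriched_in = rep(c("A", "B"), 4), p_value = 0.5)
  pm2 <- tibble::tibble(pathway_id = "pw1", ko = paste0("K", 1:4))
  expect_equal(pathway_fisher(ko_enr2, pm2)$log_odds, 0)

  # pathway with no KO in the analysis is skipped with a message
  pm3 <- tibble::tibble(pathway_id = c("pw1", "pwX"), ko = c("K1", "K99"))
  expect_message(res3 <- pathway_fisher(ko_enr, pm3), "pwX")
  expect_equal(res3$pathway_id, "pw1")
})

test_that("Fisher p equals full fixed-margin enumeration for random tables", {
  withr::local_seed(43)
  for (rep in 1:25) {
    tab <- matrix(sample(0:5, 4, replace = TRUE), 2)
    if (sum(tab) == 0 || sum(tab) > 20) next
    expect_equal(stats::fisher.test(tab)$p.value, oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("reporter scores convert p-values to normal quantiles", {
  meta_kos <- function(p) {
    tibble::tibble(ko_id = sprintf("K%03d", seq_along(p)),
                   mean_a = 0.1, mean_b = 0.05, odds_ratio = 2,
                   enriched_in = "A", p_value = p)
  }
  # k = 1, p = 0.0228 -> Z_raw = qnorm(0.9772) ~ 2.0
  withr::local_seed(47)
  ko_enr <- meta_kos(c(0.0228, runif(49, 0.2, 0.9)))
  pm <- tibble::tibble(pathway_id = "pw1", ko = "K001")
  res <- reporter_scores(ko_enr, pm, n_background = 200, seed = 3)
  expect_equal(res$z_raw, qnorm(1 - 0.0228), tolerance = 1e-9)
  expect_equal(round(res$z_raw, 1), 2.0)
  expect_equal(res$k, 1L)
  expect_equal(res$direction, "A")

  # all member p = 0.5 -> z contributions of zero
  ko_half <- meta_kos(c(rep(0.5, 4), runif(20, 0.1, 0.9)))
  pm4 <- tibble::tibble(pathway_id = "pw1", ko = sprintf("K%03d", 1:4))
  res4 <- reporter_scores(ko_half, pm4, n_background = 200, seed = 3)
  expect_equal(res4$z_raw, 0, tolerance = 1e-12)

  # degenerate background (every KO identical) errors
  ko_all_half <- meta_kos(rep(0.5, 30))
  expect_error(reporter_scores(ko_all_half, pm4, n_background = 200, seed = 3),
               "degenerate background")
})

test_that("reporter correction standardises against same-size random KO sets", {
  withr::local_seed(53)
  p <- runif(60, 0.01, 1)
  ko_enr <- tibble::tibble(ko_id = sprintf("K%03d", 1:60), mean_a = 0.1,
                           mean_b = 0.1, odds_ratio = 1.5, enriched_in = "A",
                           p_value = p)
  pm <- tibble::tibble(pathway_id = rep(c("pw1", "pw2"), each = 5),
                       ko = sprintf("K%03d", 1:10))
  res <- reporter_scores(ko_enr, pm, n_background = 500, seed = 9)
  expect_equal(res$z_corrected, (res$z_raw - res$mu_k) / res$sigma_k)
  # same k -> same background moments
  expect_equal(res$mu_k[1], res$mu_k[2])
  expect_equal(res$sigma_k[1], res$sigma_k[2])
})
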