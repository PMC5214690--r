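# Two-group functional comparison: per-KO odds ratios with exact
# rank-sum p-values, pathway-level Fisher's exact tests with signed log
# odds, and reporter Z-scores with a sampled same-size background
# correction.

#' Per-KO odds ratios between two sample groups
#'
#' For each KO, the group-mean relative abundances are treated as odds:
#' OR = [pA / (1 - pA)] / [pB / (1 - pB)], with a pseudocount added to a
#' group mean that is exactly zero so the ratio stays finite. The per-KO
#' p-value comes from the exact rank-sum test across the samples of the
#' two groups.
#'
#' @param ko_tbl KO abundance tibble of per-sample relative abundances.
#' @param metadata Metadata tibble with `sample_id` and `group` covering
#'   every sample column.
#' @param group_a,group_b The two group labels to compare; default the
#'   first two labels in `metadata` order. `enriched_in` and odds-ratio
#'   direction are reported relative to `group_a`.
#' @param pseudocount Added to an exactly-zero group mean (default 1e-6).
#' @param or_threshold Margin on the odds ratio for an enrichment call:
#'   `enriched_in` is `group_a` iff OR > `or_threshold`, `group_b` iff
#'   OR < 1 / `or_threshold` (default 1: any departure from parity).
#' @return Tibble: `ko_id`, `mean_a`, `mean_b`, `odds_ratio`,
#'   `enriched_in` (`NA` when neither), `p_value`.
#' @export
ko_odds_ratios <- function(ko_tbl, metadata, group_a = NULL, group_b = NULL,
                           pseudocount = 1e-6, or_threshold = 1) {
  m <- abundance_matrix(ko_tbl)
  groups <- unique(metadata$group)
  group_a <- group_a %||% groups[1]
  group_b <- group_b %||% setdiff(groups, group_a)[1]
  sa <- metadata$sample_id[metadata$group == group_a]
  sb <- metadata$sample_id[metadata$group == group_b]
  sa <- intersect(sa, colnames(m)); sb <- intersect(sb, colnames(m))
  if (length(sa) == 0 || length(sb) == 0) {
    abort("each group needs at least one sample present in the KO table")
  }
  purrr::map_dfr(rownames(m), function(ko) {
    va <- m[ko, sa]; vb <- m[ko, sb]
    pa <- mean(va); pb <- mean(vb)
    pa_adj <- if (pa == 0) pseudocount else pa
    pb_adj <- if (pb == 0) pseudocount else pb
    or <- (pa_adj / (1 - pa_adj)) / (pb_adj / (1 - pb_adj))
    tibble::tibble(
      ko_id = ko, mean_a = pa, mean_b = pb, odds_ratio = or,
      enriched_in = dplyr::case_when(or > or_threshold ~ group_a,
                                     or < 1 / or_threshold ~ group_b,
                                     TRUE ~ NA_character_),
      p_value = exact_rank_sum_test(va, vb)$p.value
    )
  })
}

# Two-sided Fisher p for a 2x2 table via the exact hypergeometric test.
fisher_p2 <- function(tab) fisher.test(tab)$p.value

#' Pathway-level Fisher's exact tests on enriched-KO membership
#'
#' Per pathway, builds the 2x2 table of KOs (in / out of the pathway) x
#' (enriched in group A / group B), computes the two-sided exact
#' hypergeometric p, a Benjamini-Hochberg FDR across pathways, and a log
#' odds ratio (Haldane 0.5 correction when any cell is zero) whose
#' positive sign marks association with group A.
#'
#' @param ko_enrichments Output of [ko_odds_ratios()]; KOs with no
#'   enrichment call are excluded.
#' @param pathway_map Tibble `pathway_id`, `ko` (see
#'   [read_pathway_map()]). Pathways with no KO present in the analysis
#'   are skipped with a message.
#' @param group_a Group whose association gives a positive `log_odds`;
#'   defaults to the alphabetically first enrichment label.
#' @return Tibble: `pathway_id`, cell counts `in_a`, `in_b`, `out_a`,
#'   `out_b`, `log_odds`, `fisher_p`, `fdr_p`.
#' @export
pathway_fisher <- function(ko_enrichments, pathway_map, group_a = NULL) {
  called <- ko_enrichments[!is.na(ko_enrichments$enriched_in), , drop = FALSE]
  if (nrow(called) == 0) abort("no KOs carry an enrichment call")
  ga <- group_a %||% sort(unique(called$enriched_in))[1]
  is_a <- called$enriched_in == ga
  out <- purrr::map_dfr(unique(pathway_map$pathway_id), function(pw) {
    kos <- pathway_map$ko[pathway_map$pathway_id == pw]
    in_pw <- called$ko_id %in% kos
    if (!any(in_pw)) {
      inform(paste0("pathway ", pw, " has no KO in the analysis; skipped"))
      return(NULL)
    }
    tab <- matrix(c(sum(in_pw & is_a), sum(in_pw & !is_a),
                    sum(!in_pw & is_a), sum(!in_pw & !is_a)),
                  2, 2, byrow = TRUE)
    ct <- if (any(tab == 0)) tab + 0.5 else tab
    tibble::tibble(pathway_id = pw,
                   in_a = tab[1, 1], in_b = tab[1, 2],
                   out_a = tab[2, 1], out_b = tab[2, 2],
                   log_odds = log((ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])),
                   fisher_p = fisher_p2(tab))
  })
  out$fdr_p <- bh_fdr(out$fisher_p)
  out
}

#' Reporter Z-scores for pathways
#'
#' Converts per-KO p-values to normal quantiles z = qnorm(1 - p),
#' scores each pathway as Z_raw = sum(z over member KOs) / sqrt(k), and
#' corrects against the null of `n_background` seeded random draws of k
#' KOs from the analysis universe: Z_corrected = (Z_raw - mu_k) /
#' sigma_k. The reported direction is the sign of the
#' abundance-weighted mean direction of the member KOs.
#'
#' @param ko_enrichments Output of [ko_odds_ratios()] (uses `ko_id`,
#'   `p_value`, `enriched_in`, `mean_a`, `mean_b`).
#' @param pathway_map Tibble `pathway_id`, `ko`.
#' @param n_background Background draws per pathway size (>= 100).
#' @param seed Seed for the background sampling.
#' @param group_a Label reported for a positive weighted direction;
#'   defaults to the alphabetically first enrichment label.
#' @return Tibble: `pathway_id`, `k`, `z_raw`, `mu_k`, `sigma_k`,
#'   `z_corrected`, `direction` (group label or `NA`).
#' @export
reporter_scores <- function(ko_enrichments, pathway_map,
                            n_background = 1000, seed = 1L, group_a = NULL) {
  if (n_background < 100) abort("n_background must be at least 100")
  p <- ko_enrichments$p_value
  if (any(p <= 0)) {
    warn("p-values of 0 clamped to machine minimum")
    p[p <= 0] <- .Machine$double.xmin
  }
  # p = 1 (common under a discrete exact null) would map to z = -Inf;
  # cap so every KO contributes a finite score
  p <- pmin(p, 1 - 1e-10)
  z <- qnorm(1 - p)
  names(z) <- ko_enrichments$ko_id
  groups <- sort(unique(ko_enrichments$enriched_in[!is.na(ko_enrichments$enriched_in)]))
  ga <- group_a %||% groups[1]
  dir_num <- dplyr::case_when(ko_enrichments$enriched_in == ga ~ 1,
                              !is.na(ko_enrichments$enriched_in) ~ -1,
                              TRUE ~ 0)
  weight <- (ko_enrichments$mean_a + ko_enrichments$mean_b) / 2
  names(dir_num) <- names(weight) <- ko_enrichments$ko_id
  pw_ids <- unique(pathway_map$pathway_id)
  ks <- vapply(pw_ids, function(pw) {
    sum(pathway_map$ko[pathway_map$pathway_id == pw] %in% names(z))
  }, integer(1))
  bg <- new.env()
  bg_moments <- function(k) {
    key <- as.character(k)
    if (!is.null(bg[[key]])) return(bg[[key]])
    withr::local_seed(substream_seed(seed, paste("reporter-bg", k)))
    draws <- vapply(seq_len(n_background), function(i) {
      sum(z[sample(length(z), k)]) / sqrt(k)
    }, numeric(1))
    mom <- c(mu = mean(draws), sigma = sd(draws))
    bg[[key]] <- mom
    mom
  }
  purrr::map_dfr(pw_ids[ks > 0], function(pw) {
    kos <- intersect(pathway_map$ko[pathway_map$pathway_id == pw], names(z))
    k <- length(kos)
    z_raw <- sum(z[kos]) / sqrt(k)
    mom <- bg_moments(k)
    if (!is.finite(mom["sigma"]) || mom["sigma"] <= 0) {
      abort("degenerate background: sigma_k is zero (are all KO p-values identical?)")
    }
    wmean <- sum(dir_num[kos] * weight[kos])
    tibble::tibble(pathway_id = pw, k = k, z_raw = z_raw,
                   mu_k = unname(mom["mu"]), sigma_k = unname(mom["sigma"]),
                   z_corrected = unname((z_raw - mom["mu"]) / mom["sigma"]),
                   direction = dplyr::case_when(wmean > 0 ~ ga,
                                                wmean < 0 ~ setdiff(groups, ga)[1],
                                                TRUE ~ NA_character_))
  })
}
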