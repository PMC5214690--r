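# Taxon-resolved pathway coverage: which taxa carry which pathway
# enzymes, per-taxon completeness, community-union completeness, and
# complementation (who supplies the enzymes the dominant carrier
# lacks).

#' Per-taxon pathway enzyme coverage
#'
#' For every (taxon, pathway) pair with at least one pathway KO
#' annotated to the taxon, reports the KOs present and missing and the
#' coverage fraction |present| / |pathway KO set|.
#'
#' @param annotations Tibble with columns `gene_id`, `ko`, `taxon`
#'   (one row per annotated gene).
#' @param pathway_map Tibble `pathway_id`, `ko`.
#' @return Tibble: `taxon`, `pathway_id`, `n_present`, `n_total`,
#'   `coverage`, plus list-columns `present_kos`, `missing_kos`.
#' @export
taxon_pathway_coverage <- function(annotations, pathway_map) {
  pw_sets <- split(pathway_map$ko, pathway_map$pathway_id)
  taxa_kos <- annotations |>
    dplyr::distinct(.data$taxon, .data$ko)
  purrr::map_dfr(names(pw_sets), function(pw) {
    kos <- unique(pw_sets[[pw]])
    hit <- taxa_kos[taxa_kos$ko %in% kos, , drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    hit |>
      dplyr::group_by(.data$taxon) |>
      dplyr::summarise(present_kos = list(sort(unique(.data$ko))), .groups = "drop") |>
      dplyr::mutate(pathway_id = pw,
                    missing_kos = purrr::map(.data$present_kos, ~ sort(setdiff(kos, .x))),
                    n_present = lengths(.data$present_kos),
                    n_total = length(kos),
                    coverage = .data$n_present / .data$n_total) |>
      dplyr::select("taxon", "pathway_id", "n_present", "n_total",
                    "coverage", "present_kos", "missing_kos")
  })
}

#' Community-level pathway completion and complementation
#'
#' Per pathway and sample, takes the union of pathway KOs over taxa
#' whose relative abundance in that sample is at least `min_abundance`,
#' flags whether the union covers the full enzyme set, and reports
#' complementation: for each KO missing from the best-covered qualifying
#' taxon, the other qualifying taxa that supply it.
#'
#' @param coverages Output of [taxon_pathway_coverage()].
#' @param abundances Taxon abundance tibble (sample-normalised
#'   proportions; `feature_id` = taxon).
#' @param min_abundance Minimum per-sample abundance for a taxon to
#'   count toward the union (default 0: any detected taxon).
#' @return Tibble: `pathway_id`, `sample_id`, `n_community`, `n_total`,
#'   `community_coverage`, `complete`, `top_taxon`, and list-column
#'   `complementation` (tibble `ko`, `supplied_by`).
#' @export
community_completion <- function(coverages, abundances, min_abundance = 0) {
  m <- abundance_matrix(abundances)
  purrr::map_dfr(unique(coverages$pathway_id), function(pw) {
    cov_pw <- coverages[coverages$pathway_id == pw, , drop = FALSE]
    purrr::map_dfr(colnames(m), function(s) {
      ab <- m[, s]
      qual_taxa <- intersect(cov_pw$taxon,
                             rownames(m)[ab > 0 & ab >= min_abundance])
      rows <- cov_pw[cov_pw$taxon %in% qual_taxa, , drop = FALSE]
      n_total <- cov_pw$n_total[1]
      if (nrow(rows) == 0) {
        return(tibble::tibble(pathway_id = pw, sample_id = s, n_community = 0L,
                              n_total = n_total, community_coverage = 0,
                              complete = FALSE, top_taxon = NA_character_,
                              complementation = list(tibble::tibble(
                                ko = character(), supplied_by = list()))))
      }
      union_kos <- sort(unique(unlist(rows$present_kos)))
      # best-covered qualifying taxon; ties broken by sample abundance
      ord <- order(-rows$coverage, -m[rows$taxon, s])
      top <- rows[ord[1], ]
      comp <- purrr::map_dfr(top$missing_kos[[1]], function(ko) {
        suppliers <- rows$taxon[purrr::map_lgl(rows$present_kos, ~ ko %in% .x)]
        suppliers <- setdiff(suppliers, top$taxon)
        if (length(suppliers) == 0) return(NULL)
        tibble::tibble(ko = ko, supplied_by = list(sort(suppliers)))
      })
      if (nrow(comp) == 0) comp <- tibble::tibble(ko = character(), supplied_by = list())
      tibble::tibble(pathway_id = pw, sample_id = s,
                     n_community = length(union_kos), n_total = n_total,
                     community_coverage = length(union_kos) / n_total,
                     complete = length(union_kos) == n_total,
                     top_taxon = top$taxon,
                     complementation = list(comp))
    })
  })
}

#' Long-format pathway contribution table
#'
#' One row per (pathway KO, carrying taxon, sample) with the taxon's
#' abundance in that sample — the data behind taxon-by-enzyme bubble
#' charts. Taxa absent from a sample contribute no rows there.
#'
#' @param coverages Output of [taxon_pathway_coverage()].
#' @param abundances Taxon abundance tibble.
#' @return Tibble: `pathway_id`, `ko`, `taxon`, `sample_id`,
#'   `abundance`.
#' @export
pathway_contribution_table <- function(coverages, abundances) {
  m <- abundance_matrix(abundances)
  long <- coverages |>
    dplyr::select("pathway_id", "taxon", "present_kos") |>
    tidyr::unnest_longer("present_kos", values_to = "ko") |>
    tidyr::expand_grid(sample_id = colnames(m))
  long$abundance <- m[cbind(match(long$taxon, rownames(m)),
                            match(long$sample_id, colnames(m)))]
  long$abundance[is.na(long$abundance)] <- 0
  long <- long[long$abundance > 0, , drop = FALSE]
  long[c("pathway_id", "ko", "taxon", "sample_id", "abundance")]
}
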