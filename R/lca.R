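# Taxonomic assignment of query features (metagenomic ORFs, OTU
# representatives) from alignment hit tables: e-value / coverage
# filtering, best-hit selection, lowest-common-ancestor resolution, and
# identity-threshold lifting of the assignment rank.

#' Parameters for LCA taxonomic assignment
#'
#' Defaults follow the ORF-assignment rules used for shotgun data:
#' hits kept at e-value <= 1e-5 with alignment coverage >= 80% of the
#' reference gene length; species-level assignment requires >= 95%
#' identity, genus >= 85%, and any shallower rank (family through
#' phylum) >= 65%. Below 65% identity a query stays unassigned. In OTU
#' (amplicon-representative) mode the coverage filter is disabled.
#'
#' @param evalue_max Maximum e-value (inclusive).
#' @param coverage_min Minimum alignment coverage as a fraction of the
#'   reference (subject) length; `NULL` disables the coverage filter.
#' @param identity_species,identity_genus,identity_phylum Percent-identity
#'   floors gating the deepest permitted rank.
#' @param bitscore_tie_tol Hits within this bit-score margin of the best
#'   hit count as tied best hits (0 = exact ties only).
#' @return A list of class `lca_params`.
#' @export
lca_params <- function(evalue_max = 1e-5, coverage_min = 0.80,
                       identity_species = 95, identity_genus = 85,
                       identity_phylum = 65, bitscore_tie_tol = 0) {
  if (!(identity_species > identity_genus && identity_genus > identity_phylum)) {
    abort("identity thresholds must satisfy species > genus > phylum")
  }
  structure(list(evalue_max = evalue_max, coverage_min = coverage_min,
                 identity_species = identity_species,
                 identity_genus = identity_genus,
                 identity_phylum = identity_phylum,
                 bitscore_tie_tol = bitscore_tie_tol),
            class = "lca_params")
}

#' Filter alignment hits on e-value and reference coverage
#'
#' Keeps hits with `evalue <= evalue_max` and, when a coverage floor is
#' set, `aln_length / subject_length >= coverage_min`. Applying a
#' coverage filter to hits lacking `subject_length` is an error rather
#' than a silent pass.
#'
#' @param hits Hit tibble from [read_hit_table()].
#' @param params An [lca_params()] object.
#' @return The filtered hit tibble.
#' @export
filter_hits <- function(hits, params = lca_params()) {
  keep <- hits$evalue <= params$evalue_max
  if (!is.null(params$coverage_min)) {
    if (!"subject_length" %in% names(hits) || anyNA(hits$subject_length)) {
      abort("coverage filtering requires `subject_length` on every hit (use the extended_with_slen dialect)")
    }
    keep <- keep & (hits$aln_length / hits$subject_length >= params$coverage_min)
  }
  hits[keep, , drop = FALSE]
}

# Deepest rank index permitted by a percent identity under the
# rank-specific thresholds; 0 = unassigned. Identities in [65, 85)
# permit phylum only; intermediate ranks (class..family) can still
# arise when the LCA of tied best hits at >= 85% resolves there.
permitted_depth <- function(identity, params) {
  dplyr::case_when(
    identity >= params$identity_species ~ 7L,
    identity >= params$identity_genus   ~ 6L,
    identity >= params$identity_phylum  ~ 2L,
    TRUE ~ 0L
  )
}

lineage_depth <- function(lin_row) {
  filled <- !is.na(unlist(lin_row[TAX_RANKS], use.names = FALSE))
  if (!any(filled)) 0L else max(which(filled))
}

#' Assign taxonomy to queries by best-hit LCA with threshold lifting
#'
#' For each query, the best-hit set is every (pre-filtered) hit whose bit
#' score lies within `bitscore_tie_tol` of the maximum. The candidate
#' lineage is the deepest rank prefix shared by all best hits; the final
#' assignment rank is the shallower of that LCA rank and the rank
#' permitted by the maximum identity among best hits (species at >= 95%,
#' genus at >= 85%, phylum at >= 65%). Queries whose best identity falls
#' below the phylum threshold are reported unassigned. Intermediate
#' ranks (class, order, family) arise when tied best hits at >= 85%
#' identity agree only down to one of those ranks.
#'
#' @param hits Pre-filtered hit tibble (see [filter_hits()]); may cover
#'   many queries.
#' @param lineages Lineage tibble from [read_lineages()].
#' @param params An [lca_params()] object.
#' @param query_ids Optional character vector of queries to report
#'   (queries without hits are returned unassigned). Defaults to the
#'   queries present in `hits`.
#' @return Tibble: `query_id`, the seven rank columns, `assignment_rank`
#'   (`"unassigned"` when none), `n_hits_used`, `max_identity`.
#' @export
assign_lca <- function(hits, lineages, params = lca_params(),
                       query_ids = NULL) {
  query_ids <- query_ids %||% unique(hits$query_id)
  missing <- setdiff(unique(hits$subject_id), lineages$subject_id)
  if (length(missing)) {
    abort(paste0("subject id(s) missing from lineage table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  lin_m <- as.matrix(lineages[TAX_RANKS])
  rownames(lin_m) <- lineages$subject_id
  rows <- lapply(query_ids, function(q) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    empty <- tibble::tibble(query_id = q,
                            !!!setNames(rep(list(NA_character_), 7L), TAX_RANKS),
                            assignment_rank = "unassigned",
                            n_hits_used = 0L, max_identity = NA_real_)
    if (nrow(h) == 0) return(empty)
    best <- h[h$bitscore >= max(h$bitscore) - params$bitscore_tie_tol, , drop = FALSE]
    max_id <- max(best$pct_identity)
    depth_cap <- permitted_depth(max_id, params)
    if (depth_cap == 0L) {
      empty$n_hits_used <- nrow(best); empty$max_identity <- max_id
      return(empty)
    }
    lins <- lin_m[best$subject_id, , drop = FALSE]
    # deepest contiguous prefix shared by all best-hit lineages
    shared <- 0L
    for (d in seq_along(TAX_RANKS)) {
      vals <- lins[, d]
      if (anyNA(vals) || length(unique(vals)) != 1L) break
      shared <- d
    }
    depth <- min(shared, depth_cap)
    ranks <- rep(NA_character_, 7L)
    if (depth > 0L) ranks[seq_len(depth)] <- lins[1L, seq_len(depth)]
    tibble::tibble(query_id = q,
                   !!!setNames(as.list(ranks), TAX_RANKS),
                   assignment_rank = if (depth == 0L) "unassigned" else TAX_RANKS[depth],
                   n_hits_used = nrow(best), max_identity = max_id)
  })
  dplyr::bind_rows(rows)
}

#' Remove low-abundance OTUs
#'
#' Drops OTUs whose total count across samples is at or below
#' `max_total` (default 100 sequences), the noise filter applied to
#' amplicon OTU tables.
#'
#' @param tbl OTU abundance tibble of counts.
#' @param max_total Inclusive removal threshold on the cross-sample total.
#' @return Filtered abundance tibble.
#' @export
filter_low_abundance_otus <- function(tbl, max_total = 100) {
  m <- abundance_matrix(tbl)
  keep <- rowSums(m) > max_total
  if (!any(keep)) warn("all OTUs fell at or below the abundance threshold; returning an empty table")
  tbl[keep, , drop = FALSE]
}
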