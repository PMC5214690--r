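# Single-config orchestration of the full downstream pipeline over a
# file bundle, with uniform seeding and a run manifest. Stages exchange
# data only through their declared file artifacts, so any subset can be
# re-run piecemeal.

PIPELINE_STAGES <- c("taxonomy", "quantify", "diversity", "enrichment",
                     "correlate", "community")

default_pipeline_params <- function() {
  list(otu_max_total = 100, gene_min_total = 10,
       rho_min = 0.7, fdr_alpha = 0.05, or_threshold = 1,
       shannon_base = 2, reporter_background = 1000, min_abundance = 0)
}

#' Read and validate a pipeline configuration
#'
#' YAML with three blocks: `inputs` (paths to metadata, lineages,
#' pathway_map, otu_table, gene_counts, gene_annotations, hits, tree),
#' `params` (thresholds; missing entries take package defaults), and
#' top-level `seed` and `stages`. Unknown keys anywhere are rejected.
#'
#' @param path Path to a YAML config.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg Config list (as from YAML).
#' @export
validate_pipeline_config <- function(cfg) {
  known_top <- c("inputs", "params", "seed", "stages")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown)) abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  known_inputs <- c("metadata", "lineages", "pathway_map", "otu_table",
                    "gene_counts", "gene_annotations", "hits", "tree")
  unknown <- setdiff(names(cfg$inputs), known_inputs)
  if (length(unknown)) abort(paste0("unknown input key(s): ", paste(unknown, collapse = ", ")))
  defaults <- default_pipeline_params()
  unknown <- setdiff(names(cfg$params), names(defaults))
  if (length(unknown)) abort(paste0("unknown param key(s): ", paste(unknown, collapse = ", ")))
  cfg$params <- utils::modifyList(defaults, cfg$params %||% list())
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$stages <- cfg$stages %||% PIPELINE_STAGES
  bad <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  # stage-specific input requirements, checked before any compute
  need <- list(taxonomy = c("hits", "lineages"),
               quantify = c("gene_counts", "gene_annotations"),
               diversity = c("otu_table", "gene_counts", "gene_annotations", "tree", "metadata"),
               enrichment = c("gene_counts", "gene_annotations", "pathway_map", "metadata"),
               correlate = c("otu_table", "metadata"),
               community = c("gene_annotations", "pathway_map", "otu_table"))
  for (st in cfg$stages) {
    missing <- setdiff(need[[st]], names(cfg$inputs))
    if (length(missing)) {
      abort(paste0("stage '", st, "' requires input(s): ", paste(missing, collapse = ", ")))
    }
  }
  for (f in unlist(cfg$inputs)) {
    if (!file.exists(f)) abort(paste0("input file does not exist: ", f))
  }
  cfg
}

pipeline_ko_table <- function(cfg) {
  genes <- read_abundance_tsv(cfg$inputs$gene_counts) |>
    filter_low_count_genes(min_total = cfg$params$gene_min_total)
  ann <- readr::read_tsv(cfg$inputs$gene_annotations, col_types = "ccc",
                         progress = FALSE)
  aggregate_to_ko(genes, tibble::tibble(gene_id = ann$gene_id, annotation = ann$ko))
}

#' Run the downstream pipeline over a file bundle
#'
#' Executes the requested stages against the configured inputs and
#' writes each stage's tables plus a run manifest (parameters, seed,
#' input checksums) into `out_dir`. Deterministic given config + seed.
#'
#' @param cfg Config list from [read_pipeline_config()] (or a path to
#'   the YAML).
#' @param out_dir Output directory (created if needed).
#' @return Named list of the stage results, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  cfg <- validate_pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  metadata <- if (!is.null(cfg$inputs$metadata)) read_sample_metadata(cfg$inputs$metadata)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e),
                   " — check the inputs this stage consumes"))
    })
  }

  if ("taxonomy" %in% cfg$stages) {
    out$taxonomy <- run_stage("taxonomy", {
      hits <- read_hit_table(cfg$inputs$hits, dialect = "extended_with_slen")
      lineages <- read_lineages(cfg$inputs$lineages)
      res <- assign_lca(filter_hits(hits, lca_params()), lineages, lca_params())
      readr::write_tsv(res, file.path(out_dir, "taxonomy_assignments.tsv"))
      res
    })
  }
  if ("quantify" %in% cfg$stages) {
    out$ko_table <- run_stage("quantify", {
      ko <- pipeline_ko_table(cfg)
      write_abundance_tsv(ko, file.path(out_dir, "ko_relative_abundance.tsv"))
      ko
    })
  }
  if ("diversity" %in% cfg$stages) {
    out$diversity <- run_stage("diversity", {
      otu <- read_abundance_tsv(cfg$inputs$otu_table) |>
        filter_low_abundance_otus(max_total = cfg$params$otu_max_total)
      alpha <- alpha_diversity(otu, base = cfg$params$shannon_base)
      readr::write_tsv(alpha, file.path(out_dir, "alpha_diversity.tsv"))
      ko <- out$ko_table %||% pipeline_ko_table(cfg)
      hel <- hellinger_distances(ko)
      readr::write_tsv(tibble::as_tibble(as.matrix(hel), rownames = "sample_id"),
                       file.path(out_dir, "hellinger_distances.tsv"))
      tree <- read_newick(cfg$inputs$tree, require_branch_lengths = TRUE)
      uf <- unweighted_unifrac(otu, tree)
      readr::write_tsv(tibble::as_tibble(as.matrix(uf), rownames = "sample_id"),
                       file.path(out_dir, "unifrac_distances.tsv"))
      groups <- unique(metadata$group)
      tests <- purrr::map_dfr(c("temperature", "ph", "tds"), function(v) {
        t <- exact_rank_sum_test(metadata[[v]][metadata$group == groups[1]],
                                 metadata[[v]][metadata$group == groups[2]])
        tibble::tibble(variable = v, U = t$U, p_value = t$p.value)
      })
      readr::write_tsv(tests, file.path(out_dir, "group_comparisons.tsv"))
      list(alpha = alpha, hellinger = hel, unifrac = uf, group_tests = tests)
    })
  }
  if ("enrichment" %in% cfg$stages) {
    out$enrichment <- run_stage("enrichment", {
      ko <- out$ko_table %||% pipeline_ko_table(cfg)
      pm <- read_pathway_map(cfg$inputs$pathway_map)
      kos <- ko_odds_ratios(ko, metadata, or_threshold = cfg$params$or_threshold)
      pf <- pathway_fisher(kos, pm)
      rs <- reporter_scores(kos, pm, n_background = cfg$params$reporter_background,
                            seed = cfg$seed)
      readr::write_tsv(kos, file.path(out_dir, "ko_enrichment.tsv"))
      readr::write_tsv(pf, file.path(out_dir, "pathway_fisher.tsv"))
      readr::write_tsv(rs, file.path(out_dir, "reporter_scores.tsv"))
      list(ko = kos, fisher = pf, reporter = rs)
    })
  }
  if ("correlate" %in% cfg$stages) {
    out$correlate <- run_stage("correlate", {
      sp <- normalize_abundance(read_abundance_tsv(cfg$inputs$otu_table))
      res <- spearman_screen(sp, metadata, covariate = "temperature",
                             rho_min = cfg$params$rho_min,
                             fdr_alpha = cfg$params$fdr_alpha, seed = cfg$seed)
      readr::write_tsv(res, file.path(out_dir, "temperature_correlations.tsv"))
      res
    })
  }
  if ("community" %in% cfg$stages) {
    out$community <- run_stage("community", {
      ann <- readr::read_tsv(cfg$inputs$gene_annotations, col_types = "ccc",
                             progress = FALSE)
      pm <- read_pathway_map(cfg$inputs$pathway_map)
      cov <- taxon_pathway_coverage(ann, pm)
      sp <- normalize_abundance(read_abundance_tsv(cfg$inputs$otu_table))
      cc <- community_completion(cov, sp, min_abundance = cfg$params$min_abundance)
      flat <- dplyr::select(cc, -"complementation")
      readr::write_tsv(dplyr::select(cov, -"present_kos", -"missing_kos"),
                       file.path(out_dir, "taxon_pathway_coverage.tsv"))
      readr::write_tsv(flat, file.path(out_dir, "community_completion.tsv"))
      list(coverage = cov, completion = cc)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("thermoprofiler")),
    seed = cfg$seed, stages = cfg$stages, params = cfg$params,
    input_checksums = as.list(tools::md5sum(unlist(cfg$inputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
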