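# Fully self-consistent synthetic study bundles: taxa with nested
# lineages, a gene catalog with KO annotations and a pathway map, hit
# tables consistent with the true lineages, OTU and gene count matrices
# with planted temperature correlations and planted pathway
# enrichments, a phylogeny, sample metadata, and a ground-truth
# manifest sufficient to score every downstream stage.

#' Define a synthetic study scenario
#'
#' Defaults mirror the study design the package targets: two site
#' groups (three Anhoni-like and four Tattapani-like samples) whose
#' on-site temperatures, pH and total dissolved solids are the seven
#' recorded field values, so the study's group statistics are
#' reproduced by default. Abundances are log-normal per taxon with
#' multinomial read allocation, keeping every count column's sum equal
#' to the requested depth.
#'
#' @param seed Master seed; every artifact derives its own substream.
#' @param n_taxa Number of reference taxa (>= 2; nested two-per-genus so
#'   congeners exist).
#' @param samples Tibble `sample_id`, `group`, `temperature`, `ph`,
#'   `tds`; default the seven-field-sample design.
#' @param planted_corr_taxa Tibble `taxon`, `sign` (+1 / -1): taxa whose
#'   abundance is a monotone transform of temperature plus noise.
#' @param planted_pathways Tibble `pathway_id`, `group`, `fold`: pathway
#'   KOs multiplied by `fold` in the named group.
#' @param genes_per_taxon Genes carried per taxon.
#' @param n_pathways,kos_per_pathway Size of the synthetic pathway map.
#' @param read_depth Reads allocated per sample (>= 100; applies to both
#'   the gene and OTU tables).
#' @param sigma Log-normal dispersion of taxon abundances.
#' @return List of class `synth_scenario`.
#' @export
synth_scenario <- function(seed = 1L, n_taxa = 40,
                           samples = default_samples(),
                           planted_corr_taxa = NULL,
                           planted_pathways = NULL,
                           genes_per_taxon = 20,
                           n_pathways = 15, kos_per_pathway = 8,
                           read_depth = 1e5, sigma = 0.5) {
  if (n_taxa < 2) abort("n_taxa must be at least 2")
  if (read_depth < 100) abort("read_depth must be at least 100")
  if (!is.null(planted_corr_taxa) && nrow(samples) < 3) {
    abort("planting a correlation target requires at least 3 samples")
  }
  structure(list(seed = as.integer(seed), n_taxa = n_taxa, samples = samples,
                 planted_corr_taxa = planted_corr_taxa,
                 planted_pathways = planted_pathways,
                 genes_per_taxon = genes_per_taxon, n_pathways = n_pathways,
                 kos_per_pathway = kos_per_pathway,
                 read_depth = read_depth, sigma = sigma),
            class = "synth_scenario")
}

#' The default seven-sample field design
#'
#' Three Anhoni samples and four Tattapani samples with the recorded
#' on-site temperature, pH and total-dissolved-solids values.
#'
#' @return Tibble `sample_id`, `group`, `temperature`, `ph`, `tds`.
#' @export
default_samples <- function() {
  tibble::tibble(
    sample_id = c("BAN", "CAN", "CAP", "TAT-1", "TAT-2", "TAT-3", "TAT-4"),
    group = c(rep("Anhoni", 3), rep("Tattapani", 4)),
    temperature = c(55, 43.5, 52.1, 98, 61.5, 69, 67),
    ph = c(7.8, 7.5, 7.8, 7.5, 7.6, 7.0, 7.8),
    tds = c(690, 590, 620, 880, 600, 700, 700)
  )
}

# Nested lineage table for n taxa: two species per genus, two genera
# per family, and so on up the ranks.
synth_lineages <- function(n_taxa) {
  i <- seq_len(n_taxa)
  tibble::tibble(
    subject_id = paste0("ref_t", i),
    domain = "Bacteria",
    phylum = paste0("Phylum_", (i - 1) %/% 32 + 1),
    class = paste0("Class_", (i - 1) %/% 16 + 1),
    order = paste0("Order_", (i - 1) %/% 8 + 1),
    family = paste0("Family_", (i - 1) %/% 4 + 1),
    genus = paste0("Genus_", (i - 1) %/% 2 + 1),
    species = paste0("Species_", i)
  )
}

#' Generate a synthetic study bundle
#'
#' Produces every input the downstream stages consume, plus a
#' ground-truth manifest. Hit tables are consistent with the true
#' lineages (each query's unique best hit is its own species at ~97%
#' identity, with decoy hits to a congener at ~88% and a
#' same-family/other-genus reference at ~70%), so LCA has a known right
#' answer. Count matrices have column sums exactly equal to the read
#' depth. With a fixed seed the bundle is byte-identical across runs,
#' and each artifact draws from its own substream.
#'
#' @param scenario A [synth_scenario()].
#' @param dir Optional directory; when given, every artifact is written
#'   there as TSV / Newick / JSON.
#' @return List: `metadata`, `lineages`, `tree`, `otu_table`,
#'   `gene_counts`, `gene_annotations`, `pathway_map`, `hits`, `truth`.
#' @export
generate_scenario <- function(scenario, dir = NULL) {
  stopifnot(inherits(scenario, "synth_scenario"))
  sc <- scenario
  lineages <- synth_lineages(sc$n_taxa)
  taxa <- lineages$species
  samples <- sc$samples
  metadata <- dplyr::mutate(samples, temp_class = temp_class(.data$temperature))

  planted <- sc$planted_corr_taxa
  if (!is.null(planted)) {
    bad <- setdiff(planted$taxon, taxa)
    if (length(bad)) abort(paste0("planted taxon not in scenario: ", paste(bad, collapse = ", ")))
  }

  # latent taxon abundance profiles (features x samples)
  withr::local_seed(substream_seed(sc$seed, "abundance"))
  tz <- as.numeric(scale(samples$temperature))
  base <- rlnorm(sc$n_taxa, meanlog = 0, sdlog = 1)
  lat <- matrix(0, sc$n_taxa, nrow(samples), dimnames = list(taxa, samples$sample_id))
  for (t in seq_len(sc$n_taxa)) {
    noise <- rnorm(nrow(samples), 0, sc$sigma)
    pl <- if (!is.null(planted)) match(taxa[t], planted$taxon) else NA
    if (!is.na(pl)) {
      lat[t, ] <- exp(planted$sign[pl] * 2.5 * tz + noise)
    } else {
      lat[t, ] <- base[t] * exp(noise)
    }
  }
  prop <- sweep(lat, 2, colSums(lat), "/")

  # OTU table: multinomial allocation per sample at the requested depth
  withr::local_seed(substream_seed(sc$seed, "otu"))
  otu <- vapply(seq_len(ncol(prop)), function(s) {
    as.numeric(rmultinom(1, sc$read_depth, prop[, s]))
  }, numeric(sc$n_taxa))
  dimnames(otu) <- dimnames(prop)

  # pathway map and gene catalog with KO annotations
  n_ko <- sc$n_pathways * sc$kos_per_pathway
  kos <- sprintf("K%05d", seq_len(n_ko))
  pathway_map <- tibble::tibble(
    pathway_id = rep(sprintf("pw%02d", seq_len(sc$n_pathways)), each = sc$kos_per_pathway),
    ko = kos,
    name = rep(sprintf("synthetic pathway %02d", seq_len(sc$n_pathways)),
               each = sc$kos_per_pathway)
  )
  withr::local_seed(substream_seed(sc$seed, "genes"))
  n_genes <- sc$n_taxa * sc$genes_per_taxon
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  gene_taxon <- rep(taxa, each = sc$genes_per_taxon)
  # every KO is carried by some gene; remaining genes draw KOs at random
  gene_ko <- character(n_genes)
  first <- seq_len(min(n_ko, n_genes))
  gene_ko[first] <- kos[first]
  if (n_genes > n_ko) gene_ko[(n_ko + 1):n_genes] <- sample(kos, n_genes - n_ko, replace = TRUE)
  gene_annotations <- tibble::tibble(gene_id = gene_ids, ko = gene_ko, taxon = gene_taxon)

  # gene counts: expected proportion = taxon share x gene weight,
  # times the planted pathway fold in the enriched group
  withr::local_seed(substream_seed(sc$seed, "gene-counts"))
  gene_w <- rlnorm(n_genes, 0, 0.25)
  gcounts <- matrix(0, n_genes, nrow(samples),
                    dimnames = list(gene_ids, samples$sample_id))
  fold <- rep(1, n_genes)
  for (s in seq_len(nrow(samples))) {
    f <- rep(1, n_genes)
    if (!is.null(sc$planted_pathways)) {
      for (r in seq_len(nrow(sc$planted_pathways))) {
        if (samples$group[s] == sc$planted_pathways$group[r]) {
          pk <- pathway_map$ko[pathway_map$pathway_id == sc$planted_pathways$pathway_id[r]]
          f[gene_ko %in% pk] <- f[gene_ko %in% pk] * sc$planted_pathways$fold[r]
        }
      }
    }
    pi_s <- prop[gene_taxon, s] * gene_w * f
    gcounts[, s] <- as.numeric(rmultinom(1, sc$read_depth, pi_s / sum(pi_s)))
  }

  # hit table consistent with the true lineages
  withr::local_seed(substream_seed(sc$seed, "hits"))
  hit_rows <- purrr::map_dfr(seq_len(sc$n_taxa), function(t) {
    lin <- lineages[t, ]
    self <- tibble::tibble(query_id = paste0("orf_t", t),
                           subject_id = lineages$subject_id[t],
                           pct_identity = 97, aln_length = 950,
                           evalue = 1e-50, bitscore = 500, subject_length = 1000)
    congener <- which(lineages$genus == lin$genus & lineages$species != lin$species)
    fam <- which(lineages$family == lin$family & lineages$genus != lin$genus)
    decoys <- dplyr::bind_rows(
      if (length(congener)) tibble::tibble(query_id = paste0("orf_t", t),
        subject_id = lineages$subject_id[congener[1]], pct_identity = 88,
        aln_length = 930, evalue = 1e-40, bitscore = 430, subject_length = 1000),
      if (length(fam)) tibble::tibble(query_id = paste0("orf_t", t),
        subject_id = lineages$subject_id[fam[1]], pct_identity = 70,
        aln_length = 900, evalue = 1e-20, bitscore = 250, subject_length = 1000)
    )
    dplyr::bind_rows(self, decoys)
  })

  # phylogeny over the taxa
  withr::local_seed(substream_seed(sc$seed, "tree"))
  tree <- ape::rcoal(sc$n_taxa, tip.label = taxa)

  truth <- list(
    seed = sc$seed,
    taxa = taxa,
    true_lineages = lineages,
    expected_proportions = as_abundance_tbl(prop),
    planted_corr_taxa = sc$planted_corr_taxa,
    planted_pathways = sc$planted_pathways,
    read_depth = sc$read_depth, sigma = sc$sigma
  )

  bundle <- list(metadata = metadata, lineages = lineages, tree = tree,
                 otu_table = as_abundance_tbl(otu),
                 gene_counts = as_abundance_tbl(gcounts),
                 gene_annotations = gene_annotations,
                 pathway_map = pathway_map, hits = hit_rows, truth = truth)
  if (!is.null(dir)) write_scenario(bundle, dir)
  bundle
}

# Write every artifact of a generated bundle into `dir`.
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(bundle$metadata[, c("sample_id", "group", "temperature", "ph", "tds")],
                   p("metadata.tsv"))
  lin_str <- apply(as.matrix(bundle$lineages[TAX_RANKS]), 1, function(x) {
    x[is.na(x)] <- ""
    paste(x, collapse = ";")
  })
  writeLines(paste(bundle$lineages$subject_id, lin_str, sep = "\t"), p("lineages.tsv"))
  readr::write_tsv(bundle$pathway_map, p("pathway_map.tsv"))
  write_abundance_tsv(bundle$otu_table, p("otu_table.tsv"))
  write_abundance_tsv(bundle$gene_counts, p("gene_counts.tsv"))
  readr::write_tsv(bundle$gene_annotations, p("gene_annotations.tsv"))
  hit_cols <- c("query_id", "subject_id", "pct_identity", "aln_length")
  h <- bundle$hits
  blast <- cbind(h$query_id, h$subject_id, h$pct_identity, h$aln_length,
                 0, 0, 1, h$aln_length, 1, h$aln_length,
                 format(h$evalue, scientific = TRUE), h$bitscore, h$subject_length)
  writeLines(apply(blast, 1, paste, collapse = "\t"), p("hits.tsv"))
  ape::write.tree(bundle$tree, p("tree.nwk"))
  truth <- bundle$truth
  truth$true_lineages <- as.data.frame(truth$true_lineages)
  truth$expected_proportions <- as.data.frame(truth$expected_proportions)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(dir)
}

#' The benzoate-degradation worked example
#'
#' Encodes the eight-enzyme aerobic benzoate degradation pathway
#' (benzoate -> catechol -> ortho-cleavage -> 3-oxoadipate ->
#' succinyl-CoA) as annotated to two co-occurring taxa: *Pseudomonas
#' stutzeri* carries seven of the eight enzymes but lacks 3-oxoadipate
#' CoA-transferase (K01031), which *Acidovorax* sp. supplies — the
#' canonical community-complementation case. Abundances are a synthetic
#' stand-in for a borehole-outlet-like sample in which both taxa are
#' present.
#'
#' @return List: `annotations` (`gene_id`, `ko`, `taxon`),
#'   `pathway_map`, `abundances` (taxon proportions for one sample).
#' @export
make_worked_example_benzoate <- function() {
  enzymes <- tibble::tribble(
    ~ko, ~name,
    "K05549", "benzoate 1,2-dioxygenase subunit alpha",
    "K05784", "dihydroxycyclohexadiene carboxylate dehydrogenase",
    "K03381", "catechol 1,2-dioxygenase",
    "K01856", "muconate cycloisomerase",
    "K03464", "muconolactone isomerase",
    "K01055", "3-oxoadipate enol-lactonase",
    "K01031", "3-oxoadipate CoA-transferase",
    "K00632", "3-oxoadipyl-CoA thiolase"
  )
  pathway_map <- tibble::tibble(pathway_id = "benzoate_degradation",
                                ko = enzymes$ko,
                                name = "Benzoate degradation")
  ps_kos <- setdiff(enzymes$ko, "K01031")
  av_kos <- c("K01031", "K03381", "K01856")
  annotations <- dplyr::bind_rows(
    tibble::tibble(gene_id = paste0("ps_", ps_kos), ko = ps_kos,
                   taxon = "Pseudomonas stutzeri"),
    tibble::tibble(gene_id = paste0("av_", av_kos), ko = av_kos,
                   taxon = "Acidovorax sp.")
  )
  abundances <- tibble::tibble(
    feature_id = c("Pseudomonas stutzeri", "Acidovorax sp.", "other"),
    CAP = c(0.41, 0.20, 0.39)
  )
  list(annotations = annotations, pathway_map = pathway_map,
       abundances = abundances)
}
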