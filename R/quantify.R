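# Gene, KO/eggNOG and genome quantification from paired-read mapping
# summaries, with the counting, filtering, annotation and normalisation
# rules used for the shotgun data.

#' Annotation acceptance thresholds
#'
#' A gene receives the functional label (KO or eggNOG id) of its single
#' best hit only when that hit reaches bit score >= 60 at e-value
#' <= 1e-6.
#'
#' @param bitscore_min Minimum bit score (inclusive).
#' @param evalue_max Maximum e-value (inclusive).
#' @return List of class `annotation_params`.
#' @export
annotation_params <- function(bitscore_min = 60, evalue_max = 1e-6) {
  if (bitscore_min <= 0) abort("bitscore_min must be positive")
  structure(list(bitscore_min = bitscore_min, evalue_max = evalue_max),
            class = "annotation_params")
}

#' Genome quantification thresholds
#'
#' A read pair counts as a genome hit only when both mates map
#' concordantly to the genome at >= 90% identity each.
#'
#' @param identity_min Minimum percent identity per read (inclusive).
#' @param require_concordant Require concordant pair mapping.
#' @return List of class `genome_quant_params`.
#' @export
genome_quant_params <- function(identity_min = 90, require_concordant = TRUE) {
  if (!(identity_min > 0 && identity_min <= 100)) abort("identity_min must be in (0, 100]")
  structure(list(identity_min = identity_min,
                 require_concordant = require_concordant),
            class = "genome_quant_params")
}

#' Count gene-mapped reads per sample
#'
#' Counting rule for paired-end mapping evidence: a pair with both reads
#' on the same gene contributes both reads; a pair with one read on a
#' gene and the mate unmapped contributes that one read; a pair split
#' across two different genes contributes nothing. With
#' `unit = "fragments"` a qualifying pair contributes 1 instead of 2.
#'
#' @param mappings Tibble of per-fragment mapping summaries with columns
#'   `sample_id`, `fragment_id`, `read1_gene`, `read2_gene` (`NA` =
#'   unmapped).
#' @param samples Optional sample ids fixing the output columns (samples
#'   with no mappings get all-zero columns).
#' @param unit `"reads"` (default) or `"fragments"`.
#' @return Gene-by-sample abundance tibble of counts.
#' @export
count_gene_reads <- function(mappings, samples = NULL, unit = c("reads", "fragments")) {
  unit <- match.arg(unit)
  samples <- samples %||% unique(mappings$sample_id)
  both <- !is.na(mappings$read1_gene) & !is.na(mappings$read2_gene)
  same <- both & mappings$read1_gene == mappings$read2_gene
  single1 <- !is.na(mappings$read1_gene) & is.na(mappings$read2_gene)
  single2 <- is.na(mappings$read1_gene) & !is.na(mappings$read2_gene)
  contrib <- dplyr::bind_rows(
    tibble::tibble(sample_id = mappings$sample_id[same],
                   gene = mappings$read1_gene[same],
                   n = if (unit == "reads") 2 else 1),
    tibble::tibble(sample_id = mappings$sample_id[single1],
                   gene = mappings$read1_gene[single1], n = 1),
    tibble::tibble(sample_id = mappings$sample_id[single2],
                   gene = mappings$read2_gene[single2], n = 1)
  )
  genes <- sort(unique(contrib$gene))
  m <- matrix(0, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  if (nrow(contrib)) {
    agg <- contrib |>
      dplyr::group_by(.data$sample_id, .data$gene) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop")
    m[cbind(match(agg$gene, genes), match(agg$sample_id, samples))] <- agg$n
  }
  as_abundance_tbl(m)
}

#' Remove genes with low total counts
#'
#' Drops genes whose total count across samples is below `min_total`
#' (default 10), removing ambiguous low-evidence genes.
#'
#' @param tbl Gene abundance tibble of counts.
#' @param min_total Genes with total < `min_total` are removed.
#' @return Filtered abundance tibble.
#' @export
filter_low_count_genes <- function(tbl, min_total = 10) {
  m <- abundance_matrix(tbl)
  tbl[rowSums(m) >= min_total, , drop = FALSE]
}

#' Annotate genes by best hit against a functional reference
#'
#' Each gene is labelled with the annotation of its single highest
#' bit-score hit, provided that hit satisfies the acceptance thresholds;
#' otherwise the gene is left unannotated (absent from the result). Ties
#' at the maximum bit score are broken by lower e-value, then first
#' occurrence.
#'
#' @param gene_hits Tibble of hits with columns `query_id` (gene),
#'   `subject_id`, `bitscore`, `evalue`, and `annotation` (the KO or
#'   eggNOG id carried by the subject).
#' @param params An [annotation_params()] object.
#' @return Tibble: `gene_id`, `annotation`.
#' @export
annotate_genes <- function(gene_hits, params = annotation_params()) {
  gene_hits |>
    dplyr::group_by(gene_id = .data$query_id) |>
    dplyr::slice_max(.data$bitscore, n = 1, with_ties = TRUE) |>
    dplyr::slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$bitscore >= params$bitscore_min,
                  .data$evalue <= params$evalue_max) |>
    dplyr::select("gene_id", "annotation")
}

#' Aggregate gene counts to functional identifiers
#'
#' Sums counts of genes sharing a KO (or eggNOG) id, then converts each
#' sample column to relative abundance over annotated counts only.
#' A sample with zero annotated counts is an error.
#'
#' @param gene_tbl Gene abundance tibble of (filtered) counts.
#' @param annotations Tibble `gene_id`, `annotation` from
#'   [annotate_genes()].
#' @param relative Return per-sample proportions (default) or raw sums.
#' @return Annotation-by-sample abundance tibble.
#' @export
aggregate_to_ko <- function(gene_tbl, annotations, relative = TRUE) {
  m <- abundance_matrix(gene_tbl)
  ann <- annotations[annotations$gene_id %in% rownames(m), , drop = FALSE]
  if (nrow(ann) == 0) abort("no annotated genes present in the abundance table")
  sub <- m[ann$gene_id, , drop = FALSE]
  agg <- rowsum(sub, group = ann$annotation)
  if (relative) {
    cs <- colSums(agg)
    if (any(cs == 0)) {
      abort(paste0("sample(s) with zero annotated counts: ",
                   paste(colnames(agg)[cs == 0], collapse = ", ")))
    }
    agg <- sweep(agg, 2, cs, "/")
  }
  as_abundance_tbl(agg)
}

#' Quantify reference genomes from paired-read mappings
#'
#' A qualifying hit is a concordant pair with both reads at or above the
#' identity floor. Per genome and sample, the read count (2 x qualifying
#' pairs) is normalised by reference genome length and by the sample's
#' total library size, and the resulting columns are renormalised to
#' proportions.
#'
#' @param mappings Tibble with columns `sample_id`, `fragment_id`,
#'   `genome`, `read1_identity`, `read2_identity`, `concordant`.
#' @param genome_lengths Named numeric vector, genome id -> length in bases.
#' @param library_sizes Named numeric vector, sample id -> total reads.
#' @param params A [genome_quant_params()] object.
#' @param relative Renormalise columns to proportions (default) or return
#'   the size/depth-corrected rates.
#' @return Genome-by-sample abundance tibble.
#' @export
quantify_genomes <- function(mappings, genome_lengths, library_sizes,
                             params = genome_quant_params(), relative = TRUE) {
  qual <- mappings$read1_identity >= params$identity_min &
    mappings$read2_identity >= params$identity_min
  if (params$require_concordant) qual <- qual & mappings$concordant
  hits <- mappings[qual, , drop = FALSE]
  missing <- setdiff(unique(hits$genome), names(genome_lengths))
  if (length(missing)) {
    abort(paste0("genome(s) without a reference length: ", paste(missing, collapse = ", ")))
  }
  samples <- names(library_sizes)
  genomes <- sort(unique(hits$genome))
  if (length(genomes) == 0) abort("no qualifying genome hits")
  pairs <- matrix(0, length(genomes), length(samples), dimnames = list(genomes, samples))
  agg <- hits |> dplyr::count(.data$sample_id, .data$genome)
  pairs[cbind(match(agg$genome, genomes), match(agg$sample_id, samples))] <- agg$n
  raw <- (2 * pairs) / outer(genome_lengths[genomes], library_sizes[samples])
  if (relative) {
    cs <- colSums(raw)
    cs[cs == 0] <- NA_real_
    raw <- sweep(raw, 2, cs, "/")
    raw[is.na(raw)] <- 0
  }
  as_abundance_tbl(raw)
}
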