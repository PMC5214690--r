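# Readers and writers for the external formats the pipeline touches.
# All tables are TSV, UTF-8, unquoted; readers reject invariant-violating
# input rather than coercing it.

BLAST12_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                  "mismatches", "gap_opens", "q_start", "q_end",
                  "s_start", "s_end", "evalue", "bitscore")

#' Read a tabular alignment hit file
#'
#' Parses BLAST-style tabular output (the standard 12-column dialect, or
#' the same with reference/subject length appended as column 13, needed
#' when an alignment-coverage filter will be applied downstream).
#'
#' @param path Path to a TSV hit file without header.
#' @param dialect `"blast_tab_12col"` or `"extended_with_slen"`.
#' @return Tibble with one row per hit: `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `evalue`, `bitscore` and, in the
#'   extended dialect, `subject_length`.
#' @export
read_hit_table <- function(path, dialect = c("blast_tab_12col", "extended_with_slen")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("hit file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  ncol_expect <- if (dialect == "blast_tab_12col") 12L else 13L
  cols <- c(BLAST12_COLS, if (dialect == "extended_with_slen") "subject_length")
  if (length(lines) == 0 || all(!nzchar(lines))) {
    warn(paste0("empty hit file: ", path))
    out <- tibble::as_tibble(setNames(rep(list(character()), length(cols)), cols))
    num <- setdiff(cols, c("query_id", "subject_id"))
    out[num] <- lapply(out[num], as.numeric)
    return(out[c("query_id", "subject_id", "pct_identity", "aln_length",
                 "evalue", "bitscore", intersect("subject_length", cols))])
  }
  keep <- nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  line_no <- which(keep)
  bad <- which(lengths(fields) != ncol_expect)
  if (length(bad)) {
    abort(paste0("malformed hit row(s) (expected ", ncol_expect, " columns) at line(s): ",
                 paste(head(line_no[bad], 5), collapse = ", ")))
  }
  m <- do.call(rbind, fields)
  tbl <- tibble::as_tibble(setNames(as.list(as.data.frame(m, stringsAsFactors = FALSE)), cols))
  num_cols <- setdiff(cols, c("query_id", "subject_id"))
  for (nm in num_cols) {
    v <- suppressWarnings(as.numeric(tbl[[nm]]))
    if (anyNA(v)) {
      abort(paste0("non-numeric value in column '", nm, "' at line(s): ",
                   paste(head(line_no[is.na(v)], 5), collapse = ", ")))
    }
    tbl[[nm]] <- v
  }
  chk <- function(ok, msg) {
    if (any(!ok)) abort(paste0(msg, " at line(s): ", paste(head(line_no[!ok], 5), collapse = ", ")))
  }
  chk(tbl$pct_identity >= 0 & tbl$pct_identity <= 100, "percent identity outside [0, 100]")
  chk(tbl$aln_length >= 1, "alignment length < 1")
  chk(tbl$evalue >= 0, "negative e-value")
  tbl[c("query_id", "subject_id", "pct_identity", "aln_length",
        "evalue", "bitscore", intersect("subject_length", cols))]
}

#' Read a feature-by-sample abundance table
#'
#' Header row holds sample ids; first column holds feature ids.
#' Duplicate feature ids and non-numeric cells are rejected with their
#' coordinates.
#'
#' @param path Path to a TSV abundance file.
#' @return Abundance tibble (`feature_id` + one numeric column per sample).
#' @export
read_abundance_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("abundance file not found: ", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(tbl)[1] <- "feature_id"
  if (anyDuplicated(tbl$feature_id)) {
    dup <- unique(tbl$feature_id[duplicated(tbl$feature_id)])
    abort(paste0("duplicated feature id(s) in ", path, ": ", paste(head(dup, 5), collapse = ", ")))
  }
  for (nm in names(tbl)[-1]) {
    v <- suppressWarnings(as.numeric(tbl[[nm]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(paste0("non-numeric cell in ", path, " at row ", bad, " (feature '",
                   tbl$feature_id[bad], "'), column '", nm, "'"))
    }
    tbl[[nm]] <- v
  }
  abundance_matrix(tbl)  # validates
  tbl
}

#' Write an abundance table as TSV
#'
#' Integer counts round-trip exactly; proportions are written at full
#' double precision (round-trip error below 1e-12).
#'
#' @param tbl Abundance tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(tbl, path) {
  m <- abundance_matrix(tbl)
  fmt <- apply(m, c(1, 2), function(x) {
    if (x == round(x) && abs(x) < 2^53) format(x, scientific = FALSE) else
      formatC(x, digits = 17, format = "g")
  })
  out <- cbind(feature_id = rownames(m), fmt)
  lines <- c(paste(colnames(out), collapse = "\t"),
             apply(out, 1, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' Thin wrapper over [ape::read.tree()] with validation for downstream
#' UniFrac use: when `require_branch_lengths` is set, every edge must
#' carry a branch length.
#'
#' @param path Path to a Newick file.
#' @param require_branch_lengths Error if any edge lacks a branch length.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path, require_branch_lengths = FALSE) {
  if (!file.exists(path)) abort(paste0("tree file not found: ", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort(paste0("failed to parse Newick file ", path, ": ",
                                                    conditionMessage(e))))
  if (is.null(tree)) abort(paste0("failed to parse Newick file: ", path))
  if (require_branch_lengths &&
      (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
       length(tree$edge.length) != nrow(tree$edge))) {
    abort(paste0("tree in ", path, " lacks branch lengths on some edges (required for UniFrac)"))
  }
  tree
}

#' Read a reference lineage table
#'
#' Two-column TSV: subject id, then a semicolon-separated seven-rank
#' lineage (domain;phylum;class;order;family;genus;species). Empty rank
#' slots mean "unassigned below here"; Greengenes-style rank prefixes
#' (`k__`, `p__`, ...) are stripped. Non-empty ranks must be contiguous
#' from the root.
#'
#' @param path Path to the lineage TSV (no header).
#' @return Tibble: `subject_id` plus one column per rank, `NA` where
#'   unassigned.
#' @export
read_lineages <- function(path) {
  if (!file.exists(path)) abort(paste0("lineage file not found: ", path))
  raw <- readr::read_tsv(path, col_names = c("subject_id", "lineage"),
                         col_types = "cc", progress = FALSE)
  if (anyDuplicated(raw$subject_id)) {
    abort(paste0("duplicated subject id(s) in lineage table ",
                 paste(unique(raw$subject_id[duplicated(raw$subject_id)]), collapse = ", ")))
  }
  parts <- strsplit(raw$lineage %||% character(), ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[a-z]__", "", p)
    length(p) <- length(TAX_RANKS)
    p[is.na(p) | p == ""] <- NA_character_
    p
  }, character(length(TAX_RANKS))))
  colnames(m) <- TAX_RANKS
  # contiguity: no named rank below an unnamed one
  filled <- !is.na(m)
  gaps <- apply(filled, 1, function(f) any(diff(f) == 1))
  if (any(gaps)) {
    abort(paste0("lineage with a gap (rank named below an unnamed rank) for subject(s): ",
                 paste(head(raw$subject_id[gaps], 5), collapse = ", ")))
  }
  dplyr::bind_cols(tibble::tibble(subject_id = raw$subject_id), tibble::as_tibble(m))
}

#' Read a pathway membership map
#'
#' TSV with header columns `pathway_id`, `ko` and optionally `name`.
#' Every pathway must have at least one KO; duplicate (pathway, KO) pairs
#' are rejected.
#'
#' @param path Path to the pathway-map TSV.
#' @return Tibble: `pathway_id`, `ko`, `name` (`NA` when absent).
#' @export
read_pathway_map <- function(path) {
  if (!file.exists(path)) abort(paste0("pathway map not found: ", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("pathway_id", "ko") %in% names(tbl))) {
    abort("pathway map must have columns `pathway_id` and `ko`")
  }
  if (!"name" %in% names(tbl)) tbl$name <- NA_character_
  validate_pathway_map(tbl)
  tbl[c("pathway_id", "ko", "name")]
}

validate_pathway_map <- function(tbl) {
  if (nrow(tbl) == 0) abort("pathway map is empty")
  if (any(is.na(tbl$ko) | tbl$ko == "")) {
    abort(paste0("pathway with empty KO entry: ",
                 paste(unique(tbl$pathway_id[is.na(tbl$ko) | tbl$ko == ""]), collapse = ", ")))
  }
  key <- paste(tbl$pathway_id, tbl$ko)
  if (anyDuplicated(key)) {
    abort(paste0("duplicated KO within pathway: ", paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  invisible(tbl)
}

#' Classify temperatures into the study's three thermal groups
#'
#' Moderately high covers 40-55 degrees C inclusive, high is the open
#' interval 55-75, and extremely high is 75 and above. The 55 degree
#' boundary belongs to the moderately-high class by default.
#'
#' @param temperature Numeric vector of temperatures (degrees C).
#' @param boundary_55 Class receiving exactly 55 degrees
#'   (`"moderately_high"` or `"high"`).
#' @return Factor with levels `moderately_high`, `high`, `extremely_high`;
#'   `NA` below 40 degrees.
#' @export
temp_class <- function(temperature, boundary_55 = c("moderately_high", "high")) {
  boundary_55 <- match.arg(boundary_55)
  lo55 <- if (boundary_55 == "moderately_high") temperature <= 55 else temperature < 55
  cls <- dplyr::case_when(
    temperature >= 75 ~ "extremely_high",
    temperature >= 40 & lo55 ~ "moderately_high",
    temperature >= 40 ~ "high",
    TRUE ~ NA_character_
  )
  factor(cls, levels = c("moderately_high", "high", "extremely_high"))
}

#' Read per-sample metadata
#'
#' TSV with header columns `sample_id`, `group`, `temperature`, `ph`,
#' `tds`. A `temp_class` factor is derived from temperature.
#'
#' @param path Path to the metadata TSV.
#' @return Tibble with the columns above plus `temp_class`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("metadata file not found: ", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), group = readr::col_character(),
    temperature = readr::col_double(), ph = readr::col_double(),
    tds = readr::col_double()), progress = FALSE)
  if (anyDuplicated(tbl$sample_id)) abort("duplicated sample ids in metadata")
  tbl$temp_class <- temp_class(tbl$temperature)
  tbl
}
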