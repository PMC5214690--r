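# Internal helpers shared across modules.

# An abundance table is a tibble whose first column is `feature_id`
# (unique, character) and whose remaining columns are one numeric,
# non-negative vector per sample.

#' Convert an abundance tibble to a numeric matrix
#'
#' Validates the feature-by-sample contract (unique feature ids, numeric
#' non-negative sample columns) and returns the values as a matrix with
#' feature ids as rownames.
#'
#' @param tbl Abundance tibble: first column `feature_id`, one numeric
#'   column per sample.
#' @return Numeric matrix, features in rows, samples in columns.
#' @export
abundance_matrix <- function(tbl) {
  if (!is.data.frame(tbl) || ncol(tbl) < 2) {
    abort("abundance table must be a data frame with `feature_id` plus at least one sample column")
  }
  if (names(tbl)[1] != "feature_id") {
    abort("first column of an abundance table must be `feature_id`")
  }
  ids <- as.character(tbl[["feature_id"]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicated feature ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (nrow(m) == 0) storage.mode(m) <- "double"
  if (!is.numeric(m)) abort("sample columns must be numeric")
  if (anyNA(m)) abort("abundance table contains missing values")
  if (any(m < 0)) abort("abundance values must be non-negative")
  rownames(m) <- ids
  m
}

#' Build an abundance tibble from a matrix
#'
#' @param m Numeric matrix with feature rownames and sample colnames.
#' @return Tibble with `feature_id` first column.
#' @export
as_abundance_tbl <- function(m) {
  tibble::as_tibble(m, rownames = "feature_id")
}

#' Column-normalise an abundance table to proportions
#'
#' Divides every sample column by its total so columns sum to one.
#'
#' @param tbl Abundance tibble.
#' @return Abundance tibble of per-sample proportions.
#' @export
normalize_abundance <- function(tbl) {
  m <- abundance_matrix(tbl)
  cs <- colSums(m)
  if (any(cs == 0)) {
    abort(paste0("cannot normalise all-zero sample column(s): ",
                 paste(colnames(m)[cs == 0], collapse = ", ")))
  }
  as_abundance_tbl(sweep(m, 2, cs, "/"))
}

# Derive a reproducible 32-bit substream seed from a master seed and a
# stream label, so adding an artifact never perturbs the others.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- rlang::`%||%`
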