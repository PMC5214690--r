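# Broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a principal-coordinates ordination
#'
#' @param x A `tp_pcoa` object.
#' @param ... Unused.
#' @return Tibble of sample coordinates (`sample_id`, `Axis1..k`).
#' @export
tidy.tp_pcoa <- function(x, ...) x$points

#' One-row summary of a principal-coordinates ordination
#'
#' @param x A `tp_pcoa` object.
#' @param ... Unused.
#' @return Tibble: `n_samples`, `n_negative_eig`, `explained_axis1`,
#'   `explained_axis2`.
#' @export
glance.tp_pcoa <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$points),
    n_negative_eig = sum(x$eig < -1e-9),
    explained_axis1 = x$explained[1],
    explained_axis2 = if (length(x$explained) > 1) x$explained[2] else NA_real_
  )
}

#' Tidy an exact rank-sum test
#'
#' @param x A `tp_ranksum` object.
#' @param ... Unused.
#' @return One-row tibble: `U`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
tidy.tp_ranksum <- function(x, ...) {
  tibble::tibble(U = x$U, p_value = x$p.value, n_a = x$n_a, n_b = x$n_b,
                 method = x$method)
}

#' Tidy a distance object into long form
#'
#' @param x A [stats::dist] object.
#' @param ... Unused.
#' @return Tibble: `sample_a`, `sample_b`, `distance` (lower triangle).
#' @export
tidy.dist <- function(x, ...) {
  m <- as.matrix(x)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble::tibble(sample_a = rownames(m)[idx[, 2]],
                 sample_b = rownames(m)[idx[, 1]],
                 distance = m[idx])
}
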