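# broom-style accessors for the fitted/derived objects.

#' Tidy a substitution spectrum
#'
#' @param x An `rdd_spectrum`.
#' @param ... Ignored.
#' @return Tibble with `class`, `n`, `fraction`.
#' @exportS3Method generics::tidy
tidy.rdd_spectrum <- function(x, ...) {
  total <- attr(x, "total")
  tibble(class = x$class, n = x$n,
         fraction = if (total > 0) x$n / total else NA_real_)
}

#' @rdname tidy.rdd_spectrum
#' @return `glance()`: one row with `total` and `frac_ag`.
#' @exportS3Method generics::glance
glance.rdd_spectrum <- function(x, ...) {
  tibble(total = attr(x, "total"), frac_ag = attr(x, "frac_ag"))
}

#' Tidy a tissue dendrogram
#'
#' @param x An `rdd_dendrogram`.
#' @param ... Ignored.
#' @return The merge table: `step`, `left`, `right`, `height` (negative
#'   entries are leaves, positive entries earlier merges, as in
#'   [stats::hclust()]).
#' @exportS3Method generics::tidy
tidy.rdd_dendrogram <- function(x, ...) {
  x$merges
}

#' @rdname tidy.rdd_dendrogram
#' @exportS3Method generics::glance
glance.rdd_dendrogram <- function(x, ...) {
  tibble(n_leaves = length(x$labels),
         n_merges = nrow(x$merges),
         max_height = max(x$merges$height),
         last_separated = paste(last_merged_leaves(x), collapse = ","))
}

#' Tidy the 3'-context bias test
#'
#' @param x An `rdd_bias`.
#' @param ... Ignored.
#' @return One-row tibble: `estimate` (proportion of sites with a 3' A),
#'   `null_value` (background A frequency), `p_value`, `conf_low`,
#'   `conf_high`, `n`.
#' @exportS3Method generics::tidy
tidy.rdd_bias <- function(x, ...) {
  ht <- attr(x, "test")
  tibble(estimate = x$proportion, null_value = x$background,
         p_value = x$p_value,
         conf_low = ht$conf.int[1L], conf_high = ht$conf.int[2L],
         n = x$n_events)
}

#' One-row summary of a pipeline report
#'
#' @param x An `rdd_report`.
#' @param ... Ignored.
#' @return Tibble: gene/clone/event counts, A>G fraction, synonymous and
#'   non-synonymous totals, and the last-separated tissue (when a
#'   dendrogram exists).
#' @exportS3Method generics::glance
glance.rdd_report <- function(x, ...) {
  tibble(
    n_genes = length(x$genes),
    n_clones = sum(x$clones$source == "cDNA"),
    n_events = nrow(x$events),
    n_substitutions = sum(x$events$kind == "substitution"),
    n_insertions = sum(x$events$kind == "insertion"),
    n_deletions = sum(x$events$kind == "deletion"),
    frac_ag = attr(x$spectrum, "frac_ag"),
    synonymous = sum(x$syn_nonsyn$synonymous),
    nonsynonymous = sum(x$syn_nonsyn$nonsynonymous),
    last_separated = if (is.null(x$dendrogram)) NA_character_ else
      paste(last_merged_leaves(x$dendrogram), collapse = ","))
}
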