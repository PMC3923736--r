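# Tissue-level statistics: the 12-class substitution spectrum, 3'-context
# bias, gene x tissue tabulation, synonymous split, per-clone rates, and
# complete-linkage clustering of tissues on their RDD profiles.

#' Substitution spectrum
#'
#' Counts substitution events in the 12 ordered base-change classes
#' (`A>C`, `A>G`, ..., `T>G`). Indels are ignored. The A>G fraction is the
#' classic readout of A-to-I editing, which presents as an A>G mismatch
#' when the edited transcript is sequenced.
#'
#' @param events Event tibble.
#' @return Tibble of class `rdd_spectrum` with `class`, `n`; attributes
#'   `total` and `frac_ag`.
#' @export
substitution_spectrum <- function(events) {
  subs <- filter(events, .data$kind == "substitution")
  cls <- paste0(subs$ref_allele, ">", subs$alt_allele)
  counts <- table(factor(cls, levels = SUB_CLASSES))
  out <- tibble(class = SUB_CLASSES, n = as.integer(counts))
  attr(out, "total") <- nrow(subs)
  attr(out, "frac_ag") <- if (nrow(subs)) {
    out$n[out$class == "A>G"] / nrow(subs)
  } else {
    NA_real_
  }
  class(out) <- c("rdd_spectrum", class(out))
  out
}

#' 3'-neighbour adenosine context bias
#'
#' Tests whether substituted sites sit 5' of an adenosine more often than
#' the reference base composition predicts. For each substitution not at
#' the reference 3' terminus, the 3' neighbour is the reference base at
#' `pos + 1`; the observed proportion of A neighbours is compared to the
#' background frequency of A among the possible 3'-neighbour positions
#' (2..L of the reference) with a two-sided exact binomial test. A single
#' planned test, so no multiplicity correction is applied.
#'
#' @param events Event tibble (substitutions used).
#' @param ref A [transcript_ref()] or cDNA string.
#' @return Tibble of class `rdd_bias`: `n_events`, `n_3prime_a`,
#'   `proportion`, `background`, `p_value`; the `htest` is kept as
#'   attribute `test`.
#' @export
three_prime_context_bias <- function(events, ref) {
  cdna <- if (inherits(ref, "transcript_ref")) ref$cdna else ref
  check_dna(cdna, "ref")
  L <- str_length(cdna)
  subs <- filter(events, .data$kind == "substitution", .data$pos < L)
  if (nrow(subs) == 0L) {
    abort("No eligible substitution events (internal positions) to test.")
  }
  neighbours <- str_sub(cdna, subs$pos + 1L, subs$pos + 1L)
  x <- sum(neighbours == "A")
  chars <- str_split(cdna, "")[[1L]]
  background <- mean(chars[2:L] == "A")
  ht <- binom.test(x, nrow(subs), p = background, alternative = "two.sided")
  out <- tibble(n_events = nrow(subs), n_3prime_a = x,
                proportion = x / nrow(subs), background = background,
                p_value = ht$p.value)
  attr(out, "test") <- ht
  class(out) <- c("rdd_bias", class(out))
  out
}

#' Gene-by-tissue RDD count matrix
#'
#' Tabulates events per gene and tissue, with row totals, a column-total
#' row and the grand total, in the layout of a per-gene/tissue RDD table.
#'
#' @param events Event tibble with `gene_id` and `tissue`.
#' @param genes,tissues Optional orderings (and zero-count levels).
#' @return Tibble of class `rdd_matrix`: one row per gene plus a `Total`
#'   row; columns per tissue plus `Total`.
#' @export
gene_tissue_counts <- function(events, genes = NULL, tissues = NULL) {
  genes <- genes %||% unique(events$gene_id)
  tissues <- tissues %||% unique(events$tissue)
  counts <- events |>
    count(gene_id = factor(.data$gene_id, levels = genes),
          tissue = factor(.data$tissue, levels = tissues),
          .drop = FALSE, name = "n") |>
    filter(!is.na(.data$gene_id), !is.na(.data$tissue)) |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "n",
                       values_fill = 0L) |>
    mutate(gene_id = as.character(.data$gene_id))
  tissue_cols <- setdiff(names(counts), "gene_id")
  counts$Total <- rowSums(counts[tissue_cols])
  total_row <- c(list(gene_id = "Total"),
                 as.list(colSums(counts[c(tissue_cols, "Total")])))
  out <- bind_rows(counts, as_tibble(total_row))
  class(out) <- c("rdd_matrix", class(out))
  out
}

#' Build an `rdd_matrix` from a pre-tabulated count grid
#'
#' Takes a gene-by-tissue grid of counts (first column `gene_id`, one
#' numeric column per tissue) - e.g. a published tabulation ingested as a
#' fixture - and attaches the row totals, column-total row and grand
#' total.
#'
#' @param grid Data frame with `gene_id` plus numeric tissue columns.
#' @return Tibble of class `rdd_matrix`, as from [gene_tissue_counts()].
#' @export
as_rdd_matrix <- function(grid) {
  grid <- as_tibble(grid)
  if (names(grid)[1L] != "gene_id") abort("First column must be `gene_id`.")
  tissue_cols <- setdiff(names(grid), "gene_id")
  grid$Total <- rowSums(grid[tissue_cols])
  total_row <- c(list(gene_id = "Total"),
                 as.list(colSums(grid[c(tissue_cols, "Total")])))
  out <- bind_rows(grid, as_tibble(total_row))
  class(out) <- c("rdd_matrix", class(out))
  out
}

#' Synonymous / non-synonymous split of coding substitutions
#'
#' Compares, per substitution event inside the reading frame (including
#' the stop codon), the native codon against the substituted codon under
#' the standard genetic code. Events outside the reading frame are counted
#' in neither class and reported via a message.
#'
#' @param events Event tibble.
#' @param ref A [transcript_ref()].
#' @return Tibble: `synonymous`, `nonsynonymous`, `outside_orf`.
#' @export
syn_nonsyn_counts <- function(events, ref) {
  stopifnot(inherits(ref, "transcript_ref"))
  subs <- filter(events, .data$kind == "substitution")
  orf_start <- ref$orf_offset + 1L
  orf_end <- ref$orf_offset + 3L * (ref$native_len_aa + 1L)  # incl. stop
  syn <- 0L; nonsyn <- 0L; outside <- 0L
  code <- codon_table()
  for (k in seq_len(nrow(subs))) {
    p <- subs$pos[k]
    if (p < orf_start || p > orf_end) {
      outside <- outside + 1L
      next
    }
    codon_idx <- (p - orf_start) %/% 3L
    c_start <- orf_start + 3L * codon_idx
    codon <- str_sub(ref$cdna, c_start, c_start + 2L)
    var_codon <- codon
    str_sub(var_codon, p - c_start + 1L, p - c_start + 1L) <- subs$alt_allele[k]
    if (identical(unname(code[codon]), unname(code[var_codon]))) {
      syn <- syn + 1L
    } else {
      nonsyn <- nonsyn + 1L
    }
  }
  if (outside > 0L) {
    inform(sprintf("%d substitution(s) outside the reading frame were not classified.",
                   outside))
  }
  tibble(synonymous = syn, nonsynonymous = nonsyn, outside_orf = outside)
}

#' RDD rate per clone and per kb per clone
#'
#' @param events Event tibble (one gene).
#' @param clones Clone tibble or an integer clone count (cDNA clones).
#' @param ref A [transcript_ref()] or cDNA string (for the kb length).
#' @return Tibble: `n_events`, `n_clones`, `rate_per_clone`,
#'   `rate_per_kb_per_clone`.
#' @export
rdd_rate <- function(events, clones, ref) {
  n_clones <- if (is.data.frame(clones)) {
    sum(clones$source == "cDNA")
  } else {
    as.integer(clones)
  }
  if (n_clones < 1L) abort("Need at least one clone.")
  cdna <- if (inherits(ref, "transcript_ref")) ref$cdna else ref
  kb <- str_length(cdna) / 1000
  tibble(n_events = nrow(events), n_clones = n_clones,
         rate_per_clone = nrow(events) / n_clones,
         rate_per_kb_per_clone = nrow(events) / n_clones / kb)
}

#' Tissue-by-site feature matrix for clustering
#'
#' Builds the numeric matrix tissues are clustered on: rows are tissues,
#' columns either per-site event counts (`feature = "sites"`, the
#' default) or the 12 substitution classes (`feature = "spectrum"`).
#' Clones without RDDs contribute nothing, so they are implicitly
#' excluded, as in the analysis this reproduces.
#'
#' @param events Event tibble.
#' @param feature `"sites"` or `"spectrum"`.
#' @return Numeric matrix with tissue row names.
#' @export
tissue_feature_matrix <- function(events, feature = c("sites", "spectrum")) {
  feature <- match.arg(feature)
  if (feature == "sites") {
    tab <- events |>
      count(.data$tissue, site = paste0(.data$gene_id, ":", .data$pos)) |>
      tidyr::pivot_wider(names_from = "site", values_from = "n",
                         values_fill = 0L)
  } else {
    tab <- events |>
      filter(.data$kind == "substitution") |>
      count(.data$tissue,
            class = factor(paste0(.data$ref_allele, ">", .data$alt_allele),
                           levels = SUB_CLASSES), .drop = FALSE) |>
      tidyr::pivot_wider(names_from = "class", values_from = "n",
                         values_fill = 0L)
  }
  m <- as.matrix(tab[-1L])
  rownames(m) <- tab$tissue
  storage.mode(m) <- "double"
  m
}

#' Complete-linkage clustering of tissues
#'
#' Pairwise Euclidean distances between tissue feature rows, agglomerated
#' with complete linkage (`stats::hclust`), with heights therefore
#' non-decreasing. The result carries a Newick export of the merge tree.
#'
#' @param mat Numeric tissue-by-feature matrix (rows >= 2) or an event
#'   tibble (then passed through [tissue_feature_matrix()]).
#' @param feature Feature space when `mat` is an event tibble.
#' @return Object of class `rdd_dendrogram`: `hclust` (the fit), `labels`,
#'   `merges` (tibble of merge heights) and `newick` (string).
#' @export
tissue_dendrogram <- function(mat, feature = "sites") {
  if (is.data.frame(mat) && "tissue" %in% names(mat)) {
    mat <- tissue_feature_matrix(mat, feature)
  }
  if (!is.matrix(mat) || nrow(mat) < 2L) {
    abort("Need a matrix with at least two tissue rows.")
  }
  hc <- hclust(dist(mat, method = "euclidean"), method = "complete")
  merges <- tibble(step = seq_len(nrow(hc$merge)),
                   left = hc$merge[, 1L], right = hc$merge[, 2L],
                   height = hc$height)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, labels = hc$labels, merges = merges,
                 newick = newick),
            class = "rdd_dendrogram")
}

#' @export
print.rdd_dendrogram <- function(x, ...) {
  cat(sprintf("<rdd_dendrogram> %d leaves, %d merges; heights %s\n",
              length(x$labels), nrow(x$merges),
              paste(signif(x$merges$height, 4), collapse = ", ")))
  invisible(x)
}

# Leaves merged in the final agglomeration step; a singleton here is the
# tissue that separates from everything else at the largest height.
last_merged_leaves <- function(dendro) {
  hc <- dendro$hclust
  last <- hc$merge[nrow(hc$merge), ]
  singletons <- -last[last < 0]
  hc$labels[singletons]
}
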