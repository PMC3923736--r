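# ggplot2 views of the result types: spectrum bars, gene x tissue
# heatmap, and a segment-drawn dendrogram.

#' @describeIn substitution_spectrum Bar chart of the 12 substitution
#'   classes.
#' @param object An `rdd_spectrum`.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.rdd_spectrum <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$class, y = .data$n)) +
    geom_col(fill = "grey25") +
    labs(x = "substitution class", y = "events",
         title = "RDD substitution spectrum") +
    theme_minimal()
}

#' @describeIn gene_tissue_counts Heatmap of per-gene, per-tissue counts
#'   (totals row/column dropped).
#' @param object An `rdd_matrix`.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.rdd_matrix <- function(object, ...) {
  long <- as_tibble(object) |>
    filter(.data$gene_id != "Total") |>
    select(-"Total") |>
    tidyr::pivot_longer(-"gene_id", names_to = "tissue", values_to = "n")
  ggplot(long, aes(x = .data$tissue, y = .data$gene_id, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n), colour = "white") +
    scale_fill_gradient(low = "grey70", high = "grey10") +
    labs(x = NULL, y = NULL, fill = "RDDs",
         title = "RDD counts by gene and tissue") +
    theme_minimal()
}

#' @describeIn tissue_dendrogram Dendrogram drawn with segments; height is
#'   the complete-linkage merge distance.
#' @param object An `rdd_dendrogram`.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.rdd_dendrogram <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  leaf_x <- setNames(seq_len(n), hc$labels[hc$order])
  x_of <- numeric(nrow(hc$merge))
  h_of <- numeric(nrow(hc$merge))
  segs <- list()
  node_x <- function(id) {
    if (id < 0) unname(leaf_x[hc$labels[-id]]) else x_of[id]
  }
  node_h <- function(id) if (id < 0) 0 else h_of[id]
  for (k in seq_len(nrow(hc$merge))) {
    a <- hc$merge[k, 1L]; b <- hc$merge[k, 2L]
    xa <- node_x(a); xb <- node_x(b)
    h <- hc$height[k]
    segs[[length(segs) + 1L]] <- tibble(
      x = c(xa, xb, min(xa, xb)), xend = c(xa, xb, max(xa, xb)),
      y = c(node_h(a), node_h(b), h), yend = c(h, h, h))
    x_of[k] <- (xa + xb) / 2
    h_of[k] <- h
  }
  labels <- tibble(x = unname(leaf_x), label = names(leaf_x))
  ggplot() +
    geom_segment(data = list_rbind(segs),
                 aes(x = .data$x, xend = .data$xend,
                     y = .data$y, yend = .data$yend)) +
    geom_text(data = labels,
              aes(x = .data$x, y = -0.02 * max(hc$height),
                  label = .data$label),
              angle = 90, hjust = 1, size = 3) +
    labs(y = "height (complete linkage)", x = NULL,
         title = "Tissue clustering on RDD profiles") +
    theme_minimal()
}

#' Plot per-site RDD recurrence along the transcript
#'
#' One panel-free map of event positions: point size is the number of
#' clones of the tissue carrying the change at the site, mirroring
#' per-site editing maps.
#'
#' @param sites Output of [summarize_sites()].
#' @return A ggplot.
#' @export
plot_site_map <- function(sites) {
  ggplot(sites, aes(x = .data$pos, y = .data$tissue,
                    size = .data$n_clones, shape = .data$kind)) +
    ggplot2::geom_point() +
    labs(x = "cDNA position", y = NULL, size = "clones",
         title = "RDD sites by tissue") +
    theme_minimal()
}
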