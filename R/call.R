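# Per-clone RDD calling from normalised alignments, deletion-run merging,
# the RNA-level variant nomenclature, and per-site recurrence summaries.

event_cols <- c("clone_id", "gene_id", "tissue", "individual",
                "kind", "pos", "end", "ref_allele", "alt_allele", "rna_name")

empty_events <- function() {
  tibble(clone_id = character(), gene_id = character(), tissue = character(),
         individual = character(), kind = character(), pos = integer(),
         end = integer(), ref_allele = character(), alt_allele = character(),
         rna_name = character())
}

#' Call RNA-DNA differences for one aligned clone
#'
#' Walks the columns of a left-normalised alignment of a cDNA clone against
#' the genomic consensus and emits one event per differing column:
#' substitutions where both rows carry different bases, deletions where the
#' clone row is gapped, insertions where the consensus row is gapped
#' (adjacent inserted columns are emitted as one multi-base insertion,
#' anchored to the preceding reference base). Columns at the consensus'
#' `variable_positions` are skipped: disagreement among gDNA clones marks
#' possible allelic variation, not an RNA-level difference. Adjacent
#' deleted columns are then collapsed by [merge_deletion_runs()] and names
#' attached with [rna_name()].
#'
#' @param consensus A `consensus_result` from [build_gdna_consensus()].
#' @param pair An `aligned_pair` of the clone (query) against the consensus
#'   sequence (ref), already left-normalised.
#' @param clone_meta One-row data frame (or named list) with `clone_id`,
#'   `gene_id`, `tissue`, `individual`.
#' @param merge Collapse adjacent deletions into multi-base events
#'   (default `TRUE`).
#' @return Tibble of events with columns `clone_id`, `gene_id`, `tissue`,
#'   `individual`, `kind`, `pos`, `end`, `ref_allele`, `alt_allele`,
#'   `rna_name`. Positions are 1-based on the consensus; a deletion's `pos`
#'   is its first deleted base, an insertion's `pos` the base after which
#'   the bases are inserted (0 for an insertion before base 1).
#' @export
call_events <- function(consensus, pair, clone_meta, merge = TRUE) {
  stopifnot(inherits(consensus, "consensus_result"),
            inherits(pair, "aligned_pair"))
  meta <- as.list(clone_meta)[c("clone_id", "gene_id", "tissue", "individual")]
  rr <- str_split(pair$ref_row, "")[[1L]]
  qq <- str_split(pair$query_row, "")[[1L]]
  rpos <- cumsum(rr != "-")
  masked <- consensus$variable_positions

  kind <- character(0); pos <- integer(0); ref_a <- character(0)
  alt_a <- character(0)
  i <- 1L
  n <- length(rr)
  while (i <= n) {
    if (rr[i] == "-") {                      # insertion run
      j <- i
      while (j < n && rr[j + 1L] == "-") j <- j + 1L
      anchor <- if (i > 1L) rpos[i] else 0L
      if (!(anchor %in% masked)) {
        kind <- c(kind, "insertion"); pos <- c(pos, anchor)
        ref_a <- c(ref_a, ""); alt_a <- c(alt_a, paste(qq[i:j], collapse = ""))
      }
      i <- j + 1L
    } else if (qq[i] == "-") {               # deleted reference base
      if (!(rpos[i] %in% masked)) {
        kind <- c(kind, "deletion"); pos <- c(pos, rpos[i])
        ref_a <- c(ref_a, rr[i]); alt_a <- c(alt_a, "")
      }
      i <- i + 1L
    } else {
      if (rr[i] != qq[i] && !(rpos[i] %in% masked)) {
        kind <- c(kind, "substitution"); pos <- c(pos, rpos[i])
        ref_a <- c(ref_a, rr[i]); alt_a <- c(alt_a, qq[i])
      }
      i <- i + 1L
    }
  }
  ev <- tibble(
    clone_id = meta$clone_id %||% NA_character_,
    gene_id = meta$gene_id %||% NA_character_,
    tissue = meta$tissue %||% NA_character_,
    individual = meta$individual %||% NA_character_,
    kind = kind, pos = as.integer(pos),
    end = as.integer(pos + pmax(nchar(ref_a) - 1L, 0L)),
    ref_allele = ref_a, alt_allele = alt_a, rna_name = NA_character_)
  if (nrow(ev) == 0L) return(empty_events())
  if (merge) ev <- merge_deletion_runs(ev)
  ev$rna_name <- map_chr(seq_len(nrow(ev)), function(k) {
    rna_name(ev[k, ])
  })
  ev
}

#' Collapse adjacent single-base deletions into multi-base deletions
#'
#' Maximal runs of deletions at consecutive positions within one clone are
#' merged into a single event whose `ref_allele` is the concatenated
#' deleted bases; other events pass through untouched. Total deleted base
#' count is conserved.
#'
#' @param events Event tibble (one clone, sorted by `pos`).
#' @return Event tibble with merged deletions.
#' @export
merge_deletion_runs <- function(events) {
  if (nrow(events) == 0L) return(events)
  events <- arrange(events, .data$pos)
  out <- list()
  k <- 1L
  n <- nrow(events)
  while (k <= n) {
    row <- events[k, ]
    if (row$kind == "deletion") {
      j <- k
      while (j < n && events$kind[j + 1L] == "deletion" &&
             events$pos[j + 1L] == events$end[j] + 1L) {
        j <- j + 1L
      }
      if (j > k) {
        row$ref_allele <- paste(events$ref_allele[k:j], collapse = "")
        row$end <- events$end[j]
        if ("rna_name" %in% names(row)) row$rna_name <- NA_character_
      }
      out[[length(out) + 1L]] <- row
      k <- j + 1L
    } else {
      out[[length(out) + 1L]] <- row
      k <- k + 1L
    }
  }
  bind_rows(out)
}

#' RNA-level variant name
#'
#' Generates the RNA nomenclature used for clone-level RDDs:
#' substitution `r.68c>a`; single-base deletion `r.187a<`; two-base
#' deletion `r.115_116at<`; longer deletion `r.181-192ga<` (first and last
#' deleted base, all bases between the endpoints removed); insertion
#' `r.317a>` (base(s) inserted after position 317). Bases are lower-case.
#'
#' @param event One-row event tibble (or named list) with `kind`, `pos`,
#'   `ref_allele`, `alt_allele`.
#' @return The name string.
#' @export
rna_name <- function(event) {
  e <- as.list(event)
  ref <- str_to_lower(e$ref_allele %||% "")
  alt <- str_to_lower(e$alt_allele %||% "")
  switch(
    e$kind,
    substitution = sprintf("r.%d%s>%s", e$pos, ref, alt),
    insertion = sprintf("r.%d%s>", e$pos, alt),
    deletion = {
      len <- str_length(ref)
      if (len == 1L) {
        sprintf("r.%d%s<", e$pos, ref)
      } else if (len == 2L) {
        sprintf("r.%d_%d%s<", e$pos, e$pos + 1L, ref)
      } else {
        sprintf("r.%d-%d%s%s<", e$pos, e$pos + len - 1L,
                str_sub(ref, 1L, 1L), str_sub(ref, len, len))
      }
    },
    abort(sprintf("Unknown event kind: %s", e$kind))
  )
}

#' Parse an RNA-level variant name
#'
#' Exact inverse of [rna_name()] on generated names. For range deletions
#' (`r.181-192ga<`) the name only records the first and last deleted base,
#' so the returned `ref_allele` carries `N` for the interior bases.
#'
#' @param name Name string.
#' @return One-row tibble with `kind`, `pos`, `end`, `ref_allele`,
#'   `alt_allele`.
#' @export
parse_rna_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- str_match(name, "^r\\.(\\d+)([acgt])>([acgt])$")
  if (!is.na(m[1, 1])) {
    return(tibble(kind = "substitution", pos = as.integer(m[1, 2]),
                  end = as.integer(m[1, 2]),
                  ref_allele = str_to_upper(m[1, 3]),
                  alt_allele = str_to_upper(m[1, 4])))
  }
  m <- str_match(name, "^r\\.(\\d+)([acgt]+)>$")
  if (!is.na(m[1, 1])) {
    return(tibble(kind = "insertion", pos = as.integer(m[1, 2]),
                  end = as.integer(m[1, 2]),
                  ref_allele = "", alt_allele = str_to_upper(m[1, 3])))
  }
  m <- str_match(name, "^r\\.(\\d+)([acgt])<$")
  if (!is.na(m[1, 1])) {
    return(tibble(kind = "deletion", pos = as.integer(m[1, 2]),
                  end = as.integer(m[1, 2]),
                  ref_allele = str_to_upper(m[1, 3]), alt_allele = ""))
  }
  m <- str_match(name, "^r\\.(\\d+)_(\\d+)([acgt]{2})<$")
  if (!is.na(m[1, 1])) {
    p1 <- as.integer(m[1, 2]); p2 <- as.integer(m[1, 3])
    if (p2 != p1 + 1L) abort(sprintf("Malformed two-base deletion: %s", name))
    return(tibble(kind = "deletion", pos = p1, end = p2,
                  ref_allele = str_to_upper(m[1, 4]), alt_allele = ""))
  }
  m <- str_match(name, "^r\\.(\\d+)-(\\d+)([acgt])([acgt])<$")
  if (!is.na(m[1, 1])) {
    p1 <- as.integer(m[1, 2]); p2 <- as.integer(m[1, 3])
    if (p2 <= p1 + 1L) abort(sprintf("Malformed range deletion: %s", name))
    ref <- paste0(str_to_upper(m[1, 4]),
                  strrep("N", p2 - p1 - 1L),
                  str_to_upper(m[1, 5]))
    return(tibble(kind = "deletion", pos = p1, end = p2,
                  ref_allele = ref, alt_allele = ""))
  }
  abort(sprintf("Cannot parse RNA variant name: %s", name))
}

#' Per-site recurrence summary across tissues
#'
#' Tabulates, for one gene, how many clones of each tissue carry each
#' alternative at each reference site, mirroring per-site editing maps
#' where an entry such as "3^A" means three clones of the tissue switched
#' to A at that position. Also reports, per site, the number of distinct
#' tissues in which it was hit, so sites private to one tissue versus
#' shared between two or more can be tallied.
#'
#' @param events Event tibble for one gene.
#' @param clones_per_tissue Optional named integer vector of clone counts
#'   (used only for the coverage attribute).
#' @return Tibble with `pos`, `tissue`, `kind`, `alt_allele`, `n_clones`,
#'   `n_tissues_at_site`.
#' @export
summarize_sites <- function(events, clones_per_tissue = NULL) {
  if (nrow(events) == 0L) {
    return(tibble(pos = integer(), tissue = character(), kind = character(),
                  alt_allele = character(), n_clones = integer(),
                  n_tissues_at_site = integer()))
  }
  if (length(unique(events$gene_id)) > 1L) {
    abort("`summarize_sites()` expects events from a single gene.")
  }
  per <- events |>
    count(.data$pos, .data$tissue, .data$kind, .data$alt_allele,
          name = "n_clones")
  site_tissues <- events |>
    distinct(.data$pos, .data$tissue) |>
    count(.data$pos, name = "n_tissues_at_site")
  out <- left_join(per, site_tissues, by = "pos") |>
    arrange(.data$pos, .data$tissue)
  if (!is.null(clones_per_tissue)) {
    attr(out, "clones_per_tissue") <- clones_per_tissue
  }
  out
}
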