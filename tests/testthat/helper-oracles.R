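# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: alignment scores come from a memoised three-state
# recursion written here (not Biostrings), clustering from a naive
# agglomeration loop (not stats::hclust), translation from
# Biostrings::translate (not the package's codon walk), and effect
# categories from a direct re-translation rule-out.

# Optimal global affine-gap score by exhaustive three-state recursion
# (memoised); gap of length k costs gap_open + k * gap_extend.
oracle_align_score <- function(a, b, params = align_params()) {
  na <- nchar(a); nb <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  memo <- array(NA_real_, dim = c(na + 1L, nb + 1L, 3L))
  states <- c(M = 1L, D = 2L, I = 3L)
  rec <- function(i, j, prev) {
    if (i > na && j > nb) return(0)
    m <- memo[i, j, prev]
    if (!is.na(m)) return(m)
    best <- -Inf
    if (i <= na && j <= nb) {
      s <- if (av[i] == bv[j]) params$match else params$mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, states["M"]))
    }
    if (i <= na) {
      pen <- params$gap_extend + if (prev == states["D"]) 0 else params$gap_open
      best <- max(best, pen + rec(i + 1L, j, states["D"]))
    }
    if (j <= nb) {
      pen <- params$gap_extend + if (prev == states["I"]) 0 else params$gap_open
      best <- max(best, pen + rec(i, j + 1L, states["I"]))
    }
    memo[i, j, prev] <<- best
    best
  }
  rec(1L, 1L, states["M"])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Naive complete-linkage agglomeration: repeatedly merge the cluster pair
# with the smallest maximum pairwise distance. Returns merge heights and,
# per step, the sorted leaf set of the newly formed cluster.
oracle_complete_linkage <- function(m) {
  d <- as.matrix(dist(m, method = "euclidean"))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  members <- list()
  while (length(clusters) > 1L) {
    best_h <- Inf; bi <- NA; bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        h <- max(d[clusters[[i]], clusters[[j]], drop = FALSE])
        if (h < best_h) { best_h <- h; bi <- i; bj <- j }
      }
    }
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    heights <- c(heights, best_h)
    members[[length(members) + 1L]] <- merged
    clusters[[bj]] <- merged
    clusters[[bi]] <- NULL
  }
  list(heights = heights, members = members)
}

# Leaf sets formed at each hclust merge step, for comparison with the
# oracle above.
hclust_step_members <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    grab <- function(id) if (id < 0) -id else sets[[id]]
    sets[[k]] <- sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2])))
  }
  sets
}

# Independent translation: Biostrings' translator on whole codon blocks.
oracle_translate <- function(seq, offset = 0L) {
  body <- substr(seq, offset + 1L, nchar(seq))
  n <- (nchar(body) %/% 3L) * 3L
  if (n == 0L) return(list(protein = "", stop_found = FALSE))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(body, 1L, n)), no.init.codon = TRUE))
  star <- regexpr("*", aa, fixed = TRUE)
  if (star > 0L) {
    list(protein = substr(aa, 1L, star - 1L), stop_found = TRUE)
  } else {
    list(protein = aa, stop_found = FALSE)
  }
}

# Direct rule application on independently translated proteins.
oracle_classify <- function(ref, variant_cdna) {
  nat <- oracle_translate(ref$cdna, ref$orf_offset)$protein
  vp <- oracle_translate(variant_cdna, ref$orf_offset)$protein
  net <- nchar(variant_cdna) - nchar(ref$cdna)
  if (net %% 3L != 0L) {
    return(if (nchar(vp) > nchar(nat)) "frameshift_late" else "frameshift_early")
  }
  if (identical(vp, nat)) return("silent")
  if (nchar(vp) < nchar(nat) + net / 3L) return("stop_gain")
  if (net < 0L) return("motif_deletion")
  "missense"
}

# Random single-event variant of a transcript, away from the edges.
random_single_event <- function(ref) {
  L <- nchar(ref$cdna)
  kind <- sample(c("substitution", "insertion", "deletion"), 1L,
                 prob = c(0.5, 0.2, 0.3))
  pos <- sample(10:(L - 30L), 1L)
  if (kind == "substitution") {
    old <- substr(ref$cdna, pos, pos)
    tibble::tibble(kind = kind, pos = pos, end = pos, ref_allele = old,
                   alt_allele = sample(setdiff(c("A", "C", "G", "T"), old), 1L))
  } else if (kind == "insertion") {
    tibble::tibble(kind = kind, pos = pos, end = pos, ref_allele = "",
                   alt_allele = random_dna(sample(1:4, 1L)))
  } else {
    len <- sample(1:12, 1L)
    tibble::tibble(kind = kind, pos = pos, end = pos + len - 1L,
                   ref_allele = substr(ref$cdna, pos, pos + len - 1L),
                   alt_allele = "")
  }
}

# A reference transcript for caller tests that needs no reading frame:
# every base differs from its neighbours, so all indels are canonical.
patterned_ref <- function(n = 400L) {
  substr(strrep("ACGT", ceiling(n / 4)), 1L, n)
}

consensus_of <- function(ref) {
  structure(list(consensus = ref, variable_positions = integer(0)),
            class = "consensus_result")
}
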