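# Global affine-gap alignment of clones against the coding reference, gap
# left-normalisation, and the gDNA consensus. Clones are near-identical
# amplicons of one reference, so pairwise global alignment followed by
# columnwise comparison replaces a multiple alignment.

#' Alignment scoring parameters
#'
#' Affine-gap scoring: a gap of length k costs `gap_open + k * gap_extend`
#' (both penalties stored as negative numbers). The defaults discourage
#' spurious indels in near-identical pairs.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (<= 0).
#' @param gap_open Gap-opening penalty (<= 0), charged once per gap run.
#' @param gap_extend Gap-extension penalty (<= 0), charged per gapped base.
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 2L, mismatch = -2L, gap_open = -6L,
                         gap_extend = -1L) {
  if (match <= 0) abort("`match` must be positive.")
  if (mismatch > 0 || gap_open > 0 || gap_extend > 0) {
    abort("Penalties must be <= 0.")
  }
  if (gap_open > gap_extend) abort("`gap_open` must be <= `gap_extend`.")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_params")
}

new_aligned_pair <- function(ref_row, query_row, score) {
  stopifnot(str_length(ref_row) == str_length(query_row))
  structure(list(ref_row = ref_row, query_row = query_row, score = score),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> %d columns, score %g\n",
              str_length(x$ref_row), x$score))
  cat(" ref  ", x$ref_row, "\n query", x$query_row, "\n")
  invisible(x)
}

#' Global alignment of a clone against the reference
#'
#' Optimal global alignment under affine-gap scoring (three-state dynamic
#' programming), followed by [left_normalize_gaps()] so that every gap run
#' sits at its leftmost score-equivalent position. Canonical gap placement
#' makes downstream event positions deterministic.
#'
#' @param ref,query Nucleotide strings over `{A,C,G,T}`.
#' @param params An [align_params()] object.
#' @return An `aligned_pair`: `ref_row`/`query_row` (equal-length strings
#'   over `{A,C,G,T,-}`, no gap/gap column) and `score`.
#' @export
global_align <- function(ref, query, params = align_params()) {
  check_dna(ref, "ref"); check_dna(query, "query")
  stopifnot(inherits(params, "align_params"))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ref),
    subject = Biostrings::DNAString(query),
    type = "global", substitutionMatrix = mat,
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend)
  pair <- new_aligned_pair(
    as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)),
    Biostrings::score(aln))
  left_normalize_gaps(pair)
}

#' Left-normalise gap runs in an alignment
#'
#' Shifts every gap run to its leftmost score-equivalent position: a run of
#' gaps opposite bases `b[i..j]` can move one column left whenever
#' `b[i-1] == b[j]` and the preceding column is gap-free. Idempotent;
#' preserves the score and the multiset of edit operations. This is the
#' same convention used to left-align indels in variant files, and it is
#' what makes a deletion inside a repeat tract report one canonical
#' position.
#'
#' @param pair An `aligned_pair`.
#' @return An `aligned_pair` with canonical gap placement.
#' @export
left_normalize_gaps <- function(pair) {
  stopifnot(inherits(pair, "aligned_pair"))
  ref <- str_split(pair$ref_row, "")[[1L]]
  qry <- str_split(pair$query_row, "")[[1L]]
  # Shifting a gap run left by one column moves the base just before the
  # run (in the gapped row) to the run's end; the opposite row is
  # untouched. When the opposite row carries the same base at both ends of
  # the window the score is unchanged whatever the displaced base was.
  qry <- shift_gap_runs_left(qry, ref)   # deletions (gaps in query row)
  ref <- shift_gap_runs_left(ref, qry)   # insertions (gaps in ref row)
  new_aligned_pair(paste(ref, collapse = ""), paste(qry, collapse = ""),
                   pair$score)
}

shift_gap_runs_left <- function(gapped, solid) {
  n <- length(gapped)
  i <- 1L
  while (i <= n) {
    if (gapped[i] == "-") {
      j <- i
      while (j < n && gapped[j + 1L] == "-") j <- j + 1L
      while (i > 1L && gapped[i - 1L] != "-" && solid[i - 1L] != "-" &&
             solid[i - 1L] == solid[j]) {
        gapped[j] <- gapped[i - 1L]
        gapped[i - 1L] <- "-"
        i <- i - 1L
        j <- j - 1L
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  gapped
}

#' Build the genomic consensus from gDNA clones
#'
#' Aligns each gDNA clone to the reference and takes the per-column
#' majority base. Any column where the clones disagree among themselves is
#' recorded in `variable_positions` (possible allelic variation) and is
#' later masked from RDD calling. Ties are broken toward the reference
#' base.
#'
#' @param ref Reference cDNA string (the spliced coding amplicon).
#' @param gdna_clones Character vector (or tibble with a `seq` column) of
#'   gDNA clone sequences; at least one.
#' @param params [align_params()].
#' @return A list of class `consensus_result`: `consensus` (string, same
#'   length as `ref`) and `variable_positions` (sorted unique 1-based
#'   positions).
#' @export
build_gdna_consensus <- function(ref, gdna_clones, params = align_params()) {
  if (is.data.frame(gdna_clones)) gdna_clones <- gdna_clones$seq
  if (length(gdna_clones) < 1L) abort("Need at least one gDNA clone.")
  check_dna(ref, "ref")
  L <- str_length(ref)
  ref_chars <- str_split(ref, "")[[1L]]
  votes <- matrix("", nrow = length(gdna_clones), ncol = L)
  for (k in seq_along(gdna_clones)) {
    pair <- global_align(ref, gdna_clones[k], params)
    rr <- str_split(pair$ref_row, "")[[1L]]
    qq <- str_split(pair$query_row, "")[[1L]]
    pos <- cumsum(rr != "-")
    keep <- rr != "-"
    votes[k, pos[keep]] <- qq[keep]   # "-" where the clone has a deletion
  }
  consensus <- character(L)
  variable <- logical(L)
  for (p in seq_len(L)) {
    v <- votes[, p]
    variable[p] <- length(unique(v)) > 1L || any(v == "-")
    bases <- v[v %in% c("A", "C", "G", "T")]
    if (!length(bases)) {
      consensus[p] <- ref_chars[p]
      next
    }
    tab <- table(bases)
    best <- names(tab)[tab == max(tab)]
    consensus[p] <- if (ref_chars[p] %in% best) ref_chars[p] else best[1L]
  }
  structure(list(consensus = paste(consensus, collapse = ""),
                 variable_positions = which(variable)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d bp, %d variable position(s)\n",
              str_length(x$consensus), length(x$variable_positions)))
  invisible(x)
}
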