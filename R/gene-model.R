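# Gene models (genomic exon structure on a scaffold) and transcript
# references (the spliced coding amplicon each clone is compared against).

#' Construct a gene model
#'
#' A gene model ties an exon structure (1-based inclusive coordinates on a
#' scaffold) to the scaffold sequence. Exons must be sorted, non-overlapping
#' and within bounds.
#'
#' @param gene_id,scaffold_id Labels.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame (or tibble) with integer columns `start`, `end`.
#' @param scaffold_seq Scaffold nucleotide string over `{A,C,G,T}`.
#' @param repeats Optional annotation tibble (`start`, `end`, `label`);
#'   carried through untouched.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, scaffold_id, strand, exons, scaffold_seq,
                       repeats = NULL) {
  check_dna(scaffold_seq, "scaffold_seq")
  exons <- as_tibble(exons)
  if (!all(c("start", "end") %in% names(exons)) || nrow(exons) < 1L) {
    abort("`exons` needs columns start/end and at least one row.")
  }
  exons <- mutate(exons, start = as.integer(.data$start),
                  end = as.integer(.data$end))
  if (any(exons$start > exons$end)) abort("Exon start > end.")
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    abort("Exons must be sorted and non-overlapping.")
  }
  if (min(exons$start) < 1L || max(exons$end) > str_length(scaffold_seq)) {
    abort("Exon outside scaffold bounds.")
  }
  if (!strand %in% c("+", "-")) abort("`strand` must be '+' or '-'.")
  structure(
    list(gene_id = gene_id, scaffold_id = scaffold_id, strand = strand,
         exons = exons, scaffold_seq = scaffold_seq, repeats = repeats),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s(%s): %d exon(s), scaffold %d bp\n",
              x$gene_id, x$scaffold_id, x$strand, nrow(x$exons),
              str_length(x$scaffold_seq)))
  invisible(x)
}

#' Splice a gene model into its transcript sequence
#'
#' Concatenates exon subsequences in transcript order; on the `-` strand the
#' concatenation is reverse-complemented so the result is always the coding
#' strand 5'->3'.
#'
#' @param model A [gene_model()].
#' @return Nucleotide string of length `sum(end - start + 1)`.
#' @examples
#' m <- gene_model("g", "s", "+", data.frame(start = c(1, 7), end = c(3, 9)),
#'                 "ATGCCCAAATAG")
#' splice_transcript(m) # "ATGAAA"
#' @export
splice_transcript <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  pieces <- str_sub(model$scaffold_seq, model$exons$start, model$exons$end)
  out <- paste(pieces, collapse = "")
  if (model$strand == "-") out <- revcomp(out)
  out
}

#' Construct a transcript reference
#'
#' The spliced coding amplicon a clone set is compared against, together
#' with its reading frame. `orf_offset` is the number of bases before codon
#' 1 and is an explicit per-gene input: amplicons may start at the initial
#' ATG or at the first codon of the mature protein, so the frame cannot be
#' inferred from coordinates alone. All reported positions downstream are
#' 1-based on this cDNA.
#'
#' @param gene_id Label.
#' @param cdna Amplicon nucleotide string (coding strand).
#' @param orf_offset Bases before codon 1 (>= 0).
#' @return Object of class `transcript_ref` with fields `gene_id`, `cdna`,
#'   `orf_offset`, `native_protein`, `native_len_aa`, `native_stop_base`
#'   (1-based first base of the native stop codon).
#' @export
transcript_ref <- function(gene_id, cdna, orf_offset = 0L) {
  check_dna(cdna, "cdna")
  orf_offset <- as.integer(orf_offset)
  if (orf_offset < 0L) abort("`orf_offset` must be >= 0.")
  if (str_length(cdna) < orf_offset + 3L) {
    abort("`cdna` must hold at least one codon past `orf_offset`.")
  }
  tr <- translate_orf(cdna, orf_offset)
  if (!tr$stop_found) {
    abort(sprintf("No stop codon in frame for %s; check `orf_offset`.", gene_id))
  }
  n_aa <- str_length(tr$protein)
  structure(
    list(gene_id = gene_id, cdna = cdna, orf_offset = orf_offset,
         native_protein = tr$protein, native_len_aa = n_aa,
         native_stop_base = orf_offset + 3L * n_aa + 1L),
    class = "transcript_ref"
  )
}

#' @export
print.transcript_ref <- function(x, ...) {
  cat(sprintf("<transcript_ref> %s: %d bp cDNA, ORF offset %d, %d aa\n",
              x$gene_id, str_length(x$cdna), x$orf_offset, x$native_len_aa))
  invisible(x)
}
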