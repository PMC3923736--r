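# Deterministic synthetic toy transcripts for worked examples and tests:
# small ORFs with chosen residues at chosen positions, and a hand-built
# frameshift scenario whose single-base deletion creates a late stop.

# One fixed codon per amino acid (alphabetically first among its codons).
aa_to_codon <- function() {
  code <- codon_table()
  sense <- sort(names(code)[code != "*"])
  tapply(sense, unname(code[sense]), function(x) x[1L])
}

#' Build a deterministic toy transcript
#'
#' Returns a [transcript_ref()] encoding `n_codons` residues: ATG first,
#' a fixed non-repeating filler (Glu/Ala/Lys cycling) elsewhere, with any
#' requested residues placed at their positions, then a TAA stop. Useful
#' for engineering worked-example variants (e.g. an in-frame deletion of
#' a named motif).
#'
#' @param n_codons Number of residues in the native protein.
#' @param residues Optional named character vector: positions (names,
#'   coercible to integer) to 1-letter residue codes, e.g.
#'   `c("45" = "D", "48" = "P")`.
#' @param gene_id Label.
#' @param orf_offset 5' bases before codon 1 (filled with a fixed
#'   pattern).
#' @return A [transcript_ref()].
#' @examples
#' ref <- make_toy_transcript(104, c("45" = "D", "46" = "K",
#'                                   "47" = "I", "48" = "P"))
#' ref$native_len_aa
#' @export
make_toy_transcript <- function(n_codons, residues = NULL,
                                gene_id = "toy", orf_offset = 0L) {
  if (n_codons < 2L) abort("Need at least 2 codons.")
  filler <- c("GAA", "GCT", "AAG")  # Glu, Ala, Lys
  codons <- c("ATG", rep_len(filler, n_codons)[-1L])
  if (!is.null(residues)) {
    tab <- aa_to_codon()
    pos <- as.integer(names(residues))
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > n_codons)) {
      abort("Residue positions must be within 1..n_codons.")
    }
    codons[pos] <- unname(tab[unlist(residues)])
    if (anyNA(codons)) abort("Unknown residue code in `residues`.")
  }
  utr5 <- if (orf_offset > 0L) {
    paste(rep_len(c("C", "A", "G", "T"), orf_offset), collapse = "")
  } else {
    ""
  }
  transcript_ref(gene_id, paste0(utr5, paste(codons, collapse = ""), "TAA"),
                 orf_offset)
}

#' Synthetic late-stop frameshift scenario
#'
#' A hand-constructed 111-codon transcript (His at residue 87) in which
#' deleting the single base at cDNA position 259 - the first base of
#' codon 87 - shifts the reading frame so translation runs 18 codons past
#' the native stop before terminating, i.e. a `fsHis87*l` variant of 129
#' residues. The downstream sequence is engineered so the native frame
#' stops at codon 112 while the shifted frame stays open for exactly 43
#' codons from residue 87. This is a synthetic stand-in for a
#' pheromone-gland clone carrying such a deletion; only its frame
#' arithmetic, not its biological sequence, is meaningful.
#'
#' @return List with `ref` (the [transcript_ref()]), `event` (one-row
#'   deletion event tibble at position 259) and `expected` (list of the
#'   designed outcomes: category, name, residue count).
#' @export
frameshift_demo_transcript <- function() {
  filler <- c("GAA", "GCT", "AAG")
  prefix <- c("ATG", rep_len(filler, 86L)[-1L])       # codons 1..86
  s_codons <- c("ATA",                                 # shifted codon 87: Ile
                rep("GCA", 23L), "ACT", "AAA",         # keeps both frames open
                rep("GCA", 17L), "TAA")                # shifted stop
  s <- paste(s_codons, collapse = "")
  stopifnot(str_length(s) == 132L)
  cdna <- paste0(paste(prefix, collapse = ""), "C", s)
  ref <- transcript_ref("toyCSP1", cdna, 0L)
  stopifnot(ref$native_len_aa == 111L,
            str_sub(ref$native_protein, 87L, 87L) == "H")
  event <- tibble(clone_id = "demo-PG-01", gene_id = "toyCSP1",
                  tissue = "pheromone_gland", individual = "F1",
                  kind = "deletion", pos = 259L, end = 259L,
                  ref_allele = "C", alt_allele = "",
                  rna_name = "r.259c<")
  list(ref = ref, event = event,
       expected = list(category = "frameshift_late",
                       protein_name = "fsHis87*l", reported_len_aa = 129L))
}
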