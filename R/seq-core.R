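# Sequence primitives shared by every stage: codon translation with explicit
# stop semantics and average-mass protein weights.

# Standard genetic code, taken from Biostrings at load time so the table is
# the canonical one (64 codons, 3 stops; "*" marks stop).
codon_table <- function() {
  Biostrings::GENETIC_CODE
}

# One- to three-letter residue codes (IUPAC).
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

# Average (not monoisotopic) residue masses in Da; protein mass = sum +
# one water. Average masses match the kDa style used for whole proteins.
AA_MASS_AVG <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

check_dna <- function(seq, arg = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("`%s` must be a single string.", arg))
  }
  if (str_detect(seq, "[^ACGT]")) {
    abort(sprintf("`%s` contains characters outside {A,C,G,T}; ambiguity codes are not accepted.", arg))
  }
  invisible(seq)
}

#' Translate an open reading frame with explicit stop semantics
#'
#' Translates consecutive codons of `seq` starting after `offset` bases,
#' stopping before the first stop codon. A trailing partial codon is
#' ignored. This is the reading-frame engine behind effect classification,
#' where frameshifted transcripts routinely run past (or short of) the
#' native stop.
#'
#' @param seq Nucleotide string over `{A,C,G,T}` (coding strand, 5'->3').
#' @param offset Number of bases before the first codon (>= 0).
#' @return A list with `protein` (amino-acid string, possibly empty) and
#'   `stop_found` (`TRUE` iff a stop codon terminated translation).
#' @examples
#' translate_orf("ATGTAA", 0) # M, stop found
#' translate_orf("ATG", 0)    # M, no stop
#' @export
translate_orf <- function(seq, offset = 0L) {
  check_dna(seq)
  offset <- as.integer(offset)
  if (offset < 0L || offset >= str_length(seq)) {
    abort("`offset` must satisfy 0 <= offset < nchar(seq).")
  }
  code <- codon_table()
  body <- str_sub(seq, offset + 1L)
  n_codon <- str_length(body) %/% 3L
  if (n_codon == 0L) {
    return(list(protein = "", stop_found = FALSE))
  }
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- str_sub(body, starts, starts + 2L)
  aas <- unname(code[codons])
  stop_at <- which(aas == "*")
  if (length(stop_at)) {
    list(protein = paste(aas[seq_len(stop_at[1L] - 1L)], collapse = ""),
         stop_found = TRUE)
  } else {
    list(protein = paste(aas, collapse = ""), stop_found = FALSE)
  }
}

#' Average molecular mass of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da), reported in
#' kDa. Matches the convention used when whole-protein weights are quoted
#' alongside variant tables.
#'
#' @param protein Amino-acid string over the 20 standard residues.
#' @param digits Decimal places for the kDa figure (default 2).
#' @return Mass in kDa (numeric scalar).
#' @examples
#' protein_mass("G")  # 0.08 kDa (75.07 Da)
#' @export
protein_mass <- function(protein, digits = 2L) {
  if (!is.character(protein) || length(protein) != 1L || is.na(protein) ||
      !nzchar(protein)) {
    abort("`protein` must be a non-empty string.")
  }
  aas <- str_split(protein, "")[[1L]]
  bad <- setdiff(unique(aas), names(AA_MASS_AVG))
  if (length(bad)) {
    abort(sprintf("Unknown residue(s): %s", paste(bad, collapse = ", ")))
  }
  round((sum(AA_MASS_AVG[aas]) + WATER_MASS) / 1000, digits)
}

# Internal: exact mass in Da (no rounding), for tests and additivity checks.
protein_mass_da <- function(protein) {
  aas <- str_split(protein, "")[[1L]]
  sum(AA_MASS_AVG[aas]) + WATER_MASS
}

# Three-letter code for a single one-letter residue.
aa3 <- function(aa) {
  out <- AA_THREE[aa]
  if (anyNA(out)) abort(sprintf("Unknown residue: %s", aa))
  unname(out)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
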