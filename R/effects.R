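# Variant transcript reconstruction, frameshift-aware re-translation and
# classification into the five protein-effect categories, with protein
# nomenclature, residue counts and masses.

#' Apply events to a reference cDNA
#'
#' Rebuilds a clone's variant transcript from its called (or planted)
#' events: substitutions replace bases in place, deletions remove their
#' reference span, insertions add bases after their anchor. Events must not
#' overlap; they are applied right-to-left so positions never shift.
#'
#' @param ref A [transcript_ref()] or a plain cDNA string.
#' @param events Event tibble with `kind`, `pos`, `ref_allele`,
#'   `alt_allele` (positions 1-based on `ref`).
#' @return Variant cDNA string of length
#'   `nchar(ref) - deleted + inserted`.
#' @export
apply_events_to_cdna <- function(ref, events) {
  cdna <- if (inherits(ref, "transcript_ref")) ref$cdna else ref
  check_dna(cdna, "ref")
  if (nrow(events) == 0L) return(cdna)
  ev <- arrange(events, .data$pos)
  span_end <- ev$pos + pmax(str_length(ev$ref_allele) - 1L, 0L)
  if (any(ev$pos < ifelse(ev$kind == "insertion", 0L, 1L)) ||
      any(span_end > str_length(cdna))) {
    abort("Event position outside the reference.")
  }
  if (nrow(ev) > 1L) {
    # footprints: insertions occupy the boundary after `pos` only
    starts <- ifelse(ev$kind == "insertion", ev$pos + 0.5, ev$pos)
    ends <- ifelse(ev$kind == "insertion", ev$pos + 0.5, span_end)
    if (any(starts[-1L] <= ends[-nrow(ev)])) {
      abort("Overlapping events cannot be applied to one transcript.")
    }
  }
  for (k in rev(seq_len(nrow(ev)))) {
    p <- ev$pos[k]
    if (ev$kind[k] == "substitution") {
      str_sub(cdna, p, p) <- ev$alt_allele[k]
    } else if (ev$kind[k] == "deletion") {
      str_sub(cdna, p, p + str_length(ev$ref_allele[k]) - 1L) <- ""
    } else if (ev$kind[k] == "insertion") {
      cdna <- paste0(str_sub(cdna, 1L, p), ev$alt_allele[k],
                     str_sub(cdna, p + 1L))
    } else {
      abort(sprintf("Unknown event kind: %s", ev$kind[k]))
    }
  }
  cdna
}

#' Classify the protein-level effect of a variant transcript
#'
#' Re-translates the variant cDNA in the native reading frame and assigns
#' exactly one of the five effect categories observed for clone-level
#' RDDs, plus `silent`:
#'
#' * `silent` - variant protein identical to the native protein;
#' * `missense` - in-frame change, same termination behaviour, at least
#'   one residue replaced (in-frame insertions are also reported here);
#' * `stop_gain` - an in-frame change converts a sense codon to a stop,
#'   truncating the C-terminus;
#' * `frameshift_early` / `frameshift_late` - a net indel not divisible by
#'   3 shifts the frame; early if the variant protein is shorter than the
#'   native protein, late if longer (the frame runs past the native stop);
#' * `motif_deletion` - an in-frame deletion removes whole codons,
#'   excising an internal amino-acid motif.
#'
#' @param ref A [transcript_ref()].
#' @param variant_cdna Variant transcript string (e.g. from
#'   [apply_events_to_cdna()]).
#' @param stop_gain_convention `"stop_position"` (default) reports, for
#'   stop-gain variants, the index of the residue mutated to stop, matching
#'   the tabulation style in clone variant tables; `"length"` reports the
#'   strict residue count of the truncated protein.
#' @param signal_peptide_end Optional residue index; variants whose first
#'   affected residue falls at or before it are flagged
#'   (`in_signal_peptide`) but still reported.
#' @return One-row tibble: `category`, `first_affected` (residue index),
#'   `first_affected_aa` (native residue, 3-letter), `protein_name`,
#'   `variant_protein`, `reported_len_aa`, `mass_kda`, `stop_found`,
#'   `aborted`, `in_signal_peptide`.
#' @export
classify_effect <- function(ref, variant_cdna,
                            stop_gain_convention = c("stop_position", "length"),
                            signal_peptide_end = NULL) {
  stopifnot(inherits(ref, "transcript_ref"))
  convention <- match.arg(stop_gain_convention)
  check_dna(variant_cdna, "variant_cdna")
  native <- ref$native_protein
  n_nat <- ref$native_len_aa
  tr <- if (ref$orf_offset < str_length(variant_cdna)) {
    translate_orf(variant_cdna, ref$orf_offset)
  } else {
    list(protein = "", stop_found = FALSE)
  }
  vp <- tr$protein
  n_var <- str_length(vp)
  net <- str_length(variant_cdna) - str_length(ref$cdna)
  aborted <- n_var == 0L

  first_diff <- first_difference(native, vp)

  if (identical(vp, native) && net == 0L) {
    category <- "silent"
  } else if (net %% 3L != 0L) {
    category <- if (n_var > n_nat) "frameshift_late" else "frameshift_early"
  } else {
    expected_len <- n_nat + net %/% 3L
    if (n_var < expected_len) {
      category <- "stop_gain"
    } else if (net < 0L) {
      category <- "motif_deletion"
    } else if (identical(vp, native)) {
      category <- "silent"   # e.g. compensating in-frame events
    } else {
      category <- "missense"
    }
  }

  nm <- effect_protein_name(category, native, vp, net, first_diff)
  reported_len <- if (aborted) {
    0L
  } else if (category == "stop_gain" && convention == "stop_position") {
    n_var + 1L
  } else {
    n_var
  }
  mass <- if (aborted) NA_real_ else protein_mass(vp)
  first_aa <- if (!is.na(first_diff) && first_diff <= n_nat) {
    aa3(str_sub(native, first_diff, first_diff))
  } else {
    NA_character_
  }
  tibble(
    category = category,
    first_affected = first_diff,
    first_affected_aa = first_aa,
    protein_name = nm,
    variant_protein = vp,
    reported_len_aa = as.integer(reported_len),
    mass_kda = mass,
    stop_found = tr$stop_found,
    aborted = aborted,
    in_signal_peptide = !is.null(signal_peptide_end) && !is.na(first_diff) &&
      first_diff <= signal_peptide_end
  )
}

# Index of the first residue where the two proteins differ; NA if the
# shorter is a prefix of the longer and lengths are equal (identical).
first_difference <- function(a, b) {
  if (identical(a, b)) return(NA_integer_)
  la <- str_length(a); lb <- str_length(b)
  n <- min(la, lb)
  if (n > 0L) {
    av <- str_split(a, "")[[1L]][seq_len(n)]
    bv <- str_split(b, "")[[1L]][seq_len(n)]
    d <- which(av != bv)
    if (length(d)) return(d[1L])
  }
  n + 1L
}

# Internal: protein-level name for a classified variant.
effect_protein_name <- function(category, native, vp, net, first_diff) {
  at <- function(p) aa3(str_sub(native, p, p))
  switch(
    category,
    silent = "silent",
    missense = {
      p <- first_diff
      # past the native C-terminus = a destroyed stop codon (read-through)
      old_aa <- if (p <= str_length(native)) at(p) else "Ter"
      new_aa <- if (p <= str_length(vp)) aa3(str_sub(vp, p, p)) else "del"
      sprintf("pmut%s%d%s", old_aa, p, new_aa)
    },
    stop_gain = {
      p <- str_length(vp) + 1L
      sprintf("pmut%s%d*", at(p), p)
    },
    frameshift_early = sprintf("fs%s%d*e", at(first_diff), first_diff),
    frameshift_late = sprintf("fs%s%d*l", at(first_diff), first_diff),
    motif_deletion = {
      k <- -net %/% 3L
      start <- first_diff
      end <- start + k - 1L
      sprintf("dele%s%d-%s%d", at(start), start, at(end), end)
    },
    abort(sprintf("Unknown category: %s", category))
  )
}

#' Protein-level name for a classified variant
#'
#' Regenerates the nomenclature string from a classification row:
#' stop-gain `pmutLys96*`, frameshift `fsHis87*l` / `fsPro90*e` (first
#' affected residue; `*e`/`*l` for an early/late stop), in-frame motif
#' deletion `deleAsp45-Pro48`, missense `pmutTyr23Phe`, and `silent`.
#'
#' @param variant One-row tibble from [classify_effect()].
#' @return Name string.
#' @export
protein_name <- function(variant) {
  v <- as.list(variant)
  if (is.null(v$protein_name)) abort("Not a classified variant.")
  v$protein_name
}

#' Residue count and mass under a reporting convention
#'
#' Residues before the first stop for frameshift, deletion, silent and
#' missense variants; for stop-gain variants the default
#' `"stop_position"` convention reports the index of the residue mutated
#' to stop (one more than the strict residue count), while `"length"`
#' reports the strict count. Mass is the average molecular weight of the
#' translated variant protein in kDa.
#'
#' @param variant_protein Amino-acid string (may be empty).
#' @param category Effect category string.
#' @param convention `"stop_position"` or `"length"`.
#' @return One-row tibble with `reported_len_aa`, `mass_kda`, `aborted`.
#' @export
variant_metrics <- function(variant_protein, category = "missense",
                            convention = c("stop_position", "length")) {
  convention <- match.arg(convention)
  n <- str_length(variant_protein)
  if (n == 0L) {
    return(tibble(reported_len_aa = 0L, mass_kda = NA_real_, aborted = TRUE))
  }
  len <- if (category == "stop_gain" && convention == "stop_position") {
    n + 1L
  } else {
    n
  }
  tibble(reported_len_aa = as.integer(len),
         mass_kda = protein_mass(variant_protein), aborted = FALSE)
}

#' Classify every clone in an event table
#'
#' Groups events by clone, rebuilds each variant transcript, and runs
#' [classify_effect()] once per clone (multiple events in one clone are
#' classified jointly from the full variant transcript). Clones without
#' events are reported as `silent` when listed in `clones`.
#'
#' @param ref A [transcript_ref()].
#' @param events Event tibble (one gene).
#' @param clones Optional clone metadata tibble (`clone_id`, `tissue`,
#'   `individual`, `source`); cDNA clones with no events are then included
#'   as silent rows.
#' @inheritParams classify_effect
#' @return Tibble with one row per clone: metadata, comma-joined
#'   `rna_names`, and the classification columns.
#' @export
classify_clones <- function(ref, events, clones = NULL,
                            stop_gain_convention = "stop_position",
                            signal_peptide_end = NULL) {
  stopifnot(inherits(ref, "transcript_ref"))
  ids <- unique(events$clone_id)
  rows <- map(ids, function(id) {
    ev <- filter(events, .data$clone_id == id)
    variant <- apply_events_to_cdna(ref, ev)
    cls <- classify_effect(ref, variant,
                           stop_gain_convention = stop_gain_convention,
                           signal_peptide_end = signal_peptide_end)
    bind_cols(
      tibble(clone_id = id, gene_id = ref$gene_id,
             tissue = ev$tissue[1L], individual = ev$individual[1L],
             rna_names = paste(ev$rna_name, collapse = ",")),
      cls)
  })
  out <- list_rbind(rows)
  if (!is.null(clones)) {
    quiet <- clones |>
      filter(.data$source == "cDNA", !.data$clone_id %in% ids)
    if (nrow(quiet)) {
      silent_cls <- classify_effect(ref, ref$cdna,
                                    stop_gain_convention = stop_gain_convention,
                                    signal_peptide_end = signal_peptide_end)
      silent_rows <- quiet |>
        select("clone_id", "tissue", "individual") |>
        mutate(gene_id = ref$gene_id, rna_names = "", .after = "clone_id")
      out <- bind_rows(out, bind_cols(silent_rows, silent_cls))
    }
  }
  if (is.null(out)) out <- tibble()
  arrange(out, .data$clone_id)
}
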