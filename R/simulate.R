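# Seeded simulator for the sequencing design the pipeline analyses:
# per-tissue cDNA clone sets carrying planted RDDs over simulated gene
# models, with a ground-truth manifest for recovery tests. gDNA clones are
# mutation-free copies of the reference, matching the observation that
# genomic clones show no variation.

sense_codons <- function() {
  code <- codon_table()
  names(code)[code != "*"]
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

SUB_CLASSES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                 "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

empty_manifest <- function() {
  tibble(clone_id = character(), gene_id = character(), tissue = character(),
         kind = character(), pos = integer(), end = integer(),
         ref_allele = character(), alt_allele = character())
}

#' Simulation configuration
#'
#' Defaults reproduce the study design the simulator emulates: five
#' tissues (antennae, legs, head, wings, pheromone gland) from a handful
#' of individuals, 10-20 near-identical Sanger clones per tissue per gene,
#' a Poisson RDD load per clone that is about three-fold elevated in the
#' pheromone gland, an A>G-dominated 12-class substitution spectrum
#' (weights proportional to the observed class counts, with small equal
#' weights for the unreported minor classes), and rare single-base
#' insertions and 1-12-base deletions.
#'
#' @param n_genes Number of genes to simulate.
#' @param exons_per_gene Integer range `c(min, max)` of exon counts
#'   (1 exon = intronless).
#' @param exon_len,intron_len Base-count ranges `c(min, max)`.
#' @param tissues Named numeric vector: per-clone RDD rate (Poisson lambda)
#'   per tissue.
#' @param pheromone_gland_multiplier Factor (>= 1) applied to the lambda of
#'   `pheromone_tissue`.
#' @param pheromone_tissue Name of the elevated tissue.
#' @param clones_per_tissue cDNA clones per tissue per gene.
#' @param gdna_clones Genomic clones per gene.
#' @param n_individuals Individuals clones are attributed to (round-robin).
#' @param spectrum_weights Non-negative weights over the 12 ordered
#'   substitution classes `A>C ... T>G`.
#' @param p_insertion,p_deletion Per-event probabilities of the indel
#'   kinds; substitutions take the rest.
#' @param max_del_len Maximum deletion length (contiguous bases).
#' @param min_spacing Minimum distance (bases) between planted events in a
#'   clone, so each event is unambiguously recoverable.
#' @param error_rate Optional uniform per-base noise channel (default 0;
#'   Sanger consensus reads are assumed clean).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 4L,
                       exons_per_gene = c(1L, 3L),
                       exon_len = c(150L, 250L),
                       intron_len = c(60L, 300L),
                       tissues = c(antennae = 0.4, legs = 0.4, head = 0.4,
                                   wings = 0.4, pheromone_gland = 0.4),
                       pheromone_gland_multiplier = 3,
                       pheromone_tissue = "pheromone_gland",
                       clones_per_tissue = 20L,
                       gdna_clones = 15L,
                       n_individuals = 5L,
                       spectrum_weights = c(`A>C` = 6, `A>G` = 116,
                                            `A>T` = 6, `C>A` = 6, `C>G` = 4,
                                            `C>T` = 30, `G>A` = 41,
                                            `G>C` = 4, `G>T` = 19,
                                            `T>A` = 6, `T>C` = 48,
                                            `T>G` = 6),
                       p_insertion = 0.05,
                       p_deletion = 0.10,
                       max_del_len = 12L,
                       min_spacing = 10L,
                       error_rate = 0) {
  if (!setequal(names(spectrum_weights), SUB_CLASSES)) {
    abort("`spectrum_weights` must name all 12 substitution classes.")
  }
  spectrum_weights <- spectrum_weights[SUB_CLASSES]
  if (any(spectrum_weights < 0) || sum(spectrum_weights) <= 0) {
    abort("`spectrum_weights` must be non-negative with positive sum.")
  }
  if (p_insertion < 0 || p_deletion < 0 || p_insertion + p_deletion > 1) {
    abort("Indel probabilities must be in [0,1] with p_ins + p_del <= 1.")
  }
  if (any(tissues < 0)) abort("Tissue rates (lambda) must be >= 0.")
  if (pheromone_gland_multiplier < 1) abort("Multiplier must be >= 1.")
  if (exons_per_gene[1] < 1L) abort("Need at least one exon per gene.")
  structure(
    list(n_genes = as.integer(n_genes),
         exons_per_gene = as.integer(exons_per_gene),
         exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
         tissues = tissues,
         pheromone_gland_multiplier = pheromone_gland_multiplier,
         pheromone_tissue = pheromone_tissue,
         clones_per_tissue = as.integer(clones_per_tissue),
         gdna_clones = as.integer(gdna_clones),
         n_individuals = as.integer(n_individuals),
         spectrum_weights = spectrum_weights,
         p_insertion = p_insertion, p_deletion = p_deletion,
         max_del_len = as.integer(max_del_len),
         min_spacing = as.integer(min_spacing),
         error_rate = error_rate),
    class = "sim_config")
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate one gene model and its transcript reference
#'
#' Draws an exon/intron structure within the configured ranges and builds
#' a spliced cDNA holding an open reading frame with an initial ATG, no
#' internal stop and a terminal stop codon, plus short untranslated
#' flanks. Consumes the ambient RNG stream (seed it, or use
#' [simulate_dataset()] which seeds it for you).
#'
#' @param config A [sim_config()].
#' @param gene_id Label for the gene.
#' @return List with `model` ([gene_model()]) and `ref`
#'   ([transcript_ref()]).
#' @export
simulate_gene <- function(config, gene_id = "gene01") {
  stopifnot(inherits(config, "sim_config"))
  n_exons <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
  exon_lens <- sample(config$exon_len[1]:config$exon_len[2], n_exons,
                      replace = TRUE)
  L <- sum(exon_lens)
  offset <- sample(0:9, 1L)
  utr3 <- sample(3:9, 1L)
  n_codons <- (L - offset - 3L - utr3) %/% 3L
  if (n_codons < 10L) {
    abort("Configured exon lengths too short to hold an open reading frame.")
  }
  utr3 <- L - offset - 3L * n_codons - 3L  # absorb rounding into the 3' UTR
  codons <- c("ATG", sample(setdiff(sense_codons(), "ATG"), n_codons - 1L,
                            replace = TRUE))
  cdna <- paste0(random_bases(offset), paste(codons, collapse = ""),
                 sample(STOP_CODONS, 1L), random_bases(utr3))
  stopifnot(str_length(cdna) == L)

  # split the cDNA into exons and interleave introns on the + strand
  bounds <- cumsum(exon_lens)
  pieces <- str_sub(cdna, c(1L, head(bounds, -1L) + 1L), bounds)
  introns <- if (n_exons > 1L) {
    map_chr(seq_len(n_exons - 1L), function(i) {
      random_bases(sample(config$intron_len[1]:config$intron_len[2], 1L))
    })
  } else {
    character(0)
  }
  scaffold <- pieces[1L]
  starts <- 1L
  ends <- exon_lens[1L]
  if (n_exons > 1L) {
    for (i in 2:n_exons) {
      scaffold <- paste0(scaffold, introns[i - 1L], pieces[i])
      starts <- c(starts, str_length(scaffold) - exon_lens[i] + 1L)
      ends <- c(ends, str_length(scaffold))
    }
  }
  strand <- sample(c("+", "-"), 1L)
  S <- str_length(scaffold)
  if (strand == "-") {
    scaffold <- revcomp(scaffold)
    new_starts <- S - rev(ends) + 1L
    new_ends <- S - rev(starts) + 1L
    starts <- new_starts; ends <- new_ends
  }
  model <- gene_model(gene_id, paste0("scaf_", gene_id), strand,
                      tibble(start = starts, end = ends), scaffold)
  stopifnot(identical(splice_transcript(model), cdna))
  list(model = model, ref = transcript_ref(gene_id, cdna, offset))
}

# Draw one event of the given kind at a canonical, well-spaced position.
# Returns NULL when no admissible position exists.
draw_event <- function(kind, ref_chars, occupied, config) {
  L <- length(ref_chars)
  margin <- config$min_spacing + config$max_del_len + 2L
  lo <- margin; hi <- L - margin
  if (hi <= lo) return(NULL)
  admissible <- function(p, e) {
    !any(occupied$pos <= e + config$min_spacing &
         occupied$end >= p - config$min_spacing)
  }
  if (kind == "substitution") {
    cls <- sample(SUB_CLASSES, 1L, prob = config$spectrum_weights)
    from <- str_sub(cls, 1L, 1L); to <- str_sub(cls, 3L, 3L)
    cand <- which(ref_chars == from)
    cand <- cand[cand >= lo & cand <= hi]
    cand <- cand[sample.int(length(cand))]  # random order, empty-safe
    for (p in cand) {
      if (admissible(p, p)) {
        return(tibble(kind = "substitution", pos = p, end = p,
                      ref_allele = from, alt_allele = to))
      }
    }
    return(NULL)
  }
  if (kind == "deletion") {
    len <- if (config$max_del_len == 1L) 1L else {
      sample(1:config$max_del_len, 1L,
             prob = c(0.7, rep(0.3 / (config$max_del_len - 1L),
                               config$max_del_len - 1L)))
    }
    idx <- lo:(hi - len + 1L)
    cand <- idx[sample.int(length(idx))]
    for (p in cand) {
      canonical <- ref_chars[p - 1L] != ref_chars[p + len - 1L]
      if (canonical && admissible(p, p + len - 1L)) {
        return(tibble(kind = "deletion", pos = p, end = p + len - 1L,
                      ref_allele = paste(ref_chars[p:(p + len - 1L)],
                                         collapse = ""),
                      alt_allele = ""))
      }
    }
    return(NULL)
  }
  # insertion: one base after position p, canonical iff base != ref[p]
  idx <- lo:hi
  cand <- idx[sample.int(length(idx))]
  for (p in cand) {
    base <- sample(setdiff(c("A", "C", "G", "T"), ref_chars[p]), 1L)
    if (admissible(p, p)) {
      return(tibble(kind = "insertion", pos = p, end = p,
                    ref_allele = "", alt_allele = base))
    }
  }
  NULL
}

#' Simulate a tissue's cDNA clone set with planted RDDs
#'
#' Each clone carries a Poisson number of events (lambda of the tissue,
#' times the pheromone-gland multiplier where applicable). Event kinds are
#' drawn as (1 - p_ins - p_del, p_ins, p_del); substitution classes follow
#' `spectrum_weights`; deletions are contiguous 1..max_del_len bases;
#' insertions are single-base. Events are planted at least `min_spacing`
#' bases apart and only at left-canonical positions (a planted indel
#' cannot be slid left), so the manifest coordinates coincide with the
#' caller's left-normalised coordinates.
#'
#' @param ref A [transcript_ref()].
#' @param tissue Tissue name (must be in `config$tissues`).
#' @param config A [sim_config()].
#' @param clone_prefix Prefix for clone ids.
#' @return List with `clones` (tibble: `clone_id`, `gene_id`, `tissue`,
#'   `individual`, `source`, `seq`) and `manifest` (tibble: `clone_id`,
#'   `gene_id`, `tissue`, `kind`, `pos`, `end`, `ref_allele`,
#'   `alt_allele`).
#' @export
simulate_clone_set <- function(ref, tissue, config,
                               clone_prefix = NULL) {
  stopifnot(inherits(ref, "transcript_ref"), inherits(config, "sim_config"))
  if (!tissue %in% names(config$tissues)) {
    abort(sprintf("Unknown tissue: %s", tissue))
  }
  lambda <- unname(config$tissues[tissue])
  if (identical(tissue, config$pheromone_tissue)) {
    lambda <- lambda * config$pheromone_gland_multiplier
  }
  L <- str_length(ref$cdna)
  capacity <- max(0L, (L - 2L * (config$min_spacing + config$max_del_len)) %/%
                    (config$min_spacing + config$max_del_len))
  if (lambda > capacity) {
    abort("Configured RDD rate too high for the reference length and spacing.")
  }
  ref_chars <- str_split(ref$cdna, "")[[1L]]
  prefix <- clone_prefix %||% paste0(ref$gene_id, "-", tissue)
  p_kind <- c(substitution = 1 - config$p_insertion - config$p_deletion,
              insertion = config$p_insertion, deletion = config$p_deletion)

  clones <- vector("list", config$clones_per_tissue)
  manifests <- vector("list", config$clones_per_tissue)
  for (k in seq_len(config$clones_per_tissue)) {
    clone_id <- sprintf("%s-%02d", prefix, k)
    individual <- sprintf("F%d", (k - 1L) %% config$n_individuals + 1L)
    n_events <- rpois(1L, lambda)
    occupied <- tibble(pos = integer(), end = integer())
    evs <- list()
    for (e in seq_len(n_events)) {
      kind <- sample(names(p_kind), 1L, prob = p_kind)
      ev <- draw_event(kind, ref_chars, occupied, config)
      if (is.null(ev)) next   # no admissible slot left; drop the event
      occupied <- bind_rows(occupied, ev[c("pos", "end")])
      evs[[length(evs) + 1L]] <- ev
    }
    ev_tbl <- if (length(evs)) bind_rows(evs) else
      tibble(kind = character(), pos = integer(), end = integer(),
             ref_allele = character(), alt_allele = character())
    seq_out <- apply_events_to_cdna(ref$cdna, ev_tbl)
    if (config$error_rate > 0) {
      seq_out <- add_uniform_noise(seq_out, config$error_rate)
    }
    clones[[k]] <- tibble(clone_id = clone_id, gene_id = ref$gene_id,
                          tissue = tissue, individual = individual,
                          source = "cDNA", seq = seq_out)
    if (nrow(ev_tbl)) {
      manifests[[k]] <- mutate(arrange(ev_tbl, .data$pos),
                               clone_id = clone_id, gene_id = ref$gene_id,
                               tissue = tissue, .before = 1L)
    }
  }
  man <- bind_rows(manifests)
  if (ncol(man) == 0L) man <- empty_manifest()
  list(clones = list_rbind(clones), manifest = man)
}

add_uniform_noise <- function(seq, rate) {
  chars <- str_split(seq, "")[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (p in hit) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a complete dataset
#'
#' Seeds the RNG, simulates `n_genes` gene models, and for each gene a
#' cDNA clone set per tissue plus mutation-free gDNA clones. The truth
#' manifest records every planted event.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the only source of randomness.
#' @return List of class `rdd_simulation`: `genes` (named list of
#'   `model`/`ref` pairs), `clones` (tibble including gDNA rows),
#'   `manifest` (tibble), `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  genes <- list()
  clones <- list()
  manifests <- list()
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("gene%02d", g)
    genes[[gid]] <- simulate_gene(config, gid)
    ref <- genes[[gid]]$ref
    for (tissue in names(config$tissues)) {
      cs <- simulate_clone_set(ref, tissue, config)
      clones[[length(clones) + 1L]] <- cs$clones
      manifests[[length(manifests) + 1L]] <- cs$manifest
    }
    gd <- tibble(
      clone_id = sprintf("%s-gDNA-%02d", gid, seq_len(config$gdna_clones)),
      gene_id = gid, tissue = "gDNA",
      individual = sprintf("F%d", (seq_len(config$gdna_clones) - 1L) %%
                             config$n_individuals + 1L),
      source = "gDNA", seq = ref$cdna)
    clones[[length(clones) + 1L]] <- gd
  }
  structure(
    list(genes = genes, clones = list_rbind(clones),
         manifest = bind_rows(manifests), config = config,
         seed = as.integer(seed)),
    class = "rdd_simulation")
}

#' @export
print.rdd_simulation <- function(x, ...) {
  cat(sprintf("<rdd_simulation> %d gene(s), %d clone(s), %d planted event(s), seed %d\n",
              length(x$genes), nrow(x$clones), nrow(x$manifest), x$seed))
  invisible(x)
}
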