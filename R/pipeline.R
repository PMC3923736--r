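# End-to-end orchestration: consensus -> alignments -> events -> variants
# -> statistics -> clustering, with stage logging and table export.

#' Pipeline configuration
#'
#' Exactly one of `input_dir` (a dataset written by [write_dataset()]) or
#' `simulate` (a [sim_config()]) must be supplied.
#'
#' @param input_dir Dataset directory, or `NULL`.
#' @param simulate A [sim_config()], or `NULL`.
#' @param seed Integer seed used when simulating.
#' @param align [align_params()].
#' @param stop_gain_convention `"stop_position"` or `"length"` (see
#'   [classify_effect()]).
#' @param signal_peptide_end Optional residue index for the signal-peptide
#'   flag.
#' @param cluster_feature `"sites"` or `"spectrum"`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, simulate = NULL, seed = 1L,
                            align = align_params(),
                            stop_gain_convention = "stop_position",
                            signal_peptide_end = NULL,
                            cluster_feature = "sites") {
  if (is.null(input_dir) == is.null(simulate)) {
    abort("Supply exactly one of `input_dir` or `simulate`.")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  structure(list(input_dir = input_dir, simulate = simulate,
                 seed = as.integer(seed), align = align,
                 stop_gain_convention = stop_gain_convention,
                 signal_peptide_end = signal_peptide_end,
                 cluster_feature = cluster_feature),
            class = "pipeline_config")
}

#' Run the full RDD pipeline
#'
#' For every gene: builds the gDNA consensus, aligns each cDNA clone to
#' it, calls and merges events, classifies each clone's protein effect,
#' then computes the pooled statistics (gene x tissue table, substitution
#' spectrum, 3'-context bias per gene, synonymous split, per-clone rates)
#' and the complete-linkage tissue dendrogram. Reruns with the same seed
#' are reproducible.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return List of class `rdd_report` with elements `genes`, `clones`,
#'   `manifest` (when simulated), `events`, `variants`, `table1`,
#'   `spectrum`, `bias`, `syn_nonsyn`, `rates`, `dendrogram`, `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))

  data <- if (!is.null(config$simulate)) {
    say("Simulating dataset (seed %d)", config$seed)
    simulate_dataset(config$simulate, config$seed)
  } else {
    say("Reading dataset from %s", config$input_dir)
    read_dataset(config$input_dir)
  }
  genes <- data$genes
  clones <- data$clones
  tissue_levels <- unique(clones$tissue[clones$source == "cDNA"])
  say("Loaded %d gene(s), %d clone(s)", length(genes), nrow(clones))

  events <- list()
  variants <- list()
  bias <- list()
  synsplit <- list()
  rates <- list()
  for (gid in names(genes)) {
    ref <- genes[[gid]]$ref
    gdna <- filter(clones, .data$gene_id == gid, .data$source == "gDNA")
    cdna <- filter(clones, .data$gene_id == gid, .data$source == "cDNA")
    consensus <- if (nrow(gdna)) {
      build_gdna_consensus(ref$cdna, gdna$seq, config$align)
    } else {
      structure(list(consensus = ref$cdna, variable_positions = integer(0)),
                class = "consensus_result")
    }
    ev_gene <- map(seq_len(nrow(cdna)), function(k) {
      pair <- global_align(consensus$consensus, cdna$seq[k], config$align)
      call_events(consensus, pair, cdna[k, ])
    }) |> list_rbind()
    if (ncol(ev_gene) == 0L) ev_gene <- empty_events()
    say("%s: %d cDNA clone(s), %d event(s) [%s]", gid, nrow(cdna),
        nrow(ev_gene),
        paste(sprintf("%s=%d", tissue_levels,
                      map_int(tissue_levels,
                              ~ sum(ev_gene$tissue == .x))), collapse = ", "))
    events[[gid]] <- ev_gene
    variants[[gid]] <- classify_clones(
      ref, ev_gene, clones = cdna,
      stop_gain_convention = config$stop_gain_convention,
      signal_peptide_end = config$signal_peptide_end)
    bias[[gid]] <- tryCatch(
      mutate(three_prime_context_bias(ev_gene, ref), gene_id = gid,
             .before = 1L),
      error = function(e) NULL)
    synsplit[[gid]] <- mutate(suppressMessages(syn_nonsyn_counts(ev_gene, ref)),
                              gene_id = gid, .before = 1L)
    rates[[gid]] <- mutate(rdd_rate(ev_gene, cdna, ref), gene_id = gid,
                           .before = 1L)
  }
  events <- list_rbind(unname(events))
  if (ncol(events) == 0L) events <- empty_events()
  variants <- list_rbind(unname(variants))
  table1 <- gene_tissue_counts(events, genes = names(genes),
                               tissues = tissue_levels)
  spectrum <- substitution_spectrum(events)
  dendro <- tryCatch(
    tissue_dendrogram(events, feature = config$cluster_feature),
    error = function(e) {
      warn(sprintf("Tissue dendrogram unavailable: %s", conditionMessage(e)))
      NULL
    })
  say("Pipeline complete: %d event(s), %d clone variant row(s)",
      nrow(events), nrow(variants))
  structure(
    list(genes = genes, clones = clones, manifest = data$manifest,
         events = events, variants = variants, table1 = table1,
         spectrum = spectrum, bias = bind_rows(bias),
         syn_nonsyn = list_rbind(unname(synsplit)),
         rates = list_rbind(unname(rates)),
         dendrogram = dendro, config = config),
    class = "rdd_report")
}

#' @export
print.rdd_report <- function(x, ...) {
  cat(sprintf("<rdd_report> %d gene(s), %d event(s), %d clone variant row(s)\n",
              length(x$genes), nrow(x$events), nrow(x$variants)))
  invisible(x)
}

#' Export the report tables
#'
#' Writes `table1.tsv` (gene x tissue counts with totals), `table2.tsv`
#' (per-clone variants: RNA names, protein name, category, residue count,
#' mass), `spectrum.tsv`, `sites.tsv` (per-site recurrence), `events.tsv`,
#' `dendrogram.nwk` and `summary.json` into `out_dir`.
#'
#' @param report An `rdd_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
export_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "rdd_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$table1, file.path(out_dir, "table1.tsv"))
  table2 <- report$variants |>
    select("clone_id", "gene_id", "tissue", "individual", "rna_names",
           "protein_name", "category", "reported_len_aa", "mass_kda",
           "in_signal_peptide")
  readr::write_tsv(table2, file.path(out_dir, "table2.tsv"))
  readr::write_tsv(as_tibble(report$spectrum),
                   file.path(out_dir, "spectrum.tsv"))
  sites <- report$events |>
    split(report$events$gene_id) |>
    map(summarize_sites) |>
    imap(~ mutate(.x, gene_id = .y, .before = 1L)) |>
    list_rbind()
  if (ncol(sites) == 0L) {
    sites <- tibble(gene_id = character(), pos = integer(),
                    tissue = character(), kind = character(),
                    alt_allele = character(), n_clones = integer(),
                    n_tissues_at_site = integer())
  }
  readr::write_tsv(sites, file.path(out_dir, "sites.tsv"))
  readr::write_tsv(report$events, file.path(out_dir, "events.tsv"))
  if (!is.null(report$dendrogram)) {
    writeLines(report$dendrogram$newick, file.path(out_dir, "dendrogram.nwk"))
  }
  summary <- list(
    n_genes = length(report$genes),
    n_clones = nrow(report$clones),
    n_events = nrow(report$events),
    events_by_kind = as.list(table(report$events$kind)),
    spectrum_total = attr(report$spectrum, "total"),
    frac_ag = attr(report$spectrum, "frac_ag"),
    syn_nonsyn = as.list(colSums(report$syn_nonsyn[-1L])),
    rates = report$rates,
    bias = report$bias,
    note = "single planned context test; no multiple-testing correction")
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(file.path(out_dir, c("table1.tsv", "table2.tsv", "spectrum.tsv",
                                 "sites.tsv", "events.tsv", "dendrogram.nwk",
                                 "summary.json")))
}
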