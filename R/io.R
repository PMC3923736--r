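# Plain-text dataset exchange: FASTA scaffolds and clones, GFF3 gene
# models, TSV clone metadata and a JSON truth manifest. Reading back a
# written dataset reproduces the inputs.

#' Write a simulated (or assembled) dataset to disk
#'
#' Emits `scaffolds.fasta`, `genes.gff3` (1-based inclusive exon
#' coordinates, ORF offsets as gene attributes), `clones_cdna.fasta`,
#' `clones_gdna.fasta`, `clones.tsv` (clone metadata) and
#' `truth_manifest.json` (planted events, if any).
#'
#' @param genes Named list of `list(model =, ref =)` pairs as produced by
#'   [simulate_gene()].
#' @param clones Clone tibble (`clone_id`, `gene_id`, `tissue`,
#'   `individual`, `source`, `seq`).
#' @param manifest Event manifest tibble (may have zero rows).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(genes, clones, manifest, out_dir) {
  if (anyDuplicated(clones$clone_id)) abort("Duplicate clone_id values.")
  if (nrow(clones) == 0L) warn("Writing a dataset with no clones.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  scaffolds <- Biostrings::DNAStringSet(
    setNames(map_chr(genes, ~ .x$model$scaffold_seq),
             map_chr(genes, ~ .x$model$scaffold_id)))
  Biostrings::writeXStringSet(scaffolds, file.path(out_dir, "scaffolds.fasta"))

  gr <- genes_to_granges(genes)
  rtracklayer::export(gr, file.path(out_dir, "genes.gff3"), format = "gff3")

  for (src in c("cDNA", "gDNA")) {
    sub <- filter(clones, .data$source == src)
    f <- file.path(out_dir, sprintf("clones_%s.fasta", str_to_lower(src)))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(sub$seq, sub$clone_id)), f)
  }
  readr::write_tsv(select(clones, -"seq"), file.path(out_dir, "clones.tsv"))
  jsonlite::write_json(manifest, file.path(out_dir, "truth_manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(file.path(out_dir, c("scaffolds.fasta", "genes.gff3",
                                 "clones_cdna.fasta", "clones_gdna.fasta",
                                 "clones.tsv", "truth_manifest.json")))
}

genes_to_granges <- function(genes) {
  rows <- imap(genes, function(g, gid) {
    ex <- g$model$exons
    tibble(
      seqnames = g$model$scaffold_id,
      start = c(min(ex$start), ex$start),
      end = c(max(ex$end), ex$end),
      strand = g$model$strand,
      type = c("gene", rep("exon", nrow(ex))),
      ID = c(gid, sprintf("%s:exon%d", gid, seq_len(nrow(ex)))),
      Parent = c(NA_character_, rep(gid, nrow(ex))),
      orf_offset = c(g$ref$orf_offset, rep(NA_integer_, nrow(ex))))
  })
  df <- list_rbind(rows)
  GenomicRanges::makeGRangesFromDataFrame(df, keep.extra.columns = TRUE)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory holding the dataset files.
#' @return List with `genes` (named list of `model`/`ref` pairs), `clones`
#'   (tibble with sequences) and `manifest` (tibble).
#' @export
read_dataset <- function(dir) {
  scaffolds <- Biostrings::readDNAStringSet(file.path(dir, "scaffolds.fasta"))
  gff <- rtracklayer::import(file.path(dir, "genes.gff3"), format = "gff3")
  meta <- readr::read_tsv(file.path(dir, "clones.tsv"),
                          show_col_types = FALSE)
  seqs <- c(Biostrings::readDNAStringSet(file.path(dir, "clones_cdna.fasta")),
            Biostrings::readDNAStringSet(file.path(dir, "clones_gdna.fasta")))
  clones <- mutate(meta, seq = as.character(seqs[.data$clone_id]))

  gene_rows <- gff[gff$type == "gene"]
  genes <- list()
  for (i in seq_along(gene_rows)) {
    gid <- gene_rows$ID[i]
    ex <- gff[gff$type == "exon" &
                vapply(gff$Parent, function(p) gid %in% p, logical(1))]
    scaf_id <- as.character(GenomicRanges::seqnames(gene_rows[i]))
    model <- gene_model(
      gid, scaf_id,
      as.character(GenomicRanges::strand(gene_rows[i])),
      tibble(start = GenomicRanges::start(ex), end = GenomicRanges::end(ex)),
      as.character(scaffolds[[scaf_id]]))
    ref <- transcript_ref(gid, splice_transcript(model),
                          as.integer(gene_rows$orf_offset[i]))
    genes[[gid]] <- list(model = model, ref = ref)
  }
  manifest_path <- file.path(dir, "truth_manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    m <- jsonlite::fromJSON(manifest_path)
    if (length(m) == 0L || is.null(nrow(m)) || nrow(m) == 0L) {
      empty_manifest()
    } else {
      mutate(as_tibble(m), pos = as.integer(.data$pos),
             end = as.integer(.data$end),
             ref_allele = as.character(.data$ref_allele),
             alt_allele = as.character(.data$alt_allele))
    }
  } else {
    empty_manifest()
  }
  list(genes = genes, clones = as_tibble(clones), manifest = manifest)
}
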