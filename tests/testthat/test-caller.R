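# Event calling, deletion-run merging, nomenclature and site summaries.

meta1 <- tibble::tibble(clone_id = "c1", gene_id = "g1",
                        tissue = "antennae", individual = "F1")

call_on <- function(ref, query, masked = integer(0)) {
  cons <- structure(list(consensus = ref, variable_positions = masked),
                    class = "consensus_result")
  call_events(cons, global_align(ref, query), meta1)
}

test_that("an identical clone yields no events", {
  ref <- patterned_ref(100)
  expect_identical(nrow(call_on(ref, ref)), 0L)
})

test_that("a clone missing one base is called as a deletion at that position", {
  # base 307 of a patterned reference, mirroring a single-C-deletion clone
  ref <- substr(strrep("TACG", 90), 1, 360)
  expect_identical(substr(ref, 307, 307), "C")
  clone <- paste0(substr(ref, 1, 306), substr(ref, 308, 360))
  ev <- call_on(ref, clone)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "deletion")
  expect_identical(ev$pos, 307L)
  expect_identical(ev$ref_allele, "C")
  expect_identical(ev$rna_name, "r.307c<")
})

test_that("substitutions, insertions and masked columns are handled", {
  ref <- patterned_ref(80)
  sub <- ref; substr(sub, 41, 41) <- "T"   # ref base A -> T
  ev <- call_on(ref, sub)
  expect_identical(ev$kind, "substitution")
  expect_identical(ev$rna_name, "r.41a>t")
  # the same difference at a masked (variable) site is dropped
  expect_identical(nrow(call_on(ref, sub, masked = 41L)), 0L)

  # inserted base differs from its anchor, so the position is canonical
  ins <- paste0(substr(ref, 1, 40), "C", substr(ref, 41, 80))
  evi <- call_on(ref, ins)
  expect_identical(evi$kind, "insertion")
  expect_identical(evi$pos, 40L)
  expect_identical(evi$rna_name, "r.40c>")
})

test_that("adjacent deletions merge into one multi-base event", {
  ev <- tibble::tibble(
    clone_id = "c", gene_id = "g", tissue = "t", individual = "F1",
    kind = "deletion", pos = c(115L, 116L), end = c(115L, 116L),
    ref_allele = c("A", "T"), alt_allele = "", rna_name = NA_character_)
  m <- merge_deletion_runs(ev)
  expect_identical(nrow(m), 1L)
  expect_identical(m$ref_allele, "AT")
  expect_identical(rna_name(m[1, ]), "r.115_116at<")

  run3 <- tibble::tibble(
    clone_id = "c", gene_id = "g", tissue = "t", individual = "F1",
    kind = "deletion", pos = 10:12, end = 10:12,
    ref_allele = c("G", "C", "A"), alt_allele = "", rna_name = NA_character_)
  m3 <- merge_deletion_runs(run3)
  expect_identical(m3$ref_allele, "GCA")
  # merging conserves the deleted base count
  expect_identical(nchar(m3$ref_allele), sum(nchar(run3$ref_allele)))

  # isolated deletions and non-adjacent runs stay separate
  apart <- dplyr::mutate(run3, pos = c(10L, 12L, 14L), end = pos)
  expect_identical(nrow(merge_deletion_runs(apart)), 3L)
})

test_that("the caller recovers a merged multi-base deletion end to end", {
  set.seed(52)
  repeat {   # draw a reference where the 181-192 deletion is left-canonical
    ref <- random_dna(240)
    if (substr(ref, 180, 180) != substr(ref, 192, 192)) break
  }
  clone <- paste0(substr(ref, 1, 180), substr(ref, 193, 240))  # drop 181-192
  ev <- call_on(ref, clone)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "deletion")
  expect_identical(ev$pos, 181L)
  expect_identical(nchar(ev$ref_allele), 12L)
  expect_match(ev$rna_name, "^r\\.181-192[acgt]{2}<$")
})

test_that("rna_name covers the dialect and parse inverts it", {
  sub <- tibble::tibble(kind = "substitution", pos = 68L, end = 68L,
                        ref_allele = "C", alt_allele = "A")
  expect_identical(rna_name(sub), "r.68c>a")
  del1 <- tibble::tibble(kind = "deletion", pos = 187L, end = 187L,
                         ref_allele = "A", alt_allele = "")
  expect_identical(rna_name(del1), "r.187a<")
  ins <- tibble::tibble(kind = "insertion", pos = 317L, end = 317L,
                        ref_allele = "", alt_allele = "A")
  expect_identical(rna_name(ins), "r.317a>")
  expect_error(parse_rna_name("r.abc"), "parse")
})

test_that("parse_rna_name inverts rna_name on 1000 random events", {
  set.seed(51)
  ok <- logical(1000)
  for (i in 1:1000) {
    kind <- sample(c("substitution", "deletion", "insertion"), 1)
    pos <- sample(1:5000, 1)
    if (kind == "substitution") {
      ref <- sample(c("A", "C", "G", "T"), 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    } else if (kind == "deletion") {
      ref <- random_dna(sample(c(1, 1, 1, 2, 2, 3:12), 1))
      alt <- ""
    } else {
      ref <- ""
      alt <- random_dna(sample(1:4, 1))
    }
    e <- tibble::tibble(kind = kind, pos = pos,
                        end = pos + max(nchar(ref) - 1L, 0L),
                        ref_allele = ref, alt_allele = alt)
    back <- parse_rna_name(rna_name(e))
    nb <- nchar(back$ref_allele); ne <- nchar(e$ref_allele)
    # range-deletion names carry only the boundary bases; interior is N
    ok[i] <- identical(back$kind, e$kind) &&
      identical(back$pos, e$pos) &&
      identical(back$end, as.integer(e$end)) &&
      identical(back$alt_allele, e$alt_allele) &&
      nb == ne &&
      substr(back$ref_allele, 1, 1) == substr(e$ref_allele, 1, 1) &&
      substr(back$ref_allele, nb, nb) == substr(e$ref_allele, ne, ne) &&
      (ne > 2 || identical(back$ref_allele, e$ref_allele))
  }
  expect_true(all(ok))
})

test_that("summarize_sites counts per-tissue recurrence and shared sites", {
  ev <- tibble::tibble(
    clone_id = c("a1", "a2", "a3", "l1"), gene_id = "g1",
    tissue = c("antennae", "antennae", "antennae", "legs"),
    individual = "F1", kind = "substitution",
    pos = c(50L, 50L, 50L, 50L), end = 50L,
    ref_allele = "G", alt_allele = "A", rna_name = "r.50g>a")
  s <- summarize_sites(ev)
  ant <- dplyr::filter(s, tissue == "antennae")
  expect_identical(ant$n_clones, 3L)
  expect_identical(unique(s$n_tissues_at_site), 2L)
  expect_identical(nrow(summarize_sites(ev[0, ])), 0L)
  expect_error(summarize_sites(dplyr::mutate(ev, gene_id = c("g1", "g1", "g2", "g2"))),
               "single gene")
})
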