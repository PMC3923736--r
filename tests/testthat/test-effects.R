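# Variant reconstruction, effect classification and protein nomenclature.

test_that("apply_events_to_cdna edits, conserves length arithmetic, and
           rejects overlap", {
  ref <- make_toy_transcript(30)
  expect_identical(apply_events_to_cdna(ref, rddclone:::empty_events()),
                   ref$cdna)
  del <- tibble::tibble(kind = "deletion", pos = 10L, end = 10L,
                        ref_allele = substr(ref$cdna, 10, 10), alt_allele = "")
  expect_identical(nchar(apply_events_to_cdna(ref, del)),
                   nchar(ref$cdna) - 1L)
  ins <- tibble::tibble(kind = "insertion", pos = 20L, end = 20L,
                        ref_allele = "", alt_allele = "AC")
  expect_identical(nchar(apply_events_to_cdna(ref, ins)),
                   nchar(ref$cdna) + 2L)
  overlap <- tibble::tibble(kind = c("deletion", "substitution"),
                            pos = c(10L, 11L), end = c(12L, 11L),
                            ref_allele = c(substr(ref$cdna, 10, 12), "A"),
                            alt_allele = c("", "G"))
  expect_error(apply_events_to_cdna(ref, overlap), "Overlapping")
})

test_that("applied events are recovered by re-alignment and calling", {
  # a random (aperiodic) reference where the chosen events are
  # left-canonical: the deletion's flanks differ and the inserted base
  # differs from its anchor
  set.seed(61)
  repeat {
    ref <- random_dna(200)
    if (substr(ref, 79, 79) != substr(ref, 82, 82) &&
        substr(ref, 150, 150) != "G" && substr(ref, 30, 30) != "A") break
  }
  ev <- tibble::tibble(
    kind = c("substitution", "deletion", "insertion"),
    pos = c(30L, 80L, 150L), end = c(30L, 82L, 150L),
    ref_allele = c(substr(ref, 30, 30), substr(ref, 80, 82), ""),
    alt_allele = c("A", "", "G"))
  variant <- apply_events_to_cdna(ref, ev)
  called <- call_events(consensus_of(ref), global_align(ref, variant),
                        list(clone_id = "c", gene_id = "g",
                             tissue = "t", individual = "F1"))
  expect_identical(as.data.frame(called[c("kind", "pos", "ref_allele", "alt_allele")]),
                   as.data.frame(ev[c("kind", "pos", "ref_allele", "alt_allele")]))
})

test_that("classification reproduces the five category archetypes", {
  # silent third-position change
  ref <- make_toy_transcript(50)
  silent <- tibble::tibble(kind = "substitution", pos = 6L, end = 6L,
                           ref_allele = substr(ref$cdna, 6, 6),
                           alt_allele = "G")  # GCT -> GCG, still Ala
  expect_identical(substr(ref$cdna, 4, 6), "GCT")
  cls <- classify_effect(ref, apply_events_to_cdna(ref, silent))
  expect_identical(cls$category, "silent")
  expect_identical(cls$protein_name, "silent")
  expect_identical(cls$reported_len_aa, 50L)

  # missense
  mis <- tibble::tibble(kind = "substitution", pos = 4L, end = 4L,
                        ref_allele = "G", alt_allele = "T")  # GCT -> TCT, A->S
  clm <- classify_effect(ref, apply_events_to_cdna(ref, mis))
  expect_identical(clm$category, "missense")
  expect_identical(clm$protein_name, "pmutAla2Ser")

  # stop gain: Lys codon AAG -> TAG at residue 96 of a 110-codon protein
  ref96 <- make_toy_transcript(110, c("96" = "K"))
  expect_identical(substr(ref96$cdna, 286, 288), "AAA")
  sg <- tibble::tibble(kind = "substitution", pos = 286L, end = 286L,
                       ref_allele = "A", alt_allele = "T")
  cls96 <- classify_effect(ref96, apply_events_to_cdna(ref96, sg))
  expect_identical(cls96$category, "stop_gain")
  expect_identical(cls96$protein_name, "pmutLys96*")
  # stop-position convention counts the mutated residue; strict length is 95
  expect_identical(cls96$reported_len_aa, 96L)
  strict <- classify_effect(ref96, apply_events_to_cdna(ref96, sg),
                            stop_gain_convention = "length")
  expect_identical(strict$reported_len_aa, 95L)
})

test_that("frameshifts split into early and late by protein length", {
  demo <- frameshift_demo_transcript()
  variant <- apply_events_to_cdna(demo$ref, demo$event)
  cls <- classify_effect(demo$ref, variant)
  expect_identical(cls$category, "frameshift_late")
  expect_identical(cls$protein_name, "fsHis87*l")
  expect_identical(cls$reported_len_aa, 129L)
  expect_identical(cls$reported_len_aa - demo$ref$native_len_aa, 18L)

  # a single-base insertion early in the frame typically truncates
  ref <- make_toy_transcript(111)
  ins <- tibble::tibble(kind = "insertion", pos = 268L, end = 268L,
                        ref_allele = "", alt_allele = "T")
  cli <- classify_effect(ref, apply_events_to_cdna(ref, ins))
  expect_match(cli$category, "^frameshift_")
  expect_identical(cli$category,
                   if (cli$reported_len_aa > 111L) "frameshift_late"
                   else "frameshift_early")
})

test_that("in-frame deletions report the excised motif and shortened count", {
  ref <- make_toy_transcript(104, c("45" = "D", "46" = "K",
                                    "47" = "I", "48" = "P"))
  del <- tibble::tibble(kind = "deletion", pos = 133L, end = 144L,
                        ref_allele = substr(ref$cdna, 133, 144),
                        alt_allele = "")
  cls <- classify_effect(ref, apply_events_to_cdna(ref, del))
  expect_identical(cls$category, "motif_deletion")
  expect_identical(cls$protein_name, "deleAsp45-Pro48")
  expect_identical(cls$reported_len_aa, 100L)
  expect_equal(cls$mass_kda, protein_mass(cls$variant_protein))
})

test_that("motif deletions obey the k-codon length law across sizes", {
  set.seed(62)
  for (i in 1:25) {
    n <- sample(60:150, 1)
    ref <- make_toy_transcript(n)
    k <- sample(1:8, 1)
    start_codon <- sample(5:(n - k - 5), 1)
    p1 <- ref$orf_offset + 3L * (start_codon - 1L) + 1L
    del <- tibble::tibble(kind = "deletion", pos = p1, end = p1 + 3L * k - 1L,
                          ref_allele = substr(ref$cdna, p1, p1 + 3L * k - 1L),
                          alt_allele = "")
    cls <- classify_effect(ref, apply_events_to_cdna(ref, del))
    expect_identical(cls$category, "motif_deletion")
    expect_identical(cls$reported_len_aa, as.integer(n - k))
  }
})

test_that("every variant gets exactly one category and frame arithmetic holds", {
  set.seed(63)
  inframe <- c("silent", "missense", "stop_gain", "motif_deletion")
  for (i in 1:200) {
    ref <- make_toy_transcript(sample(40:120, 1))
    ev <- random_single_event(ref)
    variant <- apply_events_to_cdna(ref, ev)
    cls <- classify_effect(ref, variant)
    expect_length(cls$category, 1)
    net <- nchar(variant) - nchar(ref$cdna)
    if (net %% 3 == 0) {
      expect_true(cls$category %in% inframe)
    } else {
      expect_match(cls$category, "^frameshift_")
    }
  }
})

test_that("variant_metrics applies the reporting conventions", {
  m <- variant_metrics(strrep("A", 95), "stop_gain")
  expect_identical(m$reported_len_aa, 96L)
  m2 <- variant_metrics(strrep("A", 95), "stop_gain", convention = "length")
  expect_identical(m2$reported_len_aa, 95L)
  m3 <- variant_metrics("", "frameshift_early")
  expect_true(m3$aborted)
  expect_identical(m3$reported_len_aa, 0L)
})

test_that("classify_clones groups events per clone and fills silent clones", {
  ref <- make_toy_transcript(60)
  ev <- tibble::tibble(
    clone_id = c("k1", "k1", "k2"), gene_id = ref$gene_id,
    tissue = c("legs", "legs", "wings"), individual = "F2",
    kind = "substitution", pos = c(31L, 61L, 10L), end = c(31L, 61L, 10L),
    ref_allele = substr(ref$cdna, c(31, 61, 10), c(31, 61, 10)),
    alt_allele = c("T", "T", "C"), rna_name = "x")
  # make the substitutions real changes
  ev <- dplyr::filter(ev, ref_allele != alt_allele)
  clones <- tibble::tibble(clone_id = c(unique(ev$clone_id), "k3"),
                           tissue = "legs", individual = "F1",
                           source = "cDNA")
  out <- classify_clones(ref, ev, clones)
  expect_identical(nrow(out), 3L)
  expect_identical(out$category[out$clone_id == "k3"], "silent")
  expect_identical(sum(out$clone_id == "k1"), 1L)
})

test_that("signal-peptide variants are flagged but still reported", {
  ref <- make_toy_transcript(60)
  mis <- tibble::tibble(kind = "substitution", pos = 4L, end = 4L,
                        ref_allele = "G", alt_allele = "T")
  cls <- classify_effect(ref, apply_events_to_cdna(ref, mis),
                         signal_peptide_end = 16)
  expect_true(cls$in_signal_peptide)
  expect_identical(cls$category, "missense")
})
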