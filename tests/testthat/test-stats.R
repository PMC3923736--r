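# Spectrum, context bias, tabulations, synonymous split, rates and
# clustering.

test_that("substitution_spectrum counts the 12 classes and ignores indels", {
  expect_identical(sum(substitution_spectrum(rddclone:::empty_events())$n), 0L)

  ev <- tibble::tibble(
    clone_id = "c", gene_id = "g", tissue = "t", individual = "F1",
    kind = c("substitution", "substitution", "substitution", "deletion"),
    pos = c(1L, 2L, 3L, 4L), end = pos,
    ref_allele = c("A", "A", "T", "G"),
    alt_allele = c("G", "G", "C", ""), rna_name = "x")
  sp <- substitution_spectrum(ev)
  expect_identical(sp$n[sp$class == "A>G"], 2L)
  expect_identical(sp$n[sp$class == "T>C"], 1L)
  expect_identical(attr(sp, "total"), 3L)
  expect_equal(attr(sp, "frac_ag"), 2 / 3)
  expect_identical(attr(substitution_spectrum(ev[ev$kind == "deletion", ]),
                        "total"), 0L)
  td <- tidy(sp)
  expect_equal(sum(td$fraction), 1)
})

test_that("spectrum of called events equals the planted truth", {
  cfg <- sim_config(n_genes = 1L, clones_per_tissue = 15L)
  rep <- suppressMessages(run_pipeline(
    pipeline_config(simulate = cfg, seed = 12), quiet = TRUE))
  sim <- simulate_dataset(cfg, seed = 12)
  got <- substitution_spectrum(rep$events)
  want <- substitution_spectrum(sim$manifest)
  expect_identical(got$n, want$n)
})

test_that("3' context bias: trivial proportions and the null calibration", {
  ref <- make_toy_transcript(80)
  # choose substitution sites whose 3' neighbour is A
  chars <- strsplit(ref$cdna, "")[[1]]
  a_next <- which(chars[-1] == "A")
  ev <- tibble::tibble(kind = "substitution", pos = a_next[1:5], end = pos,
                       ref_allele = chars[a_next[1:5]], alt_allele = "T")
  b <- three_prime_context_bias(ev, ref)
  expect_equal(b$proportion, 1)
  one <- three_prime_context_bias(ev[1, ], ref)
  expect_true(one$proportion %in% c(0, 1))
  expect_error(three_prime_context_bias(ev[0, ], ref), "No eligible")

  # null calibration: sites drawn uniformly give a roughly uniform p-value,
  # with type-I error at alpha = 0.05 no worse than 0.07
  set.seed(81)
  L <- nchar(ref$cdna)
  rejections <- 0L
  for (i in 1:1000) {
    pos <- sample(1:(L - 1), 40, replace = FALSE)
    evn <- tibble::tibble(kind = "substitution", pos = pos, end = pos,
                          ref_allele = chars[pos], alt_allele = "A")
    if (three_prime_context_bias(evn, ref)$p_value < 0.05) {
      rejections <- rejections + 1L
    }
  }
  expect_lte(rejections / 1000, 0.07)
})

test_that("gene_tissue_counts reproduces a published-style grid's totals", {
  grid <- readr::read_tsv(
    system.file("extdata", "table1_counts.tsv", package = "rddclone"),
    show_col_types = FALSE)
  m <- as_rdd_matrix(grid)
  expect_identical(m$Total[m$gene_id == "BmorCSP1"], 61)
  expect_identical(m$Total[m$gene_id == "BmorCSP14"], 91)
  expect_identical(m$Total[m$gene_id == "Total"], 233)

  # same totals when the grid is expanded to one pseudo-event per count
  ev <- tidyr::pivot_longer(grid, -gene_id, names_to = "tissue",
                            values_to = "n") |>
    tidyr::uncount(n) |>
    dplyr::mutate(kind = "substitution", pos = 1L, end = 1L,
                  ref_allele = "A", alt_allele = "G",
                  clone_id = "c", individual = "F1", rna_name = "x")
  m2 <- gene_tissue_counts(ev, genes = grid$gene_id, tissues = names(grid)[-1])
  expect_equal(m2$Total, m$Total)
  expect_equal(as.numeric(m2[m2$gene_id == "Total", -1]),
               as.numeric(m[m$gene_id == "Total", -1]))
  # empty input gives a zero matrix
  z <- gene_tissue_counts(rddclone:::empty_events(), genes = "g",
                          tissues = "t")
  expect_identical(z$Total, c(0, 0))
})

test_that("synonymous split matches a codon-table oracle", {
  ref <- make_toy_transcript(100)
  code <- Biostrings::GENETIC_CODE
  set.seed(82)
  syn <- 0L; nonsyn <- 0L
  evs <- list()
  for (i in 1:500) {
    p <- sample(seq_len(3 * 101), 1)  # anywhere in ORF incl. stop codon
    old <- substr(ref$cdna, p, p)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    evs[[i]] <- tibble::tibble(kind = "substitution", pos = p, end = p,
                               ref_allele = old, alt_allele = new)
    ci <- (p - 1) %/% 3
    codon <- substr(ref$cdna, ci * 3 + 1, ci * 3 + 3)
    var <- codon
    substr(var, p - ci * 3, p - ci * 3) <- new
    if (identical(code[[codon]], code[[var]])) syn <- syn + 1L
    else nonsyn <- nonsyn + 1L
  }
  got <- syn_nonsyn_counts(dplyr::bind_rows(evs), ref)
  expect_identical(got$synonymous, syn)
  expect_identical(got$nonsynonymous, nonsyn)
  expect_identical(got$synonymous + got$nonsynonymous, 500L)

  # events outside the reading frame are excluded and counted apart
  utr <- make_toy_transcript(20, orf_offset = 6L)
  out <- suppressMessages(syn_nonsyn_counts(
    tibble::tibble(kind = "substitution", pos = 2L, end = 2L,
                   ref_allele = substr(utr$cdna, 2, 2), alt_allele = "A"),
    utr))
  expect_identical(out$outside_orf, 1L)
})

test_that("rdd_rate reports per-clone and per-kb-per-clone denominators", {
  ev <- rddclone:::empty_events()[rep(1L, 0), ]
  expect_equal(rdd_rate(ev, 10, strrep("A", 500))$rate_per_clone, 0)
  ev5 <- tibble::tibble(kind = rep("substitution", 5), pos = 1:5, end = 1:5,
                        ref_allele = "A", alt_allele = "G")
  r <- rdd_rate(ev5, 10, strrep("A", 500))
  expect_equal(r$rate_per_clone, 0.5)
  expect_equal(r$rate_per_kb_per_clone, 1.0)
  r2 <- rdd_rate(ev5, 20, strrep("A", 500))
  expect_equal(r2$rate_per_clone, 0.25)
  expect_error(rdd_rate(ev5, 0, strrep("A", 500)), "at least one")
})

test_that("tissue_dendrogram matches hand-computed complete linkage", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4))
  d <- tissue_dendrogram(m)
  expect_equal(d$merges$height, c(0, 5))
  expect_identical(rddclone:::last_merged_leaves(d), "c")
  # three distinct rows, hand-computed: d(a,b)=1, d(a,c)=5, d(b,c)=4.47...
  m2 <- rbind(a = c(0, 0), b = c(1, 0), c = c(3, 4))
  d2 <- tissue_dendrogram(m2)
  expect_equal(d2$merges$height, c(1, 5))
  expect_error(tissue_dendrogram(m2[1, , drop = FALSE]), "at least two")
  expect_match(d2$newick, ";$")
  gl <- glance(d2)
  expect_identical(gl$last_separated, "c")
})

test_that("clustering heights are non-decreasing on random matrices", {
  set.seed(83)
  for (i in 1:20) {
    m <- matrix(runif(6 * 4), nrow = 6,
                dimnames = list(paste0("t", 1:6), NULL))
    d <- tissue_dendrogram(m)
    expect_true(all(diff(d$merges$height) >= -1e-12))
  }
})
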