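---
title: "Calling clone-level RNA-DNA differences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling clone-level RNA-DNA differences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rddclone)
library(dplyr)
```

## The problem

An RNA-DNA difference (RDD) is a site where a transcript's sequence
differs from the genomic DNA of the same individual. In a Sanger-clone
design, each sequenced plasmid insert represents one cDNA or gDNA
molecule: 10-20 clones are sequenced per tissue per individual, the gDNA
clones define an invariant genomic consensus, and every cDNA clone is
compared to it position by position. In the silkworm chemosensory-protein
(CSP) system this design reveals an A>G-dominated substitution spectrum
(the classic readout of A-to-I editing by ADAR enzymes), a strong
enrichment of edits in the pheromone gland, and indel RDDs whose
frameshifts reshape the encoded protein.

`rddclone` implements that comparison as a reusable pipeline plus a
seeded simulator, so every stage can be exercised and validated without
any sequence download.

## Pipeline model

1. **Consensus.** Each gDNA clone is globally aligned to the spliced
   coding reference; the per-column majority base is the consensus, with
   ties broken toward the reference. Columns where gDNA clones disagree
   among themselves are flagged as possible allelic variation and masked
   from RDD calling, because the design treats genomic sequence as
   invariant ground truth.
2. **Alignment.** Clones are near-identical amplicons of one reference,
   so pairwise global alignment against the consensus, columnwise,
   replaces a multiple alignment. Scoring is affine
   (match $+2$, mismatch $-2$, gap open $-6$, gap extend $-1$ by
   default): a gap of length $k$ costs $6 + k$, which discourages
   spurious indels in near-identical pairs. The engine is the Gotoh
   three-state dynamic programme provided by
   `Biostrings::pairwiseAlignment()`; tests verify its scores against an
   exhaustive enumeration oracle on short pairs.
3. **Canonical gap placement.** A gap inside a repeat tract has several
   score-equivalent positions. `left_normalize_gaps()` slides every gap
   run to its leftmost equivalent column (the same convention used to
   left-align indels in variant files), so event positions are
   deterministic. The simulator plants indels only at already-canonical
   positions, which makes planted and called coordinates directly
   comparable.
4. **Event calling.** Each differing column becomes one event;
   adjacent deleted columns merge into a single multi-base deletion, and
   adjacent inserted columns into one insertion anchored to the
   preceding reference base. Only *contiguous* deletion runs are merged:
   joining near-adjacent deletions (for example two deleted bases
   separated by one retained base) into one reported event is a display
   convention, not a well-defined call, so it is left to report-level
   grouping. Names use the RNA dialect `r.68c>a`, `r.187a<`,
   `r.115_116at<`, `r.181-192ga<` (range deletions record the boundary
   bases; everything between the endpoints is deleted), `r.317a>`.
5. **Effect classification.** Each clone's variant transcript is rebuilt
   from its events and re-translated in the native frame. Exactly one
   category is assigned:
   silent; missense (`pmutTyr23Phe`); stop-gain (`pmutLys96*`),
   a substitution creating a premature stop; frameshift
   (`fsPro90*e` / `fsHis87*l`), a net indel not divisible by 3, split
   *early*/*late* by whether the variant protein is shorter or longer
   than the native one; and motif deletion (`deleAsp45-Pro48`), an
   in-frame deletion excising whole codons. Multiple events in one clone
   are classified jointly from the full variant transcript, matching a
   per-clone reading of the data.
6. **Statistics.** Gene-by-tissue count matrix with totals; the
   12-class substitution spectrum; the proportion of substituted sites
   whose 3' neighbour is adenosine, tested against the reference's
   background A frequency with a two-sided exact binomial test;
   synonymous versus non-synonymous splits; RDD rates; and
   complete-linkage hierarchical clustering of tissues
   (`stats::hclust` on Euclidean distances, the standard tool for this
   analysis) on per-site event counts.

## Design choices worth recording

* **Reading frame is an explicit input.** Amplicons may begin at the
  initial ATG or at the first codon of the mature protein, so cDNA
  coordinates cannot be converted to residue numbers without knowing the
  5' offset. `transcript_ref()` therefore takes `orf_offset` per gene
  rather than inferring it; residue numbering (e.g. base 307 in codon
  87) follows from it.
* **Stop-gain residue counts.** Variant tables in this field typically
  report, for a stop-gain, the index of the residue mutated to stop
  (`pmutLys96*` tabulated as 96), one more than the strict residue
  count. The default `stop_gain_convention = "stop_position"`
  reproduces that; `"length"` gives the strict count.
* **Early/late frameshifts by protein length,** not stop-codon base
  position: the variant protein being shorter/longer than native is
  well defined under arbitrary indel combinations and reproduces the
  expected worked examples (a 102-residue early-stop and a 129-residue
  late-stop variant of a 111-residue protein).
* **Masses are average masses** (sum of average residue masses plus one
  water, reported in kDa to two decimals), the convention for quoting
  whole-protein molecular weights next to SDS-PAGE data. Monoisotopic
  masses are not offered.
* **Ambiguity codes are rejected**, not expanded: clone consensus
  sequences in this design are unambiguous, and a stray IUPAC code more
  likely signals an upstream problem than real polymorphism.
* **In-frame insertions** have no category of their own in the
  five-type scheme; they are reported as missense (the variant protein
  gains residues without a frame change). They are vanishingly rare
  under the simulator's single-base insertion model.
* **Read-through variants** (a substitution destroying the native stop)
  are likewise reported as missense, named with `Ter` as the reference
  residue.

## What the simulator emulates

`sim_config()` defaults encode the study conditions: five tissues
(antennae, legs, head, wings, pheromone gland), clones attributed to
five individuals, 20 cDNA clones per tissue per gene, 15 gDNA clones per
gene (all mutation-free copies of the reference), and four genes of one
to three exons whose spliced amplicons carry a complete reading frame.
Per-clone event counts are Poisson with a per-tissue rate
$\lambda = 0.4$ and a three-fold pheromone-gland multiplier, which at
the default design yields roughly 30 events per gene in ordinary tissues
versus ~95 in the gland, the order of contrast seen in tissue-resolved
RDD counts. Substitution classes are drawn from a 12-class weight vector
proportional to the reported spectrum (A>G 116, T>C 48, G>A 41, C>T 30,
G>T 19), with small equal weights (4-6) for the seven classes whose
counts are not individually reported. Deletions are contiguous, 1-12
bases (70% single-base); insertions are single-base; both are rare
(p = 0.10 and 0.05 per event).

Two simulator rules exist purely to make recovery exact rather than
approximate: events are planted at least 10 bases apart, and indels are
planted only at left-canonical positions (a planted gap cannot slide
left). Without them, two nearby events or a deletion inside a repeat
tract can have several equally optimal alignments, and "did we recover
the planted event?" stops being well defined. Real data have no such
guarantee, so perfect precision/recall on simulations bounds only the
bookkeeping, not biological calling accuracy. The simulator also omits,
by default, every error channel - reverse-transcription and polymerase
errors, chromatogram miscalls, allelic variation in gDNA - and so makes
no attempt to distinguish enzymatic editing from such artefacts; an
optional uniform per-base noise rate exists for robustness experiments
only.

## Numerical and degenerate-input behaviour

* Alignment tie-breaks are delegated to the alignment engine and then
  canonicalised by left-normalisation; normalisation is idempotent and
  score-preserving.
* Consensus ties go to the reference base; a site with any gDNA
  disagreement is masked from calling.
* A clone identical to the consensus yields an empty event list and is
  reported as `silent`.
* A variant whose translation is empty (stop in the first codon)
  carries an `aborted` flag, residue count 0 and no mass.
* A zero-rate simulation produces a valid all-silent report; the tissue
  dendrogram is skipped with a warning instead of an error.
* Clustering requires at least two tissue rows; heights from complete
  linkage are non-decreasing by construction and verified against a
  brute-force agglomeration in the tests.
* The context-bias test is a single planned comparison; no
  multiple-testing correction is applied, and the report says so.

## Problem sizes used in validation

The package's checks run at deliberately moderate scale: 500 simulated
clones for exact planted-event recovery; 1,000 random single-event
variants against an independent re-translation oracle; 200 random pairs
(length <= 10) against an exhaustive alignment-score oracle; 100 random
matrices (<= 6 leaves) against a brute-force complete-linkage oracle;
~10,000 planted substitutions for spectrum recovery within binomial
error; and 100 seeded simulations for the pheromone-gland separation
property. These sizes give the statistical assertions their stated
resolution (e.g. 3 binomial standard errors at n = 10,000 resolves a
doubled A>G weight easily) while keeping a full run of the suite fast.

## A worked example

```{r example}
cfg <- pipeline_config(
  simulate = sim_config(n_genes = 2, clones_per_tissue = 10,
                        gdna_clones = 5),
  seed = 7)
report <- run_pipeline(cfg, quiet = TRUE)
glance(report)
report$table1
head(filter(report$variants, category != "silent"))
```

```{r plots, fig.width = 6, fig.height = 3.5}
autoplot(report$spectrum)
if (!is.null(report$dendrogram)) autoplot(report$dendrogram)
```

## Known limitations

The aligner is pairwise and splice-unaware, which is correct for coding
amplicons but not for genomic reads; range-deletion names record only
their boundary bases, so parsing them cannot restore interior sequence;
the effect classifier assumes a single reading frame per transcript; and
nothing in the package attempts to decide whether a called RDD is
enzymatic editing, allelic variation that escaped the gDNA clones, or a
polymerase artefact - that separation needs orthogonal data.
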