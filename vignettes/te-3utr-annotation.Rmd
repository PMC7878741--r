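---
title: "Positional annotation of transposable elements at transcript 3' ends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional annotation of transposable elements at transcript 3' ends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Alu elements are ~300 bp primate SINE retrotransposons: two 7SL-derived
monomers (a left and a right arm) joined by an A-rich linker and ending in a
poly-A tail. When an Alu inserts in the sense orientation inside a 3'UTR, its
A-rich tract can supply a polyadenylation-competent context, shortening the
3'UTR and diversifying transcript isoforms through alternative
polyadenylation (APA). AluYRa1 is an Old-World-monkey-specific AluY
subfamily, absent from the human genome, which makes it a clean marker for
lineage-specific 3'-end remodelling in macaques.

`telocatr` implements the computational side of that analysis as a tested
package: given a UCSC gene annotation (genePred/refFlat), a RepeatMasker
table, and the six-column output of the TAPAS polyadenylation detector, it
answers

1. where each repeat sits relative to transcript structure and in which
   orientation (`classify_pair()`, `locate_all()`);
2. which genes end their 3'UTR on a given subfamily, split by registered
   (`NM_`) versus predicted (`XM_`) accessions (`gene_inventory()`);
3. which part of the Alu consensus anatomy carries a position of interest
   (`genomic_to_consensus()`, `classify_anatomy()`);
4. what fraction of detected polyadenylation sites falls on the
   sense-oriented elements, and how that fraction splits across poly-A
   tail / A-rich linker / arms (`join_apa_to_elements()`, `summarize_apa()`);
5. whether the cleavage context looks canonical: a CA dinucleotide
   immediately 5' of the cut and an upstream AATAAA/ATTAAA signal
   (`scan_cleavage_motifs()`).

## Coordinate conventions

All genomic coordinates are stored 0-based half-open, the native convention
of every input dialect (genePred, rmsk, BED). Any 1-based display is
formatting only. RepeatMasker's strand-dependent sign trick for consensus
coordinates (`repStart`/`repEnd`/`repLeft`, with the start/left roles swapped
on the minus strand) is normalized at parse time into
(`consensusStart`, `consensusEnd`, `consensusLeft`); no downstream code
branches on the raw signs.

## The positional classifier

Every repeat x transcript pair receives all categories whose definitions it
satisfies; the primary category is chosen by precedence, terminal events
first:

`UTR3_END > UTR5_START > ORF_END > ORF_START > EXON_SPLICING >
UTR3_INTERNAL > UTR5_INTERNAL > INSIDE_EXON > NO_EXONIC_OVERLAP`

The boundary semantics are deliberate and worth stating precisely, because
they are what the per-base oracle verifies:

* **Terminal bases.** The biological 3' terminal base is `txEnd - 1` on `+`
  and `txStart` on `-`. A repeat is `UTR3_END` when it covers that base --
  or starts at the first post-transcript coordinate (the transcript end is
  an exclusive coordinate, so such an element abuts the terminus at
  distance 0) -- and the terminal base lies in a 3'UTR block. `proximity_bp`
  (default 0) widens this window symmetrically; the default is strict
  because an element ending a few dozen bases short of the terminus is a
  documented *near-miss*, not a terminal event.
* **ORF boundaries.** A repeat covering the first (last) coding base is
  `ORF_START` (`ORF_END`). This follows the half-open rule: repeat
  `[a, b)` overlaps position `p` iff `a <= p < b`.
* **Splice junctions.** A repeat overlaps an internal junction only when it
  *spans* it, covering at least one base on each side (`a < j < b`).
  Merely touching an exon's first or last base is not junction overlap:
  under the covering rule a purely intronic repeat brushing an exon edge
  would be called `EXON_SPLICING` with zero exonic overlap, breaking the
  invariant that only `NO_EXONIC_OVERLAP` calls have `overlap_bp == 0`.
  (Terminal abutment at distance zero is the one sanctioned exception to
  that invariant.)
* **Noncoding transcripts** (`cdsStart == cdsEnd`) have no ORF and hence no
  UTRs; they carry empty UTR/CDS blocks and can only receive
  `INSIDE_EXON`, `EXON_SPLICING`, or `NO_EXONIC_OVERLAP`.

A repeat overlapping both a junction and the 3'UTR terminus is counted once
under its primary category; `all_categories` retains the full label set for
anyone who wants the alternative tally.

Orientation is `SENSE` iff the repeat strand equals the transcript strand.
Calls are per transcript; `gene_inventory()` collapses isoforms by gene
symbol and reports whether support comes from registered or predicted
accessions.

## Alu anatomy in consensus coordinates

`genomic_to_consensus()` is an affine map between the element's genomic
interval and its consensus interval (decreasing on the minus strand, whose
consensus 3' end sits at the genomic start). It ignores indels between copy
and consensus: exact on the generator's fixtures (equal spans by
construction), approximate on real diverged copies.

The default `anatomy_config()` -- left arm 1-131, A-rich linker 132-158,
right arm 159-311 of a 311 bp consensus -- follows the canonical AluY
dimeric layout. These are implementation defaults, not measured AluYRa1
coordinates (no printed coordinates exist to assert); every acceptance test
constructs its own config so no result depends on them. The poly-A tail is
defined positionally -- past the consensus end, or within
`polyA_max_extension` (default 30 bp) downstream of the element's sense 3'
end -- because RepeatMasker does not annotate tails.

## Joining TAPAS output

TAPAS reports per gene: name, chromosome, strand, detected polyadenylation
sites (including APA sites), abundances, read count. The join mirrors the
filtering applied before the published statistics: genes absent from the
annotation are *unjoined*; genes whose TAPAS strand conflicts with the
annotation, or whose annotated transcript has no 3'UTR block, are *excluded*
and logged rather than erroring. A site is on-element when it falls in
`[genoStart, genoEnd + polyA_max_extension)` on the element's sense side
(mirrored on `-`), and with `sense_only = TRUE` only elements matching the
transcript strand count.

Percentages are site-count weighted by default (the published figures are
site counts); abundance weighting is an option. Headline figures round
half-up to integers, TSV output keeps one decimal.

## The synthetic world

The study's inputs are not desk-reproducible: the RNA-seq of 30 macaques is
unpublished and the UCSC table versions drift. The generator therefore
emulates all four inputs with planted ground truth:

* 2 chromosomes x 1 Mb, 20 genes on a 20 kb grid (no cross-gene overlap),
  1-5 exons; UTRs 350-500 bp, terminal-exon CDS share 300-450 bp, middle
  exons 600-900 bp, introns 400-700 bp. These margins guarantee that every
  planted element (280-310 bp, the natural Alu length range) fits its
  category unambiguously -- e.g. an `ORF_END` plant covers the last coding
  base without reaching the terminal base.
* Repeat records fill the consensus fields consistently on both strands,
  exercising the rmsk sign convention end to end.
* `fig7_preset()` plants 100 polyadenylation sites across four genes that
  each carry a sense AluYRa1 spanning the 3'UTR terminus: 40 on the poly-A
  tail, 34 in the A-rich linker, 26 off-element -- the published headline
  composition (74% on-element; 40% tail, 34% A-rich) reconstructed as a
  planted fixture.
* One representative site per gene gets its cleavage context written into
  the genome FASTA (sense-strand CA at the cut, AATAAA ~25 bp upstream);
  planted sites sit a few bases apart, so per-site contexts would
  overwrite each other.

Everything is drawn from a single seeded stream; one seed, one byte pattern.

What the generator does **not** emulate: sequence divergence and indels
between copies and consensus (so the affine consensus map is exact here and
approximate in nature), overlapping or nested repeats, fragmented elements
split across rmsk rows, alternative isoforms per gene, annotation errors. A
green planted-recovery test therefore establishes that the code computes the
stated definitions correctly -- not that a particular database version
yields particular counts.

The published headline counts (ten 3'UTR-end AluYRa1 genes, 72 SINEs, the
Fig. 5 bar heights, and the 74/40/34 percentages from 30 animals) depend on
specific macFas5/rheMac/hg table versions and unpublished reads; they are
used here as planted compositions and worked examples, not as quantities
re-derivable from public inputs.

## Numerical and design choices

* "Similar" 3'UTR length across species: relative difference <= 10%
  (configurable); the source text calls lengths similar without a number.
  The verdict compares the first listed species against the second.
* 3'UTR length is the *spliced* length (sum of exonic UTR bases), not the
  genomic span; printed lengths elsewhere may be either, which is why the
  comparison utility takes a tolerance.
* Isoform selection for gene-level joins: longest registered (`NM_`)
  isoform, falling back to predicted (`XM_`) ones.
* TAPAS multi-site delimiter is unspecified upstream: the reader accepts
  comma and whitespace, the writer emits comma.
* Ties between multiple elements containing one APA site go to the
  leftmost (smallest `genoStart`); the fixtures plant one element per gene
  so the tie-break never fires there.
* All writes are atomic (temp file then rename); the CLI writes a
  deterministic manifest (no timestamps), so identical invocations produce
  byte-identical artifact sets.

## Validating against real tables

The desk-scale suite never downloads anything. To reproduce the real-table
inventory, fetch `refGene.txt.gz` and `rmsk.txt.gz` for macFas5 from the
UCSC goldenPath database dumps and run:

```{r, eval = FALSE}
reps <- read_rmsk("rmsk.txt.gz")
models <- transcript_models(read_genepred("refGene.txt.gz"))
calls <- locate_all(reps, models, rep_name = "AluYRa1")
gene_inventory(calls, category = "UTR3_END", rep_name = "AluYRa1",
               accession_classes = "NM")
```

With the table versions used in the original analysis the registered-gene
inventory contains TK2, PEX26, GTPBP4, IRF9, BLOC1S6, UBE2B and PAICS;
table-version drift may add or remove entries, which is precisely why the
acceptance tests are property-based and planted rather than count-based.

## Known limitations

* One call per repeat x transcript pair: a repeat inside two overlapping
  genes is reported against both, and deduplication is by gene symbol only
  (no ortholog mapping; cross-species comparison joins on user-supplied
  shared symbols).
* The consensus map is affine; for heavily diverged or fragmented copies
  the anatomical region near boundaries can be off by the indel budget.
* TAPAS itself (APA detection from read coverage) is out of scope; only
  its output format is consumed.
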