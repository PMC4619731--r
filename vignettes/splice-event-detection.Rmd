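---
title: "Detecting and classifying splice events from alignment gaps"
author: "spliceGaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying splice events from alignment gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceGaps)
```

## The problem and the model

Targeted analysis of alternative splicing (AS) in a single deeply covered
gene — the motivating case is *HTT*, where rare alternative isoforms sit
under a canonical transcript three orders of magnitude more abundant —
needs no isoform deconvolution model. Each spliced read alignment is
direct, countable evidence of one or more splice junctions. spliceGaps
makes that evidence the unit of analysis:

* A **splicing event** is a contiguous gap between reference-aligned
  blocks of one read alignment, of length strictly greater than 9 nt
  (`min_gap = 10`). Blocks are the maximal runs of aligned bases
  (CIGAR `M`/`=`/`X`); both skip (`N`) and deletion (`D`) operations
  separate blocks, because aligners can encode short true gaps as
  deletions and the event is defined on the resulting reference gap, not
  on the operation code. Adjacent gap operations (e.g. `N` then `D`)
  merge into one contiguous gap; insertions and clips do not advance the
  reference and never split a gap.
* **Support** of a junction is the number of read alignments containing
  that exact gap (`gap_start`, `gap_end` both identical). Each mate of a
  pair counts independently — the unit is the read alignment, not the
  fragment — so a fragment whose two mates both span a junction
  contributes 2. Events with superset support below `min_support = 10`
  are discarded; the threshold applies to the pooled superset of all
  samples, never per condition.
* **Coverage** is profiled per feature — the alternating exons and
  introns of the canonical transcript — by assigning every aligned base
  to the unique feature containing it (reads are split across feature
  boundaries; gapped positions contribute nothing). Per-condition totals
  are divided first by feature length, then by the number of samples in
  the condition. With per-condition constants the two steps commute; the
  order is fixed for documentation's sake.

All user-facing junction coordinates are 1-based inclusive positions of
the first and last gapped base (the convention of STAR's `SJ.out.tab`).
Internally the package uses 1-based closed `IRanges`, the native
Bioconductor convention; BED input/output converts to 0-based half-open
at the file boundary only. This is stated prominently because published
junction tables rarely state their convention, and a ±1 offset at either
end changes exact-match classification.

## The classification cascade

Classification compares each junction with the canonical junction set
derived from one canonical transcript (one junction per intron). The
cascade is total and deterministic; the first matching rule wins:

1. **Canonical** — exact coordinate match.
2. **SkippedExon** — `gap_start` matches the start of canonical junction
   *i* and `gap_end` the end of a different canonical junction *j*: the
   event splices a canonical donor to a downstream canonical acceptor.
   Skipped exons are the exons wholly contained in the gap, reported by
   transcription-order index.
3. **AddedExon** — one end on a canonical splice site, the other
   strictly inside the same intron, *and* a reciprocal partner junction
   in the classified set closes a novel internal exon of width ≥ 1
   between them. Both partners are labeled.
4. **Acceptor / Donor** — exactly one end shared with a canonical
   junction; the label names the novel end, strand-aware (the donor is
   the 5′ side of the gap: `gap_start` on `+`, `gap_end` on `-`).
5. **Composite** — neither end canonical. Reported as `Acceptor` with
   both novel-end contexts recorded in `notes`, rather than a sixth
   category, to keep the label set closed.

`novel_end_context` records whether a novel end falls in an annotated
exon or intron; a position outside the gene span takes the context of
the nearest (terminal exon) feature.

Two deliberate degradations follow from demanding coordinate-level
evidence:

* An added-exon junction **without** its reciprocal partner is
  indistinguishable from novel acceptor/donor use inside the intron, and
  reports as `Acceptor`/`Donor` with `novel_end_context = "intronic"`.
  Published "added exon" labels often rest on prior isoform knowledge
  (e.g. the *HTT* 41b exon); the cascade refuses to guess.
* A skipped exon whose far-side canonical junction is **absent from the
  reference** (as happens when the reference is induced from a partial
  junction table rather than a full annotation) reports as an
  `Acceptor`/`Donor` whose novel end lies beyond the matched canonical
  junction. With a complete annotation, rule 2 applies directly.

Mirror symmetry pins down the strand handling: reflecting all
coordinates through a pivot while keeping the annotated strand swaps
`Acceptor` and `Donor` (the two gap ends exchange donor/acceptor roles);
reflecting *and* flipping the strand is the same gene read backwards and
preserves every label. Both properties are tested.

**Loci.** Events are grouped by single-linkage overlap of their gap
intervals (`pad = 0` by default; padding is exposed because no standard
rule exists). Junction clusters separated by even a few bases form
separate loci under `pad = 0` — a published locus that visually spans
two nearby clusters may therefore count as two.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `min_gap` | 10 | nt | gaps > 9 nt are treated as splicing; shorter gaps are indels |
| `min_support` | 10 | reads | superset support floor for reporting an event |
| `min_mapq` | 0 | — | no mapping-quality filter; configurable |
| `pad` | 0 | nt | locus grouping pads junction intervals before overlap |
| `anchor` | 8 | nt | width of the two BED blocks flanking the gap |
| `read_length` | 101 | nt | mate length of the emulated library |
| `frag_mean`, `frag_sd` | 300, 50 | nt | fragment length (truncated rounded normal) |
| `three_prime_bias` | 5e-4 | 1/nt | exponential decay of fragment 3′-end weight with distance from the transcript 3′ end |

The 3′-bias default corresponds to a 2 kb decay length — a moderate
poly-A selection skew that leaves 5′ junctions of a ~3 kb transcript
detectable while making the downstream coverage gradient obvious. Region
filtering keeps any primary alignment *overlapping* the region (reads
crossing the boundary are kept whole; coverage binning clips to
features). Duplicate marking is ignored, and the same file listed under
two sample ids is counted twice: collection building is deliberately
literal.

## What the simulator emulates — and what it does not

`simulate_reads()` draws, per fragment: an isoform by mixture weight; a
fragment length from a rounded normal truncated (by resampling, i.e.
renormalization) to `[read_length, transcript length]`; a 3′-end
position with weight `exp(-λ · distance from 3′ end)` in transcript
coordinates (λ = 0 gives uniform start positions); and emits two mates
whose reference block structure is the isoform's splicing projected onto
the genome, as coordinate-sorted SAM. A single root seed fans out into
per-sample seeds, and identical seeds give byte-identical SAM.

The default study design (`toy_sim_config()`) is three condition groups
of unequal size (2, 2, 4 samples) over a 10-exon toy gene whose five
alternative isoforms (canonical weight 0.90, 0.02 each) produce six
event loci: intronic- and exonic-end alternative acceptors, an
alternative donor, a single and a double exon skip, and a reciprocal
added-exon pair. An optional unspliced isoform models pre-mRNA
background: it raises intron coverage without creating any junction,
the same signature that makes real intronic reads ambiguous between
retained introns and nascent transcription.

`truth_set()` computes, exactly under this generative model, the
expected support of every junction with its exact standard deviation
(the per-fragment span count takes values 0/1/2; both moments are
enumerated over the fragment-length × position grid), and expected
aligned bases per feature, whose dispersion uses the conservative bound
Var(X) ≤ 2·read_length·E(X). Recovery tests run at 3σ against these.

Two consequences of the model are worth knowing when reading results:

* **Terminal-exon falloff.** Coverage ramps down within about one
  fragment length of the transcript 3′ end, because no fragment can
  start beyond the poly-A site. The analytic expectation itself
  decreases at the last exon even under strong 3′ bias, so the
  "coverage non-decreasing toward 3′" behavior holds for interior
  exons; real poly-A libraries show the same edge.
* **No error model.** Alignments are emitted directly — no sequencing
  errors, soft clips, or mismapping. Passing recovery tests therefore
  demonstrates correctness of extraction, aggregation, classification
  and normalization, not robustness to alignment noise: on real data,
  spurious gaps from misalignment are controlled only by `min_support`.

The simulator also does not model GC bias, duplicates, or minus-strand
genes (the classifier is fully strand-aware; the generator currently
requires a plus-strand model, which the mirror-symmetry tests cover for
classification).

## Numerical and degenerate-input choices

* All outputs are sorted by (`gap_start`, `gap_end`); locus ids are
  assigned in coordinate order — the only tie-break anywhere.
* Empty inputs flow through: an empty sample sheet gives an empty
  collection; an alignment file with no reads yields an empty event
  table and a zero-filled coverage table, not an error.
* A single-block record yields no gaps; mixed-chromosome collections
  are an error, as are overlapping features, unindexed BAM under region
  query, a threshold below 1, and a transcript shorter than the read
  length.
* Junction BED records place two `anchor`-width blocks strictly
  flanking the gap, so parsing the BED recovers (`gap_start`,
  `gap_end`) exactly and `chromStart + blockStarts[last] +
  blockSizes[last] = chromEnd` holds for every record. Scores cap at
  1000 per the BED specification.
* The validation suite runs the full design at 20,000 fragments ×
  8 samples (160,000 fragments, ~320,000 mates) once and reuses it
  across conservation, recovery and bias tests; unit tests use
  hundreds-to-thousands of reads.

## Known limitations

* One canonical transcript defines the reference; multi-isoform
  references and whole-genome scans are out of scope.
* No differential splice-usage testing between conditions — per-condition
  supports and coverages are reported, but cross-library normalization
  for such comparisons is an open problem the package does not take a
  position on.
* Intron-retention frequency is not estimated: with ~300 nt fragments
  and 101 nt reads, intronic coverage cannot be attributed between
  retained introns and pre-mRNA, as the unspliced-isoform simulations
  make concrete.
* The composite (rule 5) label is a reporting convention, not a claim
  that the event is an acceptor; consult `notes` for both ends.
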