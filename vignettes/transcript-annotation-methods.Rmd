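---
title: "Annotating transcript boundaries, splicing and novel transcription in compact genomes"
author: "scvannotate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating transcript boundaries, splicing and novel transcription in compact genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scvannotate)
```

# Scope and model

`scvannotate` turns collections of per-sample, assembler-derived transcript
predictions into a single reliable transcript-level annotation of a compact
(gene-dense) genome, and layers splicing, novel-transcription and chromatin
summaries on top. The package operates downstream of read alignment,
transcript assembly and junction discovery: its inputs are the *outputs* of
those tools (GTF predictions with per-transcript average coverage, BED
junction files, bedGraph coverage, count tables), never reads.

The central assumption is simple: for a given gene, the higher the average
read coverage of an assembled transcript, the more trustworthy its
boundaries. Boundary errors in assemblies are dominated by coverage gaps
and spurious read-through, both of which shrink as expression rises. The
selection scheme (Successive Coverage Values, SCV) therefore keeps, per
gene, only the predictions whose coverage clears the most restrictive
threshold of a discrete ladder that any prediction for that gene clears.

## Assignment

A prediction is assigned to a gene only if its span fully contains the
gene's CDS span, intersects no other CDS, and is strand-compatible.
Containment is on the genomic span, not base-by-base exon coverage: a
transcript retaining an intron still "fully covers" its CDS, which is
necessary for intron-retention calling downstream to make sense.
Unstranded predictions (two of the three emulated dataset types are
unstranded) are compatible with either strand and inherit the gene's
orientation once assigned. Predictions touching two CDS — the read-through
hazard specific to compact genomes — are never assigned; together with
intergenic and antisense predictions they form the unassigned pool mined
later for novel transcripts.

## Selection and gene models

The threshold ladder spans 10 to 20,000 reads of average coverage. Only the
range is fixed by the method; the intermediate rungs are a configuration
choice, with default `(10, 20, 50, 100, 200, 500, 1000, 2000, 5000, 10000,
20000)` — roughly logarithmic, matching the dynamics of expression.
Comparison is inclusive (`>=`): a coverage exactly at a rung passes. This
is a documented dialect choice; the boundary case is exercised explicitly
in the tests. A gene whose predictions all fall below the smallest rung
receives no model rather than a bad one.

From the selected set the gene model records every distinct TSS and TES
coordinate with its supporting (sample, dataset) pairs, the per-transcript
UTR intervals (5′UTR = `[TSS, cds_start-1]` on +, mirrored on −), the
longest UTR pair, and a multiplicity class: `single`, `multi_TSS_only`,
`multi_TES_only` or `multi_both`. Distinct boundaries are distinct exact
coordinates by default; `merge_bp` optionally clusters boundaries within N
bp (representative = the position supported by the highest coverage),
because no tolerance is inherent to the method. Summaries split genes by
multiplicity class — a gene supported identically by five samples is still
a "single transcript" gene — and pool distinct UTR intervals for
multi-boundary genes.

# Splicing

## Junction events

Junction confidence requires presence in at least 2 independent samples
*and* support of at least 5 reads in at least one — replication guards
against sample-specific artifacts, the support floor against barely-covered
junctions. Both parameters are exposed (`min_samples`, `min_cov`).
Junctions are attached to genes by containment within the model span;
junctions spanning two gene models are discarded with a warning.

Within a gene, events are defined strand-aware on the coding strand: two
passing junctions sharing the acceptor-side coordinate and differing at the
donor side form an A5SS event, the converse an A3SS event. Exon skipping
requires a passing junction that strictly contains an annotated exon of the
gene's selected transcripts *and*, by default, that both flanking inclusion
junctions of that exon also pass (`require_inclusion = FALSE` relaxes to
the skipping junction alone). Purely novel cassette exons are out of scope;
classification is always against the annotation.

One design decision deserves emphasis: junctions that strictly contain an
annotated exon are treated as skipping junctions and excluded from
A5SS/A3SS pairing. A skipping junction shares its donor with one inclusion
junction and its acceptor with the other, so without this rule every real
ES event would additionally emit one spurious A5SS and one spurious A3SS
call. The exclusion keeps the three junction classes disjoint, which the
recovery tests verify (planted events are recovered at recall = precision
= 1).

## Intron retention

Intron retention is called per (intron, sample) from binned coverage:
the intron is segmented into consecutive 8-bp bins (the final partial bin
included by default; a flag drops it), and the call requires all four of

* mean per-bin coverage M **>** T1 = 30 (the intron is actually covered),
* population SD of per-bin coverages S **<** T2 = 20 (covered *evenly* —
  a spliced intron with residual edge signal is jagged),
* CDS read count E **>** T3 = 200 (the host gene is expressed enough for
  the ratio to be meaningful),
* M / Ê **>** T4 = 0.1 (retention is a sizable fraction of host
  expression).

All four inequalities are strict; a profile exactly at any gate is
rejected, and an epsilon across it flips the call — the tests pin this
behaviour on a grid straddling all four gates. SD is the population SD
(divide by n); a single-bin intron has SD 0 by definition.

The ratio denominator Ê mixes dimensions in its plainest reading: M is a
per-base-scale quantity while E is a read count, so the literal ratio
shrinks with read length and CDS length. The default
(`ratio_mode = "scaled"`) therefore uses Ê = E × read_length / CDS_length —
the mean per-base CDS coverage — making T4 length-invariant;
`ratio_mode = "raw-count"` reproduces the literal count denominator for
compatibility. The packaged fixture `inst/extdata/ir_control_synthetic/`
encodes the canonical positive-control shape — one intron covered flat at
45× in exactly two of six samples — and must be called retained in exactly
those two.

IR calls are reported per sample with a sample-count column; no cross-sample
replication is imposed (unlike junction events), since the per-sample gates
are already conservative.

# Novel transcription

Unassigned predictions with average coverage of at least 10 (inclusive)
that intersect *no* annotated feature are novel transcriptionally active
regions; those intersecting a feature without having been assignable are
reported separately as partial overlaps, never as class "none". The feature
set defaults to the CDS intervals of the supplied annotation and is
configurable (UTRs from the models, pseudogenes, repeats, rRNA), because
annotation completeness varies. Nested and overlapping nTARs merge into
non-overlapping intervals (coverage = max, samples = union); merging is
idempotent and respects strand for stranded records while unstranded
records merge per chromosome. A nTAR is spliced iff a junction lies fully
inside it. Counts both before and after merging are available
(`ntar_candidates` vs `ntars` in the pipeline result).

Antisense transcripts require strand-specific data: unstranded input is
rejected with an explanatory error. A NAT is a stranded prediction whose
span intersects exactly one CDS, on the opposite strand; the same ≥ 10
coverage floor applies by default (`min_cov = 0` disables it, since no
floor is inherent to the definition). Sense predictions and predictions
touching two CDS are never NATs, and the generator plants both as negative
controls.

# Chromatin metaprofiles

The metaprofile averages an already-normalized signal track (e.g. BPM) in
10-bp bins over ±1 kb around each gene's representative TSS, orienting
windows so upstream is left for both strands, then averages bins across the
gene set; bins extending past a chromosome end are excluded from the mean.
Per-gene-then-per-bin averaging (rather than read pooling) was chosen so
highly covered genes do not dominate the profile. For multi-TSS genes the
representative TSS is the mean of the TSS set rounded toward the CDS — the
"average TSS" is otherwise undefined. Gene sets default to the 800 most and
800 least expressed genes in a chosen sample, with lexicographic
tie-breaking so the selection is deterministic. Constant signal yields an
exactly flat profile at the constant, and the profile is invariant under
genome mirroring; both properties are tested.

# The synthetic-data generator

`simulate_transcriptome()` emulates the study conditions end to end: a
4-chromosome genome of 2000 genes with mean CDS length 1483 bp, mean
intergenic spacing 1581 bp, 1.49 introns per gene of mean length 80 bp, and
mean UTR sizes 275 bp (5′) and 303 bp (3′); six samples in three datasets
(A, B, C) of which B is strand-specific, matching the mixed
stranded/unstranded composition of public fungal RNA-seq compendia. Each
gene is emitted by 2–6 samples. Alternative TSS/TES are planted per gene
with probability 0.25 each (giving ~44% multi-boundary genes), appear in
exactly one designated sample — emulating condition-specific alternative
transcripts — and sit a jittered ~156 bp (TSS) / ~114 bp (TES) from the
primary boundary. Event rates (A3SS 0.08 > A5SS 0.05 > IR 0.05 > ES 0.03
per intron-bearing gene) preserve the observed ordering of event-type
prevalences. Sixty intergenic transcripts (a third planted as overlapping
pairs that must merge, half spliced) and forty antisense transcripts
complete the plant.

Two modelling choices matter for interpreting test results:

* **Coverage is assembly-level, not read-level.** Every consumer in the
  pipeline works from assembly summaries (average coverage, binned
  tracks), so transcript coverages are drawn directly — log-uniformly
  across the SCV ladder — rather than simulated from reads. Sequence
  content (promoter motifs, splice-site consensus) is not modelled at all.
* **Per-gene coverages stay within one ladder rung.** All of a gene's
  predictions draw their coverage from the same rung, so SCV retains all
  of them and the planted boundary set is exactly the recoverable set.
  This defines the noiseless study condition under which recall and
  precision of 1.0 are the correct expectation; `jitter_sd > 0` perturbs
  boundaries to break it deliberately. Consequently, passing recovery
  tests demonstrate the pipeline's bookkeeping is exact — they do not
  demonstrate robustness to assembler boundary noise, coverage
  heterogeneity across samples of one gene, or overlapping gene models,
  which real data exhibit.

Negative controls are systematic one-criterion violations: junctions in a
single sample with high support, junctions in two samples all below the
support floor, intron profiles exactly at T1, jagged profiles failing only
T2, under-expressed hosts failing only T3, over-expressed hosts failing
only T4, sense partial overlaps, and antisense two-gene spanners. Each must
be rejected for exactly its own reason, which keeps the threshold tests
meaningful rather than vacuous.

Everything is deterministic under `seed`; coverage tracks carry exon and
intron signal only (planted novel transcripts are not painted into the
tracks, which only the IR caller and metaprofiles read).

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout; BED (0-based half-open) is
  converted only at the I/O boundary, with a fixed fixture pair pinning the
  convention.
* Threshold comparisons: SCV inclusive (`>=`), nTAR floor inclusive
  (`>=`), IR gates strict (`>`/`<`) — each matching its stated definition
  and tested at the boundary.
* Epsilon-negative coverage values arising from floating-point summation in
  weighted coverage construction (magnitude < 1e-6) are clamped to zero.
* Empty inputs return empty, well-typed results rather than errors
  (empty prediction files, genes without junctions, empty nTAR sets);
  configuration errors (empty ladder, unstranded input to NAT calling,
  infeasible simulation requests) fail fast with explanatory messages.
* Promoter windows truncate at chromosome edges with a warning rather than
  failing, and minus-strand windows are reverse-complemented so output is
  always the coding-strand upstream sequence.

# Problem sizes used by the test suite

The shipped tests run the full boundary-recovery check on the default
2000-gene genome and the event-level checks on 300–400-gene genomes, sizes
at which every code path (all four event types, all negative-control kinds,
merging, both strands) is exercised many times over while the whole suite
stays comfortably interactive. The acceptance script re-simulates at the
same sizes from the seed it is given.

# Limitations

* SCV treats each prediction independently; when one sample assembles
  several isoforms of a gene they compete individually on coverage.
* Absolute gene counts from any particular real compendium are not
  reproducible here — they depend on the specific deposited samples and
  genome; the package's guarantees are property-level (oracle equivalence,
  exact recovery, filter correctness) on planted data.
* ES classification cannot discover unannotated cassette exons; IR calling
  needs per-base coverage and CDS counts, and inherits whatever
  normalization the count pipeline used.
* NAT detection is limited to strand-specific samples by construction, and
  the coverage floor applied to NATs is a package default, not part of the
  definition.
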