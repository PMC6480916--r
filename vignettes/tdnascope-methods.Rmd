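---
title: "tdnascope: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tdnascope: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

*Agrobacterium*-mediated transformation inserts a transfer DNA (T-DNA)
segment of a binary vector into plant genomes. Integration is captured
into chromosomal double-stranded breaks (DSBs) and repaired largely by
non-homologous end joining (NHEJ), and the outcome can be far messier
than a single clean insertion: several T-DNA fragments — arbitrarily
truncated, in arbitrary orientation — concatenate before or during
integration, and when the two ends of such a concatemer are captured by
breaks on *different* chromosomes the result is a reciprocal
translocation, with chromosome fragments lost along the way. Short reads
see only the immediate vector/genome junctions; long reads can traverse
an entire multi-fragment concatemer and its two genomic attachment
points.

tdnascope reconstructs these events from long reads of a mutant and a
control sample: insertion loci, the ordered/oriented fragment
composition of each concatemer, the chromosome fragment graph, the
repair signature at every junction (micro-homology, filler DNA, long
homology, blunt), and heterozygous/homozygous losses from depth. A
deterministic simulator plants known architectures so every stage can be
scored against an exact truth set.

# Conventions

* Internal coordinates are **1-based inclusive** (the IRanges/Biostrings
  convention; natural in R). Emitted PAF, BEDPE and bedGraph files are
  0-based half-open, as those formats require.
* A T-DNA fragment is written `(start, end)` in vector coordinates with
  `start > end` meaning reverse orientation.
* A junction *side* is `(source, position, orient)`: orient `+` means
  the joined segment lies left of the breakpoint in source-forward
  coordinates and ends at `position`; `-` means it starts there. The
  same convention is used by the generator's truth set and the
  breakpoint caller, so the two are directly comparable.
* **Junction coordinates include shared (homologous) bases on both
  sides.** A junction with *m* bases of homology has those bases written
  once in the joined molecule but counted in both adjacent fragments.
  This is the convention under which the published 4- and 6-fragment
  concatemers sum (as `sum(|end - start|)`) to exactly 11,279 and
  15,200 bp; the +1-inclusive convention would give 11,283 and 15,206.
  `concatemer_length()` implements the former.

# The simulator: a stated world

`build_reference()` draws i.i.d. random chromosomes at a target GC
(default 0.36, a typical broadleaf-tree genome average).
`synthetic_vector()` is an 11-kb random circular plasmid whose *border
coordinates* mirror the pGWB2-style layout (LB 10,509–10,524, RB
2,454–2,478, intact RB-to-LB T-DNA of 8,071 bp, inside the canonical
8,031–8,080 bp range); only coordinates, not base content, are modelled.

`plant_architecture()` realizes a list of events — insertions,
truncations, concatemer translocation bridges, bare translocations,
deletions — as two explicit haplotype sequence sets. Heterozygous events
go to haplotype 1 only (a primary transformant is hemizygous);
homozygous events to both. Each junction carries a repair-signature
specification:

* **micro-homology / long homology** — realized by *editing the source
  sequences* so the two sides genuinely share exactly *m* junction-
  adjacent bases, written once in the product. Random sequence cannot be
  asked to share bases; copying the right side's first *m* bases over
  the left side's last *m* (in the reference or vector itself) is the
  only way the classifier's flank-anchoring contract and the truth
  round-trip can both hold. Three accident classes are then broken by
  single-base edits: homopolymer-driven self-extension of the planted
  homology; and junction-slide ambiguity on either side (the source base
  just *past* the junction coinciding with the first written base after
  it, which would let maximal anchoring legitimately report *m*+1). The
  edits iterate to a fixpoint with a rotating base-choice order (so two
  constraints on one base cell cannot cycle), and every junction is then
  re-derived from the emitted haplotypes and verified against its
  specification before `plant_architecture()` returns. The function
  returns the edited reference/vector, which all downstream stages use.
* **filler** — inserted verbatim; flank bases are edited if the filler
  would extend either flank (which would misread as micro-homology:
  micro-homology wins by the package's parsimony precedence).
* **blunt** — nothing inserted, slide-ambiguity broken as above.

`simulate_reads()` samples read start positions uniformly per base
across both haplotypes (so a locus on both haplotypes receives the full
`mean_depth`, a heterozygous locus half), log-normal lengths (default
mean 12 kb, sd 6 kb, minimum 500 bp), random strand, and independent
per-base substitution/insertion/deletion errors (defaults 1%/0.5%/0.5%
— a gentle long-read error model, *not* a platform profile:
context-dependent indels, chimeras and adapters are out of scope). All
randomness flows from one integer seed; the same seed gives
byte-identical FASTQ. The per-read origin log makes the simulation its
own alignment oracle.

What a green test on this world does **not** establish: performance on
repetitive genomes (the reference is i.i.d. random, so 15-mer seeds are
essentially unique), on real error profiles, or on diverged
vector/genome homologies.

# The yl replica

`yl_replica_spec()` plants a scaled replica of the published mutant on
four chromosomes named Chr2, Chr8, Chr9, Chr11 (breakpoints at fixed
fractions of the chromosome length; vector coordinates verbatim):

```
Chr2   |----q1=====q2  del  q3=====q4-----|     (5 fragments)
der1   Chr2[1..q1] + T-DNA fragment (3000..9000)         IS1, truncation
der2   Chr8[1..r1] + TB + revcomp(Chr2[q1+1..q2])        bare TB junction
hom    Chr2[q2+1..q3] absent from BOTH haplotypes        TB->IS2, scaled 40 kb
der3   revcomp(Chr2[q3+1..q4]) + 4-fragment concatemer + Chr8[r2+1..]   IS2/IS4
der4   revcomp(Chr2[q4+1..])   + 6-fragment concatemer + Chr9[s1+1..]   IS3/IS5
Chr9   Chr9[1..s1] lost from haplotype 1                 heterozygous terminal loss
Chr11  intact RB..LB T-DNA at t1, 20-bp locus deletion   IS6, case 1
```

Six vector–genome insertion loci; the 4-fragment bridge uses
(9144,10320),(7240,2523),(2467,7239),(7919,7305) and the 6-fragment
bridge (9854,10334),(5396,2476),(9014,10354),(10404,8306),(4099,7239),
(7919,2697). Signatures: a 22-bp filler at the first bridge's genome
junction and a 3-bp filler at a vector junction of the second; 254-bp
homology at the 7239/7919 vector junction — which occurs *in both
concatemers*, so one vector edit (`v[6986..7239] :=
revcomp(v[7666..7919])`) realizes both, mirroring the joint report of
the two published long-homology junctions; 4–7-bp micro-homologies
elsewhere; blunt joins at TB, the deletion junction and the LB-side
insertion junction.

Design choices that were genuinely open, and how they were fixed:

* The published account of the derivative chromosomes is partly
  graphical and not fully consistent as text; the replica fixes one
  concrete karyotype that carries every documented feature (above) and
  keeps replica-Chr2 split into exactly five fragments.
* The homozygous interval is placed exactly between the TB and IS2
  breakpoints, so it adds no extra partition points: haplotype 1 loses
  it through the translocation structure, haplotype 2 through a simple
  interior deletion, reproducing "the wild-type locus cannot be
  amplified" homozygosity without a second rearranged haplotype.
* The size of the short deletion at the intact-insertion locus is
  unpublished; the replica uses a configurable 20 bp.
* Whether the two long-homology junctions each independently show
  254 bp is unknowable from the text; because both are the same vector
  join, the replica's single shared block reports 254 at both without
  asserting more.

# Alignment

`align_local()` is a deterministic seed–chain–extend aligner:
exact-match 15-mer seeds (repeat-capped at 64 occurrences),
single-linkage diagonal clustering, longest-increasing-subsequence
chaining, affine-gap dynamic programming between anchor blocks, and
banded x-drop extension at the ends. Scoring is fixed package-wide:
match +2, mismatch −4, gap open −4, extend −2 (a length-*L* gap costs
4 + 2(*L* − 1)); identity = matches / alignment columns. On small
instances the best local score is checked against an independent plain-R
Smith–Waterman oracle under the same scoring. The aligner is adequate at
a few percent error; it is not a general mapper (no mapping quality, no
spliced alignment, no high-error heuristics). `ingest_alignments()`
normalizes external PAF or text SAM to the same table, excluding
soft/hard clips from read intervals.

# Segmentation and breakpoints

A read from a rearranged region maps in pieces. `segment_read()` chooses
the maximal-scoring consistent subset of a read's alignments by dynamic
programming on the read axis. Overlaps on the read are *expected* at
homologous junctions — both sides claim the shared bases — so two
alignments may overlap up to half the shorter one; overlaps beyond
`overlap_tol` (30 bp) are charged to the chain score and trimmed at the
midpoint for the read-partition bookkeeping, while the **untrimmed**
target extents are retained. Breakpoint observations use the untrimmed
extents; that is what makes fragment coordinates at homologous junctions
come out at their full printed extent.

`call_breakpoints()` clusters observations by exact single linkage
(tolerance 20 bp on both sides, matching orients), keeps clusters with
three or more supporting reads, and takes per-side medians. Co-linear
same-source joins with a gap under 50 bp are discarded as
split-alignment artifacts. The implementation is checked against an
all-pairs union-find oracle.

Per-junction **consensus**: windows of ±600 bp around each supporting
read's junction boundary, orientation-normalized, offset-corrected
against a template by maximizing agreement over shifts up to ±40 bp
(reads traversing a junction in opposite directions place their
boundary on opposite sides of any filler, so the shift range must exceed
the longest filler plus endpoint wobble), then column-wise majority
vote; windows that align nowhere are excluded. The consensus is
re-anchored against the reference with 30-bp exact anchors, scanning
candidate coordinates from the most junction-ward extension inward
(an under-extended anchor of a homologous junction still matches, so
"first match from outside" is the correct maximal rule). This refines
junction coordinates to base precision and replaces the role Sanger
sequencing of junction amplicons plays in a wet-lab workflow.

Consensus reliability is gated before any coordinate is overwritten:
the mean column agreement must reach 0.95 and a majority of windows must
have contributed (with indel-dominated error most windows fail template
alignment and the "consensus" degenerates to a single raw read). An
accepted refinement must additionally be maximal — the source base just
past the junction must differ from the first written base after it, on
both sides — because a consensus error near the junction otherwise makes
the fully-extended anchor fail and the scan retreat past it, with the
skipped reference bases masquerading as filler. With substitution-only
errors the consensus is exact at 30x and every signature and coordinate
is recovered exactly; with indel errors junctions gate out to
"uncalled" and keep their cluster-median coordinates (exact in every
run we scored). A pileup/POA consensus would lift this limitation.

# Concatemers, graph, events

`reconstruct_concatemer()` walks from a genome–vector junction through
successive vector–vector junctions along supporting reads, choosing each
successor by maximal read support. Votes are conditioned on the read
containing the *previous* walk junction immediately before the current
one: the two published concatemers share one identical vector join
(7239→7919), and unconditioned votes would chimerize the two bridges at
that shared cluster. Forks with comparable support set an `ambiguous`
flag. One-ended walks (truncations) estimate the terminal fragment from
the supporting reads' maximal vector extent.

`build_fragment_graph()` partitions chromosomes at genome-side
breakpoints (merged within 100 bp, so the two ends of one break are one
partition point) into nodes named `ChrN-k`, with vector-bridged and bare
edges. `classify_events()` applies the DSB capture model: both genome
sides of one architecture at a single locus → intact insertion; one
genome side → truncation; two sides on different chromosomes or distant
loci → translocation. Bare genome–genome junctions are **deletions**
when co-linear on one chromosome and bare translocations otherwise; the
deletion case is an addition to the three-case model, needed because a
homozygous interior deletion produces exactly such a junction and is a
different phenomenon from a translocation.

# Depth and losses

`compute_depth()` bins aligned bases (1-kb bins by default).
`call_losses()` compares mutant and control:

* **Homozygous** losses are crisp — no mutant reads at all — and are
  called from runs of raw bins with ratio ≤ 0.1; boundaries are
  bin-accurate.
* **Heterozygous** losses sit at ratio ~0.5 where per-bin noise is
  large: a 12-kb read covers ~12 adjacent 1-kb bins, so bin depths are
  strongly correlated and naive band-runs (the obvious design) produce
  false calls and fragment true ones — we observed exactly that and
  redesigned. Heterozygous calling therefore uses a 25-bin rolling-mean
  ratio for run construction (only the *upper* band bound 0.65 breaks
  runs: a het region's smoothed ratio can legitimately wander below
  0.35, and "deeper loss than heterozygous" must not read as normal
  coverage), then requires a read-count z-test against equal coverage
  (|z| ≥ 3.5; effective read counts are depth × (W + L)/L). The
  operating point comes from variance arithmetic — ~6 independent
  smoothing windows per genome give a family-wise false-positive
  expectation well under one call across a 20-run experiment — and in
  20 seeded control-vs-control runs no call is made. Accepted regions
  are then grown outward to the coverage transition (smoothed ratio
  0.825, halfway between band and normal) before the ratio is measured,
  because detection-band truncation otherwise biases the measured ratio
  downward.
* Bins within about one read length of a called breakpoint are masked
  for ratio evidence (a derivative molecule's end produces a coverage
  ramp that mimics partial loss), but a masked bin with ~0 mutant depth
  stays visible so homozygous runs bounded by breakpoints keep exact
  boundaries. Bins with control depth below 10 are likewise masked.

GC-bias correction, HMM/CBS segmentation, duplications and inversions
are out of scope.

# Pipeline, reproducibility, scale

`run_pipeline()` chains the stages with per-stage logs and writes every
intermediate (PAF, segment TSV, junction TSV/BEDPE, consensus FASTA,
architecture/event JSON, depth TSV/bedGraph, loss BED, graph DOT) plus a
JSON + text report whose provenance block echoes every effective
parameter and the seed; identical config and seed give a byte-identical
report. The configuration file is JSON (`jsonlite`); no YAML parser is
assumed. `compare_to_truth()` scores junction precision/recall at the
clustering tolerance, per-architecture exact-fragment-list flags, and
loss-call overlap; truth junctions with identical sides (the shared
7239/7919 join) count once.

The replica's default scale is 4 × 500 kb. The test suite runs it at
4 × 200 kb — the smallest size the replica permits — and the 20-seed
depth properties on a dedicated single-chromosome world with the
replica's proportions (80-kb heterozygous terminal loss, 16-kb
homozygous interval on 200 kb), purely to stay inside CI time budgets;
breakpoint placement is proportional and vector coordinates fixed, so
the architecture and expected statistics are scale-invariant.

# Known limitations

* Signature calling is exact for substitution-only error at 30x;
  indel-dominated error needs a better consensus (see above).
* The simulator's reads are uniform with log-normal lengths; no
  coverage bias, chimeras or adapter artifacts.
* The aligner assumes near-unique seeds; heavily repetitive references
  would need repeat-aware chaining.
* Phasing of events across loci onto haplotypes is limited to the
  het/hom depth call.
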