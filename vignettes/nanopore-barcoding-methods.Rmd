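---
title: "Reference-guided consensus calling for nanopore DNA barcoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided consensus calling for nanopore DNA barcoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanobar)
```

## The problem

DNA barcoding identifies a specimen by sequencing a short standardized locus
(mitochondrial 16S rRNA or CO1 in vertebrates) and matching it against a
reference database. Portable nanopore sequencers make this possible in the
field, but early-chemistry 2D reads carry per-base error rates around 15-20%,
dominated by miscounted homopolymer runs. A single read is therefore useless
for species assignment at the few-percent divergence that separates related
species; the signal has to come from a consensus over many reads of the same
amplicon.

`nanobar` implements the complete workflow around that idea:

1. **Draft**: assemble a de novo draft consensus from the (2D-pass) reads by
   partial-order alignment (POA).
2. **Retrieve**: search a local barcode database with the draft and take the
   best hit.
3. **Realign**: semi-globally align all working reads to that hit.
4. **Vote**: call, at every reference position, the most frequent aligned
   nucleotide (the frequency consensus).
5. **Re-search**: identify the species with the polished consensus.

The crucial property of stage 4 is that the reference only provides a
*coordinate frame*: with even moderate coverage the reads outvote any
position where the retrieved reference differs from the sequenced molecule,
so a congeneric (not conspecific) reference still yields the correct final
sequence. The low-coverage fallback (below) is where the reference actively
fills in — precisely over homopolymer dropouts, which is what makes the
reference-guided stage more accurate than the de novo draft.

## The read error model

The simulator treats a read as a pass over the template:

* each template base is **deleted** with probability `p_del`, otherwise
  emitted and **substituted** with probability `p_mis` (uniform over the
  other three bases);
* after every template position, **insertions** of uniform random bases are
  added as a geometric run: each trial succeeds with probability `p_ins`, so
  multi-base insertions occur with the right tail behaviour and the expected
  number of inserted bases per position is `p_ins / (1 - p_ins)`;
* **homopolymer length errors** are applied at run granularity: each maximal
  template run of length $\ell \ge 2$ is, with probability
  $\min(1, h_0(\ell-1))$, lengthened or shortened by one base (fair coin).
  One dimensionless coefficient ($h_0$, default 0.05) thus produces the
  run-length-dependent coverage dips seen on real data, without inflating
  per-base rates elsewhere.

Two named profiles ship with the package: `"R7.4"` (`p_mis = 0.08`,
`p_ins = 0.04`, `p_del = 0.05`), matching the error decomposition reported
for early-chemistry 2D amplicon reads, and `"R9.4"` (`0.016 / 0.008 /
0.041`) for the later chemistry. These published components were measured
*through alignment* on real reads; using them as generative per-base rates
is an approximation, and realignment of simulated reads recovers slightly
different numbers (see *Error decomposition* below).

Reads are assigned a `pass`/`fail` tier (`pass_fraction`, default 0.3 —
roughly the 2D-pass yield of the early amplicon runs this emulates); fail
reads have all three rates multiplied by `fail_multiplier` (default 2.0 — a
free parameter, since the quality filter that defines the tiers is not a
published error model). Strand is random (`revcomp_fraction`, default 0.5)
and a uniform flowcell channel in `1..n_channels` is recorded as metadata.
Everything is driven by one integer seed; two runs with the same seed are
byte-identical.

What the generator does **not** emulate: chimeric reads, adapter/barcode
sequence, quality-score realism (qualities are tier-constant placeholders),
context-dependent substitution biases, and pore-state drift across a run.
Passing tests on these simulations therefore demonstrate the pipeline's
arithmetic and its robustness to the modelled error structure, not
performance on any particular real flowcell.

## Pairwise alignment

`semiglobal_align()` is an affine-gap (Gotoh) aligner with free end gaps on
the **reference only**: a read must align end-to-end, but may land anywhere
on the amplicon frame. This is deliberately not a local aligner — barcode
amplicon reads should span the reference, and free query ends would hide
read-end errors from the error decomposition. A gap of length $L$ costs
`gap_open + (L-1) * gap_extend`; defaults `(match, mismatch, open, extend) =
(+1, -1, -2, -1)` are a standard noisy-long-read choice and are
configurable everywhere. `N` scores as a mismatch against everything.

Tracebacks are deterministic. Ties place indels as late (3'-ward) on the
query as possible: entering a match/mismatch column, the predecessor-state
priority is insertion > deletion > match; within a gap, closing it beats
extending it; the final column prefers a match state and the smallest
reference end. So aligning `ACGGT` to `ACGT` yields `3=1I1=`, with the
inserted `G` reported after the run it extends. Percent identity is
BLAST-style: matches over *all* alignment columns, gap columns included —
stated here once and used consistently in every report.

The implementation is in C++ (via Rcpp); an independent brute-force oracle
(best global affine score over all reference substrings, plain R) verifies
scores exhaustively on short sequences in the test suite. An optional band
was considered and rejected: barcode-scale problems (reads and references
below ~1 kb) need no banding, and an unbanded matrix keeps the oracle
equivalence unconditional.

## Draft consensus by partial-order alignment

The draft stage collapses the overlap-correct-assemble chain used for
genome-scale long-read data into a single POA over full-length amplicon
reads. This is the package's largest deliberate simplification: a
single-locus amplicon has no assembly problem to solve, so overlap detection
and a genome assembler would add machinery without adding signal.

Reads (at most `max_reads = 200`, the first 200 after sorting by id) are
oriented against the first read, then fused one at a time into a DAG whose
nodes are bases and whose edge weights count read traversals. Each read is
aligned to the current graph by the same affine-gap contract as the pairwise
aligner, computed over a topological order with free end gaps on the graph
side. Equal-scoring predecessors resolve toward the heavier edge, so reads
pile onto the majority path rather than scattering across parallel branches;
a mismatching or inserted base reuses an existing branch node when one with
the same base already bridges the same neighbours.

Because the first read is as error-ridden as any, the pass-1 graph trunk is
a patchwork. The implementation therefore re-seeds: the pass-1 consensus
becomes a zero-weight trunk, all reads are fused against it, and the
consensus is re-extracted (iterated once more if it changed). Consensus
extraction itself is a heaviest-path dynamic program over edge weights with
two amendments found necessary in practice, both documented here because
they deviate from the naive "heaviest path by summed edge weight": each edge
pays a cost of 0.2 x the maximum edge weight, and the path may start/end
anywhere (local-segment semantics). Without the per-edge cost, a summed
heaviest path prefers a two-edge detour carrying 40% of the reads over a
direct edge carrying 45%, and always absorbs stray read-tail chains at the
termini; with it, detours pay for their extra step and weak termini drop
out. Node support breaks residual ties. On simulations at 100 x coverage of
a 300-bp template under the R7.4 profile, the draft is 99-100% identical to
the template across seeds — good enough for database retrieval, which is
all the draft is for.

## Pileup and the frequency consensus

`pileup_from_alignments()` walks each typed CIGAR and counts, per reference
position, the aligned `A/C/G/T` bases and deletions; insertions are counted
separately, keyed by the inter-position locus (number of reference bases
consumed before the inserted run). Coverage at a position is the sum of its
base and deletion counts.

`call_consensus()` then applies, per position:

* **coverage < `min_coverage`**: emit the reference base and flag the
  position. Emitting the reference rather than `N` is a deliberate choice:
  the dropouts concentrate over homopolymer runs, where a related-species
  reference is the best available estimate of the true run length. With
  `min_coverage = 1` (the default, appropriate for the low-yield field
  regime) this branch only triggers at zero coverage.
* **deletion modal with frequency > 0.5**: emit nothing. Exactly half is
  not enough — the call must be carried by a majority.
* otherwise emit the modal base; ties break toward the reference base
  (conservative, the pileup-caller convention), then alphabetically (for
  determinism when the reference itself is outvoted).

An insertion locus is emitted — its modal inserted sequence, lexicographic
tie-break — only when its total insertion count exceeds half the coverage
at the preceding position. Nanopore insertion noise is diffuse, so a strict
majority rule keeps the consensus parsimonious; the published descriptions
of frequency-matrix callers are silent on insertions, making this a design
decision of this package.

The per-position frequency of each called base is recorded
(`per_position_freq`, and the full matrix in the exported TSV); on real
data the minimum of that curve is the single most informative quality
statistic of a run, and the pipeline reports it rather than asserting any
particular value.

## Error decomposition and run analytics

`decompose_errors()` pools cigar events over all alignments:
mismatch/insertion/deletion percentages share one denominator, the total
aligned reference span, and the mean error is their exact sum. Pooling
(rather than averaging per-read ratios) is robust at low coverage; the
per-read table is attached for distributional plots. With the denominator
defined this way, the deletion component is directly comparable to a
per-reference-base deletion rate.

Simulating with the R7.4 generative rates and realigning recovers mismatch
~8.3%, insertion ~3.2%, deletion ~4.0%, mean ~15.4% (2,000 reads x 500 bp).
The indel components sit below their generative values because an optimal
aligner merges adjacent insertion-deletion pairs into single mismatch
columns and absorbs end-of-read deletions into the free reference end gaps;
the mismatch component is correspondingly slightly above 8%. This
reshuffling is inherent to *any* alignment-based error measurement — the
published error decompositions were produced the same way — and the
acceptance tolerances (±2 points on the mean, ±1.5 on mismatch) exist
precisely to cover it.

`coverage_vs_homopolymers()` compares mean coverage inside homopolymer runs
of length ≥ `min_run` against all other positions. Runs are annotated at
length ≥ 2 (the convention used when marking runs on coverage plots), but
the dip analysis defaults to `min_run = 4` because the simulator's — and
the chemistry's — length errors grow with run length and short runs dilute
the contrast; both thresholds appear in the outputs. With $h_0 = 0$ the
ratio is ~1; with $h_0 > 0$ it falls below 1. The direction is asserted in
tests, the magnitude only reported: it depends on run-length composition of
the template.

Run-count normalisation divides each raw yield (total / 2D / 2D-pass) by
the number of channels that produced reads — flowcells differ enormously in
health, so reads-per-channel is the comparable unit — and percentages are
of total reads. All rounding is **half-up** (241 from 240.58, 23.4 from
23.397), matching the printed run tables this reproduces; base R's
round-half-even would disagree on exact halves. Two published cells are
consistent only with truncation rather than half-up rounding and are
excluded from the test fixtures.

## Database search

`build_index()` hashes every k-mer occurrence (k = 11 by default) of every
database record; `search_db()` ranks candidates by shared-k-mer count taking
the better of the two query orientations, aligns the top 25 candidates with
`orient_and_align()`, and sorts hits by alignment score. For curated
barcode databases of $10^2$–$10^4$ records this outperforms heavier
indexing in simplicity and is exact enough that no E-value machinery is
warranted; ranking is by score, and the identity reported is over the full
semi-global alignment (gap-inclusive), which is stated in the report
because database-search identities elsewhere are often computed over
partial query coverage. Only one strand is indexed; searching both query
orientations instead halves index memory.

## Pipeline policy

The draft and realignment stages use 2D-pass reads only, falling back to
the whole read set when fewer than `min_pass = 20` pass reads exist — the
regime of low-yield field runs, where the pass tier is too thin to carry a
consensus. The same working set feeds both stages so the report's read
counts compose. The pipeline contains no random draws: rerunning with the
same inputs writes byte-identical consensus, tables and report (timings are
excluded from the report file for exactly this reason). Multi-run inputs
are assumed pre-merged by simple concatenation of read files.

## Problem sizes used in the tests

The test suite and the acceptance script size their simulations to what the
method actually needs to demonstrate: 900 reads of a 532-bp template for the
end-to-end rescue (the scale of the characterisation experiment it
re-enacts), 2,000 x 500 bp for rate recovery (Monte-Carlo error well below
the tolerances), 100-300 x 300 bp for stage-level properties, and 187
fail-tier reads for the field-regime fallback. Oracle equivalence runs on
exhaustively checkable lengths (≤ 8 bp, 200 random pairs).

## Known limitations

* The POA stage's heaviest-path amendments (per-edge cost, local-segment
  extraction) are pragmatic; a full aligned-column POA (ring merging) would
  remove duplicate parallel branches at the source and is the natural next
  step if draft accuracy ever becomes the bottleneck.
* Identity under joint reverse complement is exactly invariant in score but
  can differ by a fraction of a percentage point in identity, because
  co-optimal tracebacks need not have the same number of columns.
* The consensus caller is count-based and ignores base qualities by design
  (the callers it mirrors are count-based); quality-weighted voting is out
  of scope.
* Diploid/heterozygous calling, chimeras and demultiplexing are out of
  scope throughout.
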