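---
title: "Calling structural variants from linked reads by barcode-aware local assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling structural variants from linked reads by barcode-aware local assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svweave)
```

## The problem

Insertions and deletions of 50-10,000 bp sit in an awkward spot for variant
calling. Short-read callers lose sensitivity because a 150 bp read carries no
long-range information: an insertion longer than roughly twice the fragment
length leaves no contiguous sequence to anchor, and reads from repetitive
regions are placed ambiguously. High-coverage long reads resolve these events
well but remain expensive and demand high-quality input DNA.

Synthetic long-read (SLR) chemistries — stLFR, TELL-Seq, 10x linked reads —
offer a middle path. Input DNA is sheared into long fragments (5-100 kbp),
every short read derived from one fragment receives that fragment's barcode,
and the reads are sequenced on a standard short-read instrument. The barcode
is the long-range signal: reads sharing a barcode came from the same long
molecule, even the reads that failed to align.

`svweave` exploits this signal through *local assembly*. Rather than
assembling the whole genome, it tiles the reference into windows, decides per
window which barcodes' fragments truly span it, gathers those barcodes' reads
— including unmapped mates and poorly aligned pairs that a mapping-based
caller would discard — assembles the window de novo, and reads variants off
realignments of the contigs. Low-coverage long reads (e.g. 5x HiFi) can be
added to the window assemblies ("hybrid mode") to patch coverage holes that
short reads cannot bridge.

## Pipeline

1. **Recruited-read map.** One pass over the BAM collects *badly aligned
   pairs*: pairs where every base of both mates exceeds Phred 20 (so true
   sequencing junk is excluded) and at least one mate is unmapped, on an
   unplaced contig, soft-clipped over more than 20% of its length, or flagged
   `AM:i:0` by the aligner. These are exactly the reads displaced by SV
   breakpoints and novel sequence. They are stored keyed by barcode, so the
   set M(B) for any barcode list B is one lookup.

2. **Windows and barcode selection.** The reference is tiled into 50 kbp
   windows overlapping by 10 kbp. The overlap bounds the largest deletion
   that can be seen by a single window; events up to the overlap length are
   always fully contained in at least one window. A barcode enters a
   window's list B(s) when at least 3 of its read pairs align in the window
   and their aligned extent exceeds 5 kbp — a few spuriously mapped reads
   from a repeat cannot satisfy both.

3. **Gathering.** The window's read set is the union of (i) in-window
   primary alignments carrying a selected barcode, with out-of-window mates
   fetched by name, and (ii) M(B(s)), the recruited pairs of those barcodes
   wherever they sat in the file. In hybrid mode up to 100 long reads
   overlapping the window are added (first by coordinate; the cap bounds
   cost and is rarely binding below ~20x).

4. **Assembly.** A de Bruijn graph (k = 55) is built over the gathered
   reads. K-mers seen in fewer than two short reads are dropped; long-read
   k-mers are kept when corroborated by one short-read occurrence or a
   second long read, because even HiFi error rates flood a 55-mer spectrum
   with singletons. The graph is compacted to unitigs and simplified
   *conservatively*: only short (< k+10) coverage-1 dead-end tips, exact
   duplicate parallel unitigs, and bulge branches far below the
   heterozygous-coverage floor (25% of the length-weighted median unitig
   coverage) are removed. Balanced bulges are the two alleles of a
   heterozygous variant and must survive; long tips (>= 2k) are coverage
   drops, not errors, and also survive.

5. **Path extension and the tip rule.** Contigs are greedy unitig paths
   seeded from the longest unused unitigs. At a junction with several
   outgoing edges each branch is spelled through the shared flanks, so both
   alleles appear among the contigs. The dangerous case is a *coverage
   drop bridged by a repeat*: the repeat unitig connects the two sides of
   the hole, and the unique sequence adjacent to the hole dangles as long
   dead-end tips. Extending through such a junction spells a chimeric
   contig whose realignment reads as a deletion that does not exist. The
   tip rule refuses any extension — single-edge or fork — when a long
   dead-end tip (>= 2k) is incident at the junction or its immediate
   neighbours; the path ends there and is flagged. The vicinity radius is
   deliberately the smallest that blocks this topology: the extension
   target's two sides and the junction's other edges, excluding the path's
   own unitig and the target itself (otherwise every contig would refuse
   to enter the naturally dead-ended terminal unitig of its window).

6. **Gap closing (hybrid mode).** Window assemblies at modest coverage
   fragment where short-read k-mers are missing. A long read that anchors
   the tail of one contig and the head of another (>= 200 aligned bases per
   flank at >= 85% gap-compressed identity — thresholds a 1%-error HiFi
   read passes comfortably and random sequence essentially never) supports
   joining them, with the read itself spelling the gap. Joins are applied
   greedily by supporting-read count; each contig end joins at most once.

7. **Realignment and calling.** Each contig is aligned glocally (global in
   the contig, local in the reference) against its window padded by
   `max_sv_len + 2000` bp — the pad must exceed the largest deletion so
   that a contig assembled through an event that ends just inside the
   window still finds its true flanks. Small problems are solved by exact
   affine-gap DP (match +1, mismatch -4, gap open 6, extend 1); large
   contigs by seeding on window-unique 31-mers, collinear chaining with a
   capped gap penalty (so flank blocks across an SV-scale gap stay in the
   chain), and banded affine DP between adjacent anchors. Insertions and
   deletions of 50-10,000 bp are read off internal CIGAR operations; only
   events fully inside the window proper are emitted, since pad-zone
   junctions belong to a neighbouring window. Calls are left-aligned
   (standard VCF normalization — without it the same event discovered in
   two windows or on two haplotype contigs can sit at different shifted
   positions and the exact-key deduplication would miss it), deduplicated
   on (chrom, pos, type, length), sorted, and written as sequence-resolved
   VCF 4.2 with SVTYPE/SVLEN/END. Genotypes are emitted as `./.`:
   classifying homozygous versus heterozygous calls is out of scope.

## The simulator

`simulate_svs()` / `simulate_linked_reads()` / `simulate_long_reads()`
generate the fixtures every test runs on. The design mirrors an SLR
experiment: a random diploid genome with implanted indels (default size
mixture: Alu-like ~300 bp, L1-like ~6 kbp, STR-like motif multiples, and a
log-uniform component, clamped to [50, 9500]; implants non-overlapping and
>= 2 kbp apart), fragments of 5-100 kbp sheared uniformly — overhanging the
chromosome ends and truncated there, so coverage carries no artificial
edge ramp — one barcode per fragment (TELL-Seq-like; a
fragments-per-barcode knob emulates 10x-style collisions), read pairs
(2 x 150 bp, insert 350 +/- 50) sampled to ~0.2x coverage per fragment, and
long reads of 9,000-12,000 bp with a per-read error rate uniform in
[0.001, 0.01] (90% substitutions, 10% 1-bp indels).

Instead of requiring an external aligner, the simulator emits a
*truth-aligned* BAM: every read is placed at its reference-projected
coordinate; reads crossing an SV junction are soft-clipped at the junction
and tagged `AM:i:0` (a minimal emulation of an aligner failing to cluster
them with same-barcode reads); reads drawn entirely from inserted sequence
are unmapped. Two switches exist for targeted experiments: a coverage gap
(all pairs touching a reference interval are dropped) and planted identical
repeat copies, which together reproduce the repeat-bridged coverage-drop
topology that motivates the tip rule.

What the simulator does *not* emulate — and hence what passing tests do not
demonstrate about real data: aligner-specific placement errors, GC and
chimeric-fragment biases, real repeat families and segmental duplications,
barcode collisions under 10x chemistry defaults, and reference gaps. The
simulated background is random sequence, which is *easier* than a human
genome; the planted-repeat scenarios probe the repeat failure mode directly
but sparsely.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `segment_length` / `segment_overlap` | 50 kbp / 10 kbp | overlap bounds the largest detectable deletion; window size trades repeat content against assembly cost |
| `min_barcode_pairs`, `min_barcode_span` | 3, > 5 kbp | separates fragment-spanning barcodes from spurious repeat hits |
| `min_base_phred` | > 20, all bases | recruited reads must be misplaced, not low-quality |
| `max_softclip_fraction` | 0.20 | clips beyond this indicate a breakpoint, not adapter noise |
| `kmer_size` | 55 | single-k assembly; small enough for 150 bp reads at 30-40x, large enough to keep random 1 Mbp backgrounds repeat-free |
| `short_solid_min` | 2 | error k-mers are mostly singletons at 35-40x |
| `bulge_floor_frac` | 0.25 | het branches run ~50% of median coverage, error branches ~3% |
| `tip_vicinity_len`, `min_contig_len` | 2k | a tip longer than two k-mers of sequence is a coverage drop, not an error |
| `gap_anchor_len` / `gap_anchor_identity` | 200 bp / 0.85 | passed by 1%-error long reads, unreachable by chance |
| `match_distance` | 500 bp | benchmark breakpoint tolerance |
| `size_similarity` | 0.7 | benchmark size gate; set 0 for the pure distance criterion |

## Numerical and design choices

* Coordinates are 0-based half-open internally; conversion to 1-based
  happens once, at VCF writing.
* The assembly graph export is canonicalised (unitig orientation is the
  lexicographic minimum of a sequence and its reverse complement, unitigs
  sorted), so the graph is byte-identical under read reordering and contigs
  are deterministic; ties in path extension are broken by unitig order.
* Per-window work is seeded as a hash of the global seed and the window id,
  so results cannot depend on processing order.
* Matching in the evaluator is nearest-first greedy followed by
  augmenting-path repair. Pure greedy matching can be one short of the
  maximum (a call claims the only truth record its neighbour could have
  taken); the repair restores maximum cardinality while staying
  deterministic, which makes the evaluation insensitive to record order.
* Alignment identity is gap-compressed (a gap counts once, not per base);
  plain column identity would reject any contig carrying a real
  kilobase-scale insertion.
* Degenerate inputs: reads shorter than k give an empty graph and a
  warning; windows with no selected barcodes are recorded as `empty`; a
  failing window is isolated, and the run only errors if more than 10% of
  windows fail.

## Test-suite problem sizes

The acceptance suites run at desk scale, chosen to exercise every code path
while keeping the default test run to minutes: 20 replicates of a 1 Mbp
genome with ten homozygous events across the 60-9,500 bp size range at 40x
for exactness; 50 single-event heterozygous replicates (60 kbp) for
diploid retention; 50 repeat-flanked coverage-gap replicates (50 kbp),
each also run with the tip rule ablated to show the rule does the work;
and 50 paired hybrid replicates (90 kbp, three heterozygous events, 15x
linked reads, 5x long reads). Genome sizes for the latter suites are the
package's choice; the coverages, thresholds, and tolerances are the
pipeline's operating points described above.

## Known limitations

* Insertions and deletions only; no inversions, translocations, or
  duplication-type distinction, and no genotyping or phasing.
* Deletions longer than the window overlap (10 kbp by default) are
  invisible by construction.
* A single best contig alignment is used per contig; split-contig breakend
  calls are not composed.
* Nearby small gaps in one alignment are reported as separate events, not
  merged; recall on fragmented representations of one large insertion may
  differ from callers that merge.
* The mate-by-name lookup against a large position-sorted BAM is the known
  throughput bottleneck in streaming mode; the in-memory mode sidesteps it
  for inputs that fit.
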