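---
title: "isoweave: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isoweave: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoweave)
```

## The problem

De novo transcriptome assembly from short reads alone reconstructs
fragments well but struggles with alternatively spliced isoforms: at every
splice junction shared between isoforms the De Bruijn graph branches, and a
short-read assembler has no way to know which branch combinations co-occur
on one transcript. Long cDNA reads (nanopore-style) span transcripts end to
end and resolve exactly that phasing, but their ~10% error rate makes them
a poor substrate for base-accurate assembly on their own. isoweave combines
the two: the short reads supply an accurate unitig graph, and the long
reads supply paths through it.

## Pipeline

1. **De Bruijn graph** (`build_graph`). Edges are the k-mers (default
   k = 25) occurring at least `min_count` = 2 times in the short reads.
   Libraries are treated as strand-specific by default: under the dUTP
   convention mate 1 reads the antisense strand, so mate 1 is
   reverse-complemented (`orientation = "rf"`) and all k-mers live on the
   transcript sense strand. No canonicalization is applied. The
   non-stranded mode inserts both strands of every read instead of
   building a bidirected graph; downstream deduplication then treats a
   sequence and its reverse complement as one transcript. This gives the
   same observable output at a fraction of the implementation surface.

2. **Cleanup** (`simplify_graph`). Two standard rules iterate to a
   fixpoint: dead-end chains of at most `2k` edges with mean coverage
   below `cov_cutoff` are clipped (tips), and edges with coverage below
   `cov_cutoff` competing with a strictly higher-coverage alternative at
   either endpoint are dropped. The default `cov_cutoff` is 5: at the 50x
   depth regime this package targets, substitution errors recur often
   enough that error k-mers reach counts 2–4 and — since `min_count` = 2
   already floors retained counts at 2 — a cutoff of 2 would never fire.
   The parallel-alternative guard is what protects lowly expressed
   transcripts: their interior edges have no competing sibling edge and
   are kept regardless of coverage. Bubble popping proper (re-routing
   through the stronger branch) is deliberately not implemented; the
   long-read stage is robust to residual bubbles.

3. **Condensation** (`condense`). Maximal non-branching edge chains become
   unitigs; adjacent unitigs overlap by exactly k−1 bases. Condensation is
   idempotent, and the multiset of k-mers spelled by the unitigs equals
   the retained edge set.

4. **Full-length classification** (`detect_full_length`). A long read is
   full-length when both library adapters are found near its ends at
   ≥ 70% similarity, on either strand. Similarity is defined as
   (adapter_length − E) / adapter_length, where E is the edit distance of
   the best fitting (infix) alignment of the whole adapter inside a
   terminal window of 1.5 × adapter length; gaps count as errors. The
   threshold is evaluated in integer arithmetic
   (E ≤ ⌊len · (1 − min_similarity)⌋), so the 70% boundary is exactly
   inclusive: a 10 bp adapter with 3 mismatches passes, with 4 it fails.
   This is the strictest common reading of "70% similarity" that is also
   exactly computable; the test suite pins it against a brute-force
   minimum-Levenshtein-over-substrings oracle.

5. **Threading** (`thread_long_read`). Exact `anchor_k` = 13-mer matches
   between the (adapter-trimmed) read and the unitigs are merged into
   co-diagonal blocks and chained by dynamic programming. Two details
   matter on real graphs. First, adjacent unitigs share k−1 bases, so the
   same read region legitimately anchors to both sides of a junction; the
   chain scores a block only by the *new* read bases it covers beyond the
   current chain end, which makes chaining through redundant junction
   copies pointless (they gain nothing and pay the junction penalty).
   Second, a short unitig can receive no surviving anchors under 10%
   read error; a missing link in the chained unitig sequence is repaired
   by a bounded search (≤ 4 intermediates) for a connecting path whose
   spelled length matches the read gap, and otherwise the chain is
   truncated at the break, keeping the side covering more read bases.
   The aligned fraction is the chain footprint — per unitig segment, the
   span from first to last anchor — over the read length; reads below
   `min_aligned_fraction` = 0.5 are dropped, mirroring the tolerance of
   unmappable long reads in this kind of pipeline. Ties in the chain DP
   break toward the leftmost read coordinate, so threading is
   deterministic.

6. **Path extension** (`extend_paths`). Every unitig seeds a path. At a
   branch, *every* outgoing edge supported by at least `min_support` = 1
   phase-consistent long-read subpath spawns its own continuation — this
   multi-edge rule is what reconstructs alternative isoforms as separate
   paths rather than collapsing them into one consensus walk. Support is
   phase-consistent: a read supports extending path P with unitig v only
   if the read's chain contains the junction and the chain segment before
   it agrees with P's tail, which prevents two adjacent bubbles from
   cross-multiplying into chimeric paths. A junction with no long-read
   support falls back to the short-read-only rule: stop. In a condensed
   graph every link sits at a branch point, so the short-read-only
   baseline emits exactly the unitigs — the simplest defensible baseline,
   which makes the hybrid-vs-SR contrast attributable to long-read
   evidence alone. Extension also stops at a visited-step budget (10,000)
   and a per-seed fan-out cap (64) to guard against repeat-dense corner
   cases. `min_support` = 1 reflects the ~2x long-read depth this design
   targets: demanding more support would discard most of the evidence.

7. **Full-length injection and deduplication**. Paths threaded from
   full-length reads are added to the candidate set directly (marked
   full-length, no filtering beyond graph validity); non-full-length read
   paths contribute extension support but are not injected. Paths whose
   spelled sequences are identical collapse to one representative
   (highest support, then longest step chain, then lexicographically
   smallest id chain — deterministic), and the survivor inherits the
   full-length flag of its group. Deduplication keys on the spelled
   sequence, not the step list, because distinct step chains can spell
   identical sequences. Transcripts shorter than `min_output_len` =
   200 bp are dropped.

## The simulator

`make_transcriptome` builds genes as alternating random exons (80–300 bp)
and introns (60–200 bp); each additional isoform differs from the primary
by one sampled event — exon skipping, intron retention, alternative donor
(exon end extended ≥ 10 bp into the downstream intron) or alternative
acceptor. The default event mix (0.15 / 0.35 / 0.25 / 0.25) leans toward
intron retention and alternate-site events, the profile typical of plant
transcriptomes. Expression weights are log-normal (meanlog 0, sdlog 1), so
lowly expressed isoforms — the classic short-read failure mode — exist by
construction. Infeasible configurations (an event requested with too few
exons) raise errors rather than degrade silently.

`simulate_short_reads` emulates strand-specific 150 bp paired-end
sequencing at 50x with 0.5% i.i.d. substitutions and normal insert sizes
(300 ± 30 bp). Fragments are pieces of complete cDNA molecules, so the
sampling window may overhang a molecule end (keeping at least a
read-length of overlap) and is clamped to it: terminal fragments are
truncated at the molecule boundary, exactly as physical fragmentation
produces them. Without this boundary handling the first and last k-mers of
a transcript would almost never be sequenced and no assembler could
recover transcript ends exactly.

`simulate_long_reads` draws reads proportional to weight × length until
2x coverage. A read is full-length with probability 0.93 — carrying both
24 bp adapters — and is otherwise truncated uniformly from one end,
losing that end's adapter. Errors hit adapters and insert alike at 10%
per base, split 40/30/30 across mismatch/insertion/deletion
(indel-dominated, nanopore-like). The error rate is a package choice: the
emulated regime reports read length and full-length statistics but no
error estimate. Flat Phred qualities are emitted; quality-score realism,
chimeras and polyA tails are out of scope.

All simulators are pure functions of (inputs, seed); module streams are
derived from the run seed so the stages are independently reproducible.
Ground truth (isoform FASTA, exon/weight TSV with 0-based half-open
coordinates, long-read truth table) is always written beside the reads.

What passing tests on these simulations do **not** show: robustness to
chimeric reads, polyA tails, sequence-specific error hotspots, uneven
3'/5' coverage bias, or genome-scale repeat families. The simulator's
genes are mutually unrelated random sequences, so cross-gene k-mer
collisions are rarer than in real transcriptomes.

## Evaluation

`n50` is the largest length L such that sequences ≥ L hold at least half
of the assembled bases. A reference isoform is *x%-assembled* when one
transcript aligns to it covering ≥ x of its length at ≥ 95% identity, and
a gene counts when any of its isoforms does. `isoform_recovery` reports
sensitivity (truth isoforms recovered at ≥ 95% coverage and identity) and
precision (transcripts matching some truth isoform). Alignment reuses the
exact-anchor chaining engine with an exact-match fast path: coverage is
the chained reference span over the reference length and identity the
anchor-matched bases over that span. This transcript-to-transcript
alignment deliberately simplifies genome-based evaluation tools; it is
exact for error-free assemblies and conservative otherwise. The length
histogram uses 10 bp bins from zero.

## Problem sizes and determinism

The packaged toy is one gene with two isoforms differing by a 120 bp
skipped exon, error-free 30x pairs, and one error-free full-length long
read per isoform; its graph has no repeated (k−1)-mers with overwhelming
probability, which is what makes exact recovery provable. The default
simulated study is 30 genes × 2–3 isoforms (≈ 70–80 transcripts, ≈ 65 kb),
assembled in ~15 s; the directional hybrid-vs-SR property is evaluated
over ten seeds. The assembly itself contains no randomness: identical
inputs and configuration give byte-identical output files, which the test
suite checks by hashing.

## Known limitations

- No bubble popping or coverage-ratio branch resolution; residual error
  bubbles inflate the unitig count and are tolerated by threading instead.
- No paired-end distance scaffolding: transcripts are single graph walks.
- Threading is anchor-based; a read whose errors destroy all exact
  13-mers in a region cannot be placed there (gap repair is bounded).
- The non-stranded mode doubles k-mers rather than building a bidirected
  graph; memory roughly doubles on unstranded data.
- Expression is not quantified; `support` counts threaded long reads only.
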