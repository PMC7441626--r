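# isoweave

Hybrid de novo transcriptome assembly in R: accurate short reads build a
strand-specific De Bruijn graph, and long full-length cDNA reads thread
paths through it to reconstruct alternatively spliced isoforms that
short reads alone cannot phase.

## Who this is for

Anyone assembling a transcriptome without a reference genome from a
combination of Illumina-style paired-end RNA-seq and nanopore-style long
cDNA reads — and anyone who wants a compact, fully inspectable
implementation of the hybrid splicing-graph approach with a built-in
simulator and evaluation metrics, at a scale that runs on a laptop.

## The method in brief

Short reads are decomposed into k-mers (default k = 25, count ≥ 2) on the
transcript sense strand (dUTP convention: mate 1 is reverse-complemented).
After tip clipping and removal of low-coverage edges that compete with a
stronger parallel alternative, maximal non-branching paths are condensed
into unitigs overlapping by k−1 bases.

A long read is classified **full-length (FL)** when both library adapters
are detected near its ends at ≥ 70% similarity, where similarity of an
adapter occurrence is (len − E)/len for E the best infix-alignment edit
distance within a terminal window (gaps count; the 70% boundary is
inclusive). Reads are threaded through the unitig graph by chaining exact
13-mer anchors: a chain scores only the new read bases each anchor block
covers, junction gaps are repaired by a bounded path search, and chains
covering < 50% of the read are dropped.

Transcript paths are then built by **multi-edge extension**: at every
graph branch, each outgoing edge supported by a phase-consistent long-read
subpath spawns its own continuation, so alternative isoforms come out as
separate paths. Junctions with no long-read support stop (the
short-read-only baseline therefore emits unitigs). FL read paths are
injected into the output set directly, duplicate spellings are collapsed,
and transcripts < 200 bp are dropped.

Evaluation implements N50, transcript length classes, *x%-assembled* gene
counts (a gene counts at threshold x if some transcript covers ≥ x of one
of its isoforms at ≥ 95% identity) and isoform recovery
(sensitivity/precision at 95% coverage and identity) against a reference
or the simulator's ground truth.

## Worked example

Simulate a 30-gene transcriptome (2–3 isoforms per gene, log-normal
expression), sequence it at 50x short-read / 2x long-read coverage, and
compare hybrid against short-read-only assembly:

```r
library(isoweave)

tx  <- make_transcriptome(n_genes = 30, seed = 1)
cfg <- sim_config(seed = 1)           # SR 150 bp PE 50x, 0.5% subst;
                                      # LR 2x, 10% error, 93% full-length
sr  <- simulate_short_reads(tx, cfg)
lr  <- simulate_long_reads(tx, cfg)

res <- assemble_both(sr$r1, sr$r2, lr$reads,
                     config = assembly_config(seed = 1), verbose = TRUE)
#> short reads in: 21376
#> k-mers kept: 65672
#> unitigs: 1106 (136 links)
#> long reads: 110 (69% mapped, 94% full-length)
#> paths before dedup: 1129 (1056 extended + 73 full-length injected)
#> paths after dedup: 1068

ref <- seq_tbl(tx$isoforms$isoform_id, tx$isoforms$seq)
metrics_report(list(hybrid = res$hybrid, sr_only = res$sr_only),
               ref, genes = tx$isoforms$gene_id)
#>                metric   hybrid  sr_only
#> 1       n_transcripts   59.000  55.0000
#> 2        n_over_500bp   44.000  19.0000
#> 3                 n50 1094.000 630.0000
#> 4         genes_50pct   30.000  27.0000
#> 5         genes_95pct   20.000   5.0000
#> 6 isoform_sensitivity    0.435   0.0725
#> 7   isoform_precision    0.508   0.0909
```

The long reads quadruple the 95%-assembled gene count (5 → 20) and lift
isoform sensitivity from 7% to 44%: the short-read graph alone stops at
every splicing branch, while long-read paths phase the branches into
complete isoforms. `res$hybrid` is a data frame of transcripts with their
graph paths, full-length flags and long-read support; the assembly graph
is available as `attr(res$hybrid, "graph")` and exportable with
`write_gfa()`.

The same pipeline is scriptable from a shell:

```sh
ISOWEAVE=$(Rscript -e 'cat(system.file("scripts/isoweave.R", package = "isoweave"))')
Rscript $ISOWEAVE simulate --out sim/ --seed 1
Rscript $ISOWEAVE assemble --sr1 sim/sr_1.fastq --sr2 sim/sr_2.fastq \
    --lr sim/lr.fastq --out transcripts.fasta --gfa graph.gfa
Rscript $ISOWEAVE evaluate --transcripts transcripts.fasta \
    --reference sim/truth_isoforms.fasta --out metrics.tsv
```

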