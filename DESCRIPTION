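Package: isoweave
Title: Hybrid De Novo Transcriptome Assembly from Short and Long cDNA Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale hybrid de novo transcriptome assembler. Short
    accurate reads build a strand-specific De Bruijn graph that is condensed
    to unitigs; long noisy full-length cDNA reads are classified by adapter
    detection, threaded through the unitig graph as anchor chains, and used
    as path evidence to extend transcript paths through splicing branches so
    that alternative isoforms are reconstructed individually. Full-length
    read paths are injected directly into the output set and duplicate
    spellings are removed. Includes a transcriptome and read simulator with
    known isoform ground truth (exon skipping, intron retention, alternative
    donor/acceptor events), assembly quality metrics (N50, x%-assembled
    genes, isoform recovery), GFA1 graph export, and a command-line
    interface for the simulate/assemble/evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    stringi,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
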