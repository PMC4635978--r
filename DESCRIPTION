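Package: circscan
Title: Back-Splice Junction Detection and circRNA Feature Analysis on Synthetic Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for exonic circular RNA (circRNA) analysis:
    strict anchor-based back-splice junction detection from RNA-seq reads,
    filtering of junctions that also map linearly to the genome
    (mis-annotation removal), RPM and pseudo-RPKM quantification against host
    genes, flanking-intron length and complementary-SINE pair statistics,
    end-anchored cross-species conservation through liftOver chains with an
    in-silico control null model, and spatio-temporal expression profiling
    (clustered heatmap matrices, circ/host correlation, hot-spot genes).
    Includes a synthetic-data module that generates genomes, gene models,
    repeat tracks, ortholog assemblies with chain files and FASTQ reads with
    planted ground truth, so the whole chain is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
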