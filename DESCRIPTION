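Package: promG4
Title: Promoter G-Quadruplex Landscape Scoring and Biophysics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Scans transcription-regulatory regions (-2000 to +1000 around
    the transcription start site) for putative G-quadruplex sequences
    matching the G3+(N1-7 G3+)3+ grammar on both strands, computes
    per-transcript abundance (F) and location-significance (Q) scores with
    their genome-wide cumulative-frequency percentiles (CF/CQ) and the
    derived G4-importance classification, aggregates importance to tissue
    and KEGG-style pathway level with Wilcoxon rank-sum and iteration ANOVA
    statistics, and fits the accompanying biophysical models: two-state
    van't Hoff melting thermodynamics, double-exponential unfolding
    kinetics with pseudo-first-order, Arrhenius and Eyring analysis,
    fluorescent-intercalator-displacement DC50 and dose-response EC50
    curves. A synthetic-data module generates planted-motif genomes, gene
    sets with controlled enrichment and noisy curves with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    fgsea,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, SequenceAnalysis, MotifDiscovery, GeneRegulation
RoxygenNote: 7.3.3
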