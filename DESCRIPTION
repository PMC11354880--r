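Package: tRNAstopR
Title: Treatment-Based tRNA Modification Profiling from RT-Stop and
    Misincorporation Signatures
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects dihydrouridine (D), 4-thiouridine (s4U),
    7-methylguanosine (m7G) and pseudouridine (Psi) sites in bacterial
    tRNAs from reverse-transcription stop enrichment in chemically
    treated (NaBH4, CMCT) versus control small-RNA sequencing libraries,
    and inosine/m1A/m1G sites from base-misincorporation signatures in
    untreated libraries. Provides tRNAscan-SE parsing, identical-sequence
    tRNA clustering, structure-guided Sprinzl coordinate assignment,
    per-cluster RT-stop pileups from SAM/BAM or TSV, a per-position
    Poisson enrichment test with Benjamini-Hochberg FDR control and
    noise filters, classification of calls against a known-site catalog,
    summary tables and callset comparisons, and a seeded
    synthetic-experiment generator for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Transcriptomics, Sequencing, Epitranscriptomics, Coverage,
    Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
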