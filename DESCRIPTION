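Package: coexmotif
Title: Co-Expression-Guided Transcription Factor Motif Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying candidate transcriptional regulators of
    a gene of interest from expression data and promoter sequence. Screens a
    seed gene for induction between conditions, builds top-N co-expression gene
    sets from microarray-style probe data with Affymetrix-aware probe
    filtering, scores promoter windows with conservation-weighted log-odds
    position weight matrix scanning of JASPAR motifs, and tests per-motif
    enrichment of the gene set against the gene universe with an AUC rank
    statistic, permutation p-values and Benjamini-Hochberg q-values. Also
    provides bidirectional-promoter dissection (consensus-site and tandem-pair
    detection, cross-species conservation reports, reporter-mutant design),
    small reductions for qPCR and ChIP validation assays, and a seeded
    synthetic-data generator with planted motif sites for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
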