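Package: snvgmhi
Title: Strain-Resolved SNV Profiling and Gut Microbiome Health Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-cohort analysis of single-nucleotide variants (SNVs) in gut
    microbial strains from strain-resolved metagenomic SNV calls. Computes
    per-genome SNV-rate and nucleotide-diversity metrics, depth-normalized
    mutated-genome and SNV counts, collapsed base-variant-type profiles,
    codon-level stop-gain/start-loss bias in short-chain fatty acid (SCFA)
    production genes, gene-level pN/pS, and three Gut Microbiome Health
    Indices (abundance, SNV-rate, SCFA-SNV) with compositional marker
    selection and ROC evaluation. Includes a seeded synthetic cohort
    generator emulating the post-SNV-calling data layer so the full pipeline
    is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vegan,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
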