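Package: coipnet
Title: Co-Immunoprecipitation Proteomics Scoring, Interaction Networks and
    Phosphosite Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for affinity-purification mass-spectrometry
    (AP-MS) co-immunoprecipitation experiments on meiotic chromosome-axis
    proteins. Implements per-dataset label-free quantification with an
    empirical-Bayes moderated t-test, a two-tier protein acceptance rule
    (quantitative fold-change/p-value tier plus a qualitative
    sample-specific tier with control exclusion and a two-peptide
    threshold), best-BLAST-hit ortholog assignment with many-to-one locus
    collapse, protein-protein interaction network component analysis,
    hypergeometric term over-representation with Benjamini-Hochberg
    adjustment, Yates-corrected 2x2 chi-square tests, phosphopeptide to
    protein-site mapping with ambiguity handling, kinase consensus motif
    classification (S/TQ, CDK1, CK2), S/TQ cluster-domain detection, global
    pairwise protein alignment with cross-species site correspondence, and
    a synthetic-data generator that produces every pipeline input with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
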