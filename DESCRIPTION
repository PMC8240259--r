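Package: viromegrad
Title: Soil Virome Profiling and Phage-Bacterium Interactions Along Stress Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling soil viromes and phage-bacterium interactions
    along environmental stress gradients such as heavy-metal contamination.
    Implements explicit decision rules for viral contig identification
    (VirSorter-category acceptance plus three annotation-based viral-HMM
    criteria with a strict >5 kb length gate), CRISPR spacer-protospacer host
    linkage with polyvalence (broad host range) classification, lysogeny
    indicators (integrase carriage in viromes and metagenomes, mitomycin-C
    prophage-induction assay evaluation), metal-resistance-gene screening and
    attribution to lysogenic phages, hypergeometric gene-sharing similarity
    networks with viral clustering, TPM abundance normalization, richness
    estimators (Chao1, ACE) and nonparametric gradient statistics. A synthetic
    community generator with a known ground-truth manifest emulates the
    statistical structure these analyses assume and backs the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
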