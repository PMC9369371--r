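Package: cernet
Title: Inference of lncRNA-Mediated Competing Endogenous RNA Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for inferring lncRNA-miRNA-mRNA
    competing endogenous RNA (ceRNA) networks from bulk RNA-seq case/control
    designs. Provides TPM/CPM normalization, pseudo-floored fold-change and
    Student's t differential-expression screening with Benjamini-Hochberg
    correction, multi-database target-prediction merging, a miRNA seed-match
    site finder, anti-correlation intersection filters, tripartite network
    construction with Cytoscape-convention centralities and hub selection,
    sign-consistent sponge-triad assembly, hypergeometric overrepresentation
    analysis, and 2^-ddCt qPCR concordance validation. Seeded negative-binomial
    simulators generate every input with ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
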