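Package: rlkscan
Title: Kinase-Domain Targeted Analysis of Receptor-Like Kinase Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for kinase-domain targeted surveys of plant
    receptor-like kinase (RLK/Pelle) candidate genes. Covers in-silico
    degenerate-primer PCR and open-reading-frame screening, protein-kinase
    subdomain annotation with RD/non-RD and typical/atypical classification,
    activation-segment consensus comparison, neighbor-joining phylogenetics on
    Poisson-corrected amino-acid distances with bootstrap-based subfamily
    assignment, sliding-window Ka/Ks selection scans with Nei-Gojobori codon
    counting and rank-based group comparisons, non-synonymous position-sharing
    maps, and a codon-evolution simulator that generates sequence families with
    region-specific selective constraint for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
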