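Package: fibevo
Title: Evolutionary Sequence Analysis of the Fibrillin Protein Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative evolutionary analysis of fibrillin-like
    cysteine-rich extracellular matrix proteins. Annotates domain
    architecture (EGF, calcium-binding EGF, TB, hybrid, terminal and
    unique domains) from cysteine spacing and the calcium-binding
    consensus, scans RGD integrin-binding and furin-cleavage motifs,
    summarises unique-region amino-acid composition, and reconstructs
    gene-duplication phylogenies from per-domain and concatenated-domain
    alignments with neighbor-joining and maximum-likelihood (JTT with
    invariant sites and discrete-gamma rates, NNI search) methods,
    bootstrap resampling and majority-rule consensus. A fibrillin-family
    simulator with a known duplication history, domain grammar and
    scripted motif events makes every stage testable without database
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
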