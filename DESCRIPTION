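Package: splicescreen
Title: Exonic Splicing Enhancer Scanning, Splice-Site Strength Models and
    Paralog Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans exons for splicing-regulatory motifs (position weight
    matrices of SR proteins, enhancer and silencer hexamer sets), scores
    donor and acceptor splice-site strength with a trainable
    maximum-entropy model, aligns paralogous exons codon-wise, and screens
    gene families for loci where a weak splice site co-occurs with exonic
    splicing enhancers that are absent, together with amino-acid
    differences, in a strong-splice-site paralog. Also scans
    multi-species alignments with reconstructed ancestral node sequences,
    and fits Michaelis-Menten kinetics for the associated enzyme variants.
    All inputs can be simulated, so the full pipeline is testable without
    external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
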