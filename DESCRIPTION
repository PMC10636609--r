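Package: tlkinetics
Title: RNA Degradation and Synthesis Kinetics from Nucleotide-Recoding RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates RNA degradation and synthesis kinetics from
    nucleotide-recoding RNA-seq experiments (TimeLapse-seq/SLAM-seq), in which
    4-thiouridine fed to cells during a labeling window is chemically recoded
    so that new transcripts carry T-to-C mutations. Provides mutation calling
    from aligned reads (base-quality, read-end, pairing and SNP filters), a
    hierarchical Bayesian two-component Poisson mixture model of per-read
    mutation counts yielding the fraction of new RNA per gene, conversion of
    fraction-new posteriors into first-order degradation and synthesis rate
    constants, a fold-change decomposition attributing expression changes to
    stability versus synthesis, and a synthetic-data generator matching the
    model's generative assumptions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    edgeR,
    coda
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
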