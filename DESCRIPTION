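Package: svtune
Title: Sample-Adaptive Optimization of Structural-Variant Calling Filters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates structural variants (deletions, inversions, tandem
    duplications, translocations and insertions) on any reference genome,
    derives the rearranged sequence and paired-end reads at a chosen ploidy
    and zygosity, and uses those simulations to optimize a multi-parameter
    filter model for gridss-style breakend calls by exhaustive, pruned grid
    search maximizing the F-value. Includes an annotated-breakend caller
    emulator for fully in-process testing, explicit matching rules for
    scoring called against known variant sets, breakpoint-orientation typing
    with read-depth classification of deletion- and duplication-like
    junctions, inference of homologous and known-variant regions for
    realistic simulations, and read-depth copy-number calling with
    nonparametric (lowess) correction of GC, mappability and
    telomere-distance biases, a conservative cross-caller consensus and
    unified VCF export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics,
    optparse,
    yaml,
    seqinr
Config/testthat/edition: 3
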