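Package: pacscope
Title: Phage Genome Termini Detection and Packaging Strategy Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer bacteriophage genome packaging strategies from
    shotgun sequencing data. Simulates packaging substrates (concatemers,
    headful series with terminal redundancy, cohesive-end and direct
    terminal repeat virions) and paired-end read libraries; computes
    strand-specific read starting-position coverage (SPC) profiles from
    alignments and detects preferred packaging-initiation (pac) sites via
    a peak-ratio statistic; reorganizes circular assemblies at the
    detected pac site; designs restriction-digest experiments that expose
    the submolar terminal pac fragment for gel-based verification; and
    propagates experimentally verified packaging-strategy labels across
    terminase large subunit (TerL) phylogenies by a supported-monophyletic
    clade rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    Rsamtools,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
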