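Package: ARfidelity
Title: Detection Fidelity of Low-Abundance AR Hotspot Mutations in Cell-Free DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the fidelity of low-allele-fraction androgen
    receptor (AR) hotspot mutation detection in plasma-derived cell-free DNA.
    Implements a deep-sequencing variant-filter cascade on per-sample,
    per-locus stranded allele counts; droplet digital PCR (ddPCR)
    quantification with Poisson statistics, replicate merging and AR
    copy-number calling; a stochastic branching-process simulator of PCR
    preamplification error, sequencing count sampling and droplet
    partitioning; and a fidelity module that estimates locus- and
    polymerase-specific amplification error rates with exact binomial
    confidence intervals and classifies sequencing candidates as validated or
    false positive by cross-platform concordance with ddPCR.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
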