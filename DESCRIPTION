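Package: omegaqpcr
Title: Absolute Telomere Length from Circularizable-Probe qPCR
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design of circularizable (padlock-style) Omega-probes against
    tandem-repeat telomere targets, conversion of qPCR quantification cycles
    into absolute telomere length in base pairs via a probe-occlusion
    calculus, per-cell mean telomere length under explicit karyotype and
    cell-cycle models, hybridization-corrected mean telomere length from
    terminal restriction fragment (TRF) lane densitometry, and a seeded
    forward simulator of the whole assay for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
biocViews: Sequencing, qPCR, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'trf.R'
    'probe-design.R'
    'quant-core.R'
    'telosim.R'
    'io.R'
    'mtl.R'
    'omegaqpcr-package.R'
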