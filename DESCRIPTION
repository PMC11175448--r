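Package: panelscope
Title: Targeted Gene-Panel Copy-Number Loss Calling, Variant Interpretation and Analytical Validation
Version: 0.1.0
Authors@R: person("panelscope", "developers", role = c("aut", "cre"), email = "panelscope@example.org")
Description: Computational core of a targeted 82-gene inherited-retinal-dystrophy
    sequencing panel: a binned, reference-pool-normalized copy-number-loss
    caller with log2-ratio reporting; allele-frequency-based zygosity
    assignment and ACMG/AMP five-tier evidence combination; panel QC metrics
    (Q20/Q30, GC content, coverage breadth); analytical-validation statistics
    (positive/negative percent agreement with exact Clopper-Pearson intervals,
    replicate precision designs, interference detection rates); and seeded
    synthetic-data generators producing panel-shaped depth profiles and VCFs
    so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
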