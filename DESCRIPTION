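Package: photoepi
Title: Integrative Methylome, Transcriptome and Small-RNA Analysis for
    Photoreceptor-Mutant Plant Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Region-level differential DNA-methylation calling from
    Bismark-style cytosine reports (CG/CHG/CHH contexts, Fisher tests with
    Benjamini-Hochberg control and a minimum differentially-methylated-
    cytosine rule), two-group negative-binomial differential testing for
    gene and small-RNA-cluster counts, de novo sRNA cluster calling and
    genomic categorisation, positional transcription-factor binding-site
    enrichment in upstream regions with an exact PWM score-distribution
    threshold and a permutation null, and cross-omics integration
    statistics (promoter-methylation x expression overlap, sRNA x
    methylation association, gene-body versus promoter sRNA effects).
    Ships a deterministic synthetic-study generator with planted ground
    truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
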