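Package: apacohort
Title: Tumor-Specific Alternative Polyadenylation from Cohort Cleavage-Site Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects tumor-specific alternative polyadenylation (APA) events
    from per-sample cleavage-site (CS) call tables and an Ensembl-dialect
    transcript annotation. Annotated and predicted CSs are grouped by
    single-linkage clustering with a fixed gap cutoff; predicted calls are
    filtered by proximity to annotated sites or by polyadenylation-signal
    hexamer plus poly(A) evidence; CS usage frequencies (fraction of
    expression-sufficient samples using a site) are compared between normal
    and tumor groups with Fisher's exact test; a gene-by-cancer-type pair is
    called an APA event when at least one CS significantly gains and another
    significantly loses frequency, with pair-level p-values and
    Benjamini-Hochberg false discovery control over the full test grid.
    Events are classified as 3' UTR shortening, lengthening, or complex via
    CS-to-stop-codon mappings. A synthetic-cohort generator produces a toy
    genome, annotation, manifest, and call tables with planted ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
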