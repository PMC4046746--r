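Package: tagdge
Title: Restriction-Tag Digital Gene Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tag-based digital gene expression (DGE) profiling of the
    kind produced by NlaIII/MmeI restriction-tag sequencing (21 bp CATG-anchored
    tags). Builds a virtual tag database of all CATG+17 windows of a reference
    transcriptome, cleans raw 49 bp reads into distinct-tag libraries with full
    read accounting, maps tags with at most one mismatch and ambiguity
    filtering, normalizes per-gene counts to transcripts per million clean tags
    (TPM), tests differential expression between two libraries with the
    Audic-Claverie exact count test under Benjamini-Hochberg FDR control,
    classifies time-course response phases, performs hypergeometric pathway
    enrichment against an annotated background, and runs saturation analysis of
    gene detection versus sequencing depth. A tag-sequencing simulator with
    known expression ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cli,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
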