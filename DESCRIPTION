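Package: snvblur
Title: Privacy-Preserving Aggregation and Sharing of SNV Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates single-nucleotide-variant (SNV) genotypes from
    per-sample VCF files into a shareable, anonymized sites-only VCF.
    Sample metadata (trait, HPO phenotype terms, gender, platform) is
    suppressed until every released attribute combination is k-anonymous;
    each sample's SNVs are fragmented into unequally sized sub-samples
    whose linkage to the source sample is kept only in an encrypted,
    password-protected file; and rare variants - those occurring in at
    most 1.5 times the median number of carriers - are blurred down to
    locus, trait and submitter contact. Includes a synthetic exome-cohort
    generator with a realistic site-frequency spectrum, re-identification
    diagnostics, a validator for the aggregated format, and a local query
    engine (position, dbSNP ID, gene interval).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    openssl,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer,
    GenomicRanges,
    IRanges
Config/testthat/edition: 3
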