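Package: finemav
Title: Fine-Mapping of Adaptive Variation Scores from Population Allele
    Frequencies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritises candidate positively selected variants by computing
    per-population FineMAV scores (derived allele purity x derived allele
    frequency x CADD_PHRED) from tab-delimited variant extracts with
    per-population alternate-allele frequencies. Polarises alleles against
    an ancestral state, optionally supplementing ancestral alleles and CADD
    scores from a VEP-style annotation table, streams large tables in
    fixed-size chunks with bounded memory, and emits a score table,
    per-population bigWig tracks for genome browsers, and a run log. Includes
    a seeded synthetic-fixture generator and a naive scoring oracle for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    BiocGenerics,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    optparse,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
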