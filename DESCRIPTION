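Package: fingercore
Title: Core Collection Selection and SNP Fingerprinting for Germplasm Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a core germplasm collection from SNP genotypes
    by weighted multi-measure optimization (modified Rogers distance and Shannon
    diversity), screening genome-wide SNPs down to a core fingerprinting panel
    through a five-criterion cascade (flank specificity, missingness, minor
    allele frequency, polymorphism information content, exact Hardy-Weinberg
    test, and physical isolation), constructing and verifying DNA fingerprints
    with 2D-barcode payloads, designing KASP allele-specific PCR assays, and
    identifying population origin from genotype calls via genetic distances,
    neighbor-joining trees and principal components. Includes a Balding-Nichols
    synthetic-data generator that emulates a structured wild collection so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
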