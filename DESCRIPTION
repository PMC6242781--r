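Package: nucsig
Title: Species-Diagnostic Nucleotide Signatures for Herbal Product Authentication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers short species-diagnostic nucleotide signatures (~30-40 bp
    windows around diagnostic SNPs) from labeled marker-gene panels such as ITS2,
    designs and validates species-specific PCR assays in silico (including on
    mixtures and heat-degraded DNA), models qPCR detection sensitivity (Cq versus
    log mixing ratio, amplification efficiency, limit of detection), and classifies
    commercial products as authentic, adulterated or substituted from their
    detected-species sets. Includes a seeded synthetic-panel generator, a simple
    global/star aligner, and a local seed-and-extend search with Karlin-Altschul
    significance for signature uniqueness checks. Ships the Cistanches Herba
    reference fixtures (signatures, primer pairs, qPCR sensitivity table, and a
    66-product market survey) used throughout the documentation and tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
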