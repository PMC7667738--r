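Package: lightscreen
Title: Scoring Visible-Light Sensitivity in Yeast Colony-Array Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies photographs of 384-position pinned colony arrays into
    per-colony cell density estimates (CDE) by intensity profiling with local
    background subtraction, and calls light-sensitive and light-resistant
    gene-deletion strains from light/dark CDE tables using density-banded
    day-6 growth cutoffs and a control-normalized light/dark growth index
    (LGnorm).  Includes quantification of serial-dilution spot assays with
    pooled-variance t tests against a wild-type reference, hypergeometric
    GO-slim term enrichment with Benjamini-Hochberg FDR control, and a
    synthetic plate and screen generator with planted ground truth for
    end-to-end validation of the scoring pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
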