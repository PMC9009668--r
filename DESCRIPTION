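Package: fishaudit
Title: DNA Barcoding Audits of Seafood Mislabeling and Substitution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for market surveys of seafood mislabeling based on COI
    DNA barcoding. Assigns species to query barcodes against reference
    libraries using a percent-identity threshold with two-library consensus
    and genus-level fallback, calls samples correct or mislabeled against
    commercial-name catalogs with union semantics, computes per-name
    mislabeling and substitutability audits and the substitution network,
    and provides the survey statistics layer (Wilson score intervals,
    2x2 Pearson chi-square comparisons, and linear regressions of
    mislabeling on availability and demand proxies). Includes a synthetic
    survey generator with ground truth so the full pipeline is testable
    without external sequence databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    rlang,
    readr,
    stats,
    stringi,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
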