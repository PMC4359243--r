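Package: hcscreen
Title: High-Content siRNA Screen Analysis with Robust Z-Score Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-content siRNA screens that read out
    DNA damage as per-nucleus gamma-H2AX immunofluorescence. Covers the full
    path from two-channel well images (Hoechst nuclear stain plus signal
    channel) through nucleus segmentation, per-nucleus intensity
    quantification, per-well averaging and background-well subtraction, to
    per-plate robust z-score normalization (median/MAD), multi-siRNA
    gene-level candidate calling with cumulative z-score ranking, and the
    accompanying validation statistics (delta-delta-Ct relative expression,
    unpaired two-tailed t-tests with asterisk labels, and box-plot
    distribution summaries). Includes a synthetic screen generator with an
    implanted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    purrr,
    rlang,
    tiff,
    EBImage,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
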