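Package: midisplit
Title: Split-Intein Dual-AAV Construct Design and AlphaFold3 Confidence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing split-intein dual-AAV "midi-protein"
    constructs (domain assembly with hinge shortening, serine split-site
    enumeration, cassette-size accounting, protein mass bookkeeping) and for
    scoring protein trans-splicing competence from AlphaFold3 confidence
    outputs: region-restricted pLDDT summaries, the fraction of inter-domain
    predicted aligned error below a threshold, conditional contact
    probabilities, Kabsch superposition RMSD with outlier-rejection
    refinement, and design ranking reports. Includes a synthetic-data
    generator that emulates AlphaFold3 confidence bundles and toy structure
    pairs with planted ground truth so the whole pipeline is testable
    without any server output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    Biostrings,
    bio3d,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
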