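Package: wetrisk
Title: Contamination Indices and Probabilistic Health Risk Assessment for
    Heavy Metals in Wetland Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses heavy metal(loid) contamination of surface water and the
    human health risks it poses. Implements the single-factor pollution index
    and the Nemerow composite index with their contamination classes, chronic
    daily intake for oral ingestion and dermal contact, hazard quotients and
    the total hazard index for non-carcinogenic risk, cancer risks and the
    total cancer risk from linear slope factors, Monte Carlo propagation of
    exposure-parameter and concentration uncertainty, and contribution-to-
    variance sensitivity analysis based on Spearman rank correlations. Ships
    a moment-matched truncated-lognormal generator of per-sample water
    chemistry tables so the whole pipeline can be exercised from published
    group-level summary statistics alone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
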