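Package: drmwell
Title: Experienced Well-Being from Abbreviated Day Reconstruction Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring and validating abbreviated Day Reconstruction
    Method (DRM) episode diaries of the kind used in large multi-country
    ageing surveys. Implements duration-weighted net affect and the U-index
    on a percentile scale, hour-by-hour diurnal affect curves, hierarchical
    clustering of activities by their affect profiles with multiscale
    bootstrap AU/BP cluster support, two-factor confirmatory factor analysis
    of the seven ordinal affect items on polychoric correlations with fit
    indices and composite reliability, and cross-group effect sizes
    (Hedges' g, Cohen's f, Cramer's V). A seeded synthetic diary generator
    with known latent structure supports ground-truth recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    withr,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
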