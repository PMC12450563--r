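Package: popshape
Title: Deterministic Shape Classification of Sex-Specific Population Pyramids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying managed (studbook-based) animal populations
    through the shapes of their sex-specific population pyramids. Provides
    studbook curation rules (parentage plausibility, interbirth intervals,
    litter grouping, maximum-longevity records), data-driven estimation of
    juvenile/adult/senior life stages via a gamma fit to age-specific
    reproduction probabilities, reduction of yearly age pyramids to five
    age buckets, a deterministic classification of the reduced pyramids into
    eleven shape categories, shape-transition and population-dynamics
    statistics, and a seeded individual-based studbook simulator with
    record-error injection for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
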