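Package: regimenrank
Title: Temporal Evidence-Network Valuation and Ranking of Treatment Regimens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds temporal networks of pairwise randomized-controlled-trial
    comparisons between treatment regimens and assigns each regimen a signed,
    unnormalized value from the strength of evidence (capped negative log10
    P value), the surrogacy-weighted relative value of the selected endpoint,
    a signed effect-size coefficient, the log10 patient count, and an
    exponential aging coefficient. Includes single-generation value
    propagation with aging refresh to counter the straw-man effect (new
    regimens looking strong because they are compared against weak or
    outdated comparators), diagnostics for that bias (Pearson correlation of
    vertex value against patients studied, with confidence interval and P
    value; relative-value sensitivity analysis), network visualization with
    divergent value coloring and GraphML export, and a synthetic trial-stream
    generator with controllable comparator-selection bias for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
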