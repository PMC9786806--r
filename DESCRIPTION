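Package: seedscreen
Title: Flow Cytometric Seed Screen Analysis of Plant Reproduction Pathways
Version: 0.1.0
Authors@R:
    person("FCSS", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for inferring plant reproduction pathways from flow
    cytometric seed screen (FCSS) data. Converts G0/G1 peak measurements of
    embryo, endosperm and maternal tissues into absolute DNA amounts and
    ploidy categories, enumerates and ranks the reproduction scenarios
    (sexuality, apospory, parthenogenesis, B-III hybrid formation,
    pseudogamy, autonomous endosperm, polyspermy, endoreplication)
    arithmetically consistent with each seed's embryo/endosperm ploidy,
    aggregates classified seeds into per-tree and per-cytotype summary
    tables, and groups mother trees by reproductive profile using
    Bray-Curtis dissimilarity, Ward clustering and detrended correspondence
    analysis. Includes a synthetic seed-family generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    withr
Config/testthat/edition: 3
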