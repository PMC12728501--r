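Package: synlink
Title: Significance Testing for Shared Chromosomal Linkage Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests the statistical significance of syntenies (shared
    chromosomal linkage groups) across species. Provides exact
    hypergeometric enrichment tests of chromosome-combination overlap with
    Benjamini-Hochberg correction, permutation null models that either
    shuffle every species or only a designated one (the latter respecting
    phylogenetic relatedness among ingroup genomes), hierarchical buildup
    of multi-species chromosome combinations, detection of conserved
    adjacent ortholog pairs, reciprocal-best-hit ortholog cross-referencing,
    and a chromosome-evolution simulator (fusion with mixing, fission,
    translocation, gene loss) for generating test data with known ancestral
    linkage groups.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
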