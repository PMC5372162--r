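Package: coralguild
Title: Null-Model Analysis of Coral Exosymbiont Guilds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Community-ecology toolkit for guilds of obligate decapod
    exosymbionts (Trapezia crabs and Alpheus lottini snapping shrimps)
    living in pocilloporid corals. Provides three Monte-Carlo null models
    for binary colony-occupancy matrices (unconstrained, species-frequency
    constrained, per-colony-richness constrained) with percentile
    confidence-interval rejection of random-association hypotheses;
    richness-profile, pairwise co-occurrence and solitary-occupancy
    statistics; correspondence-analysis ordination and the ANOSIM rank
    permutation test; net nucleotide divergence summaries for cryptic
    lineage delimitation; and an auto-logistic synthetic community
    generator with exactly enumerable state probabilities for power and
    type-I-error experiments. Ships a colony-level survey of 234
    Pocillopora damicornis (types alpha and beta) colonies from Reunion
    Island and New Caledonia as a worked dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vegan,
    ape
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse
Config/testthat/edition: 3
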