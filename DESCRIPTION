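Package: pieces
Title: Phylogenetically Informed Prioritization of Species for Ex Situ Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Multi-criteria prioritization of plant taxa for ex situ conservation
    (seed banks and living collections) that balances collection deficits, threat
    rank and evolutionary distinctiveness. Implements fair-proportion evolutionary
    distinctiveness with a polytomy correction, the Fritz-Purvis D statistic for
    phylogenetic signal in binary traits (permutation and Brownian-threshold
    nulls), AHP (analytic hierarchy process) weight elicitation, the PIECES and
    EDGE priority scores, alternative prioritization schemes, return-on-investment
    metrics, weight-space and Pareto-frontier analysis, PhyloSor and Jaccard
    similarity of selected taxon sets, gap (contingency) analysis of collection
    coverage by threat rank, and the supporting tree-manipulation machinery
    (grafting at genus or family crowns, pruning, branch collapse) together with a
    synthetic-data generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    optparse,
    yaml
Config/testthat/edition: 3
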