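Package: enrichtk
Title: Gene-Set Enrichment with Rank-Calibrated Scoring, Grid Layouts and Term Networks
Version: 0.1.0
Authors@R:
    person("Enrichtk", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: An engine for gene-set enrichment analysis of input gene lists
    against GMT gene-set libraries.  Terms are ranked by three schemes: the
    one-sided Fisher exact (hypergeometric) test, a z-score measuring the
    deviation of a term's observed Fisher rank from its expected rank under
    random input lists (a correction for the set-size bias of the Fisher
    test), and a combined score c = ln(p) * z.  Also provides simulated
    annealing placement of library terms on a toroidal grid by gene-content
    similarity with a permutation-based clustering significance index,
    sparse nearest-neighbour networks of top enriched terms, gene-set
    library construction procedures (expression z-score sets, interaction
    hubs, seed expansion, peak-to-TSS targets, IUPAC consensus promoter
    scanning, CuffDiff list extraction), deterministic synthetic fixtures,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    xml2,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
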