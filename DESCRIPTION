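Package: attsites
Title: Pseudo-attB Site Discovery and Analysis for Large Serine Integrases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes integration of large-serine-integrase vectors
    (e.g. the Streptomyces phage BT1 system) at pseudo-attB sites.
    Detects plasmid insertion junctions in transformant genome assemblies,
    reconstructs attL/attR products, scores recovered sites against the
    canonical attB over nested 73/36/9 bp windows anchored on the core GT
    dinucleotide, builds a position-weight-matrix motif from observed sites
    and scans genomes for candidate sites with exact null p-values, and
    projects the total number of usable sites by rarefaction and
    abundance-based richness estimators. Includes a seeded recombination
    simulator that plants pseudo-attB sites in synthetic host genomes and
    emits post-integration transformant assemblies with full truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
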