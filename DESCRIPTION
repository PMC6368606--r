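Package: thermodiv
Title: Protein-Family Diversity and Functional Comparison of Hot-Spring
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of chemosynthetic hot-spring community
    metagenomes: cascaded greedy protein clustering into families at
    decreasing identity thresholds (90/60/30 percent), rarefaction and
    fixed-depth subsampling of protein-family richness, regression of
    richness on the sulfate-to-chloride fluid-mixing proxy, KEGG orthology
    (KO) normalization, enrichment and Bray-Curtis/principal-coordinates
    ordination, quality filtering and coverage-normalized relative
    abundance of metagenome-assembled genomes, intra-lineage metabolic
    differentiation ratios and average amino-acid identity, and
    branch-length statistics on phylogenies. Includes a synthetic-study
    generator with known ground truth so the whole pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    phangorn,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
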