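Package: pansig
Title: Pangenome Incongruence and Phylogenetic Signal of Metabolite Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how far single marker-gene (rRNA) identity between
    bacterial strains predicts whole-genome relatedness and metabolic
    capacity. Provides a synthetic pangenome simulator (species tree, marker
    and core-genome alignments under Jukes-Cantor, accessory gene gain/loss,
    feature annotations, Brownian-motion metabolite traits and an LC-MS style
    replicate table); marker percent-identity with length filtering and
    best-copy rules; ortholog clustering, shared/unshared gene counts and an
    ortholog-based average nucleotide identity with aligned-length accounting;
    neighbor-joining, UPGMA and Jaccard gene-composition trees with bootstrap
    supports, scaled patristic divergence and Robinson-Foulds discordance;
    metabolomics preprocessing (replicate-presence filtering, ion-mode
    merging, half-minimum imputation, generalized-log transform, autoscaling,
    one-way ANOVA with Benjamini-Hochberg FDR, score normalization, Ward
    heatmap ordering); and Blomberg's K with a permutation test screened per
    metabolite against alternative tree topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    igraph,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    picante,
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
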