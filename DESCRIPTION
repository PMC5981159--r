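Package: ruminfer
Title: Phylogeny-Based Functional Inference for Rumen Microbiome 16S Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the functional (KEGG ortholog) potential of a microbial
    community from 16S rRNA OTU data against a custom reference of sequenced
    genomes, in the style of PICRUSt-type workflows focused on the rumen
    microbiome. Provides construction and validation of the three-file
    reference bundle (phylogeny, KO trait counts, 16S copy numbers),
    Brownian-motion ancestral state reconstruction and trait prediction for
    unsequenced taxa with nearest-sequenced-taxon distances, closed-reference
    classification of OTU representative sequences with abundance aggregation,
    16S copy-number normalization, metagenome prediction, KEGG BRITE pathway
    collapsing, predicted-versus-observed evaluation statistics, and seeded
    synthetic-data generators (Yule trees, Brownian traits, Jukes-Cantor
    sequences, multinomial OTU sampling) for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    phytools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
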