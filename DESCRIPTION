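Package: HerbPhenoNet
Title: Phenotype-Oriented Network Analysis of Herbal Medicine
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts pharmacological effects of natural compounds from
    herbal-medicine knowledge by phenotype-oriented network analysis. A
    concept hierarchy of phenotypes is weighted by Wu-Palmer semantic
    similarity and used to diffuse each plant's known efficacy
    annotations by random walk with restart, yielding per-plant phenotype
    vectors. Plants are clustered hierarchically under cosine distance
    with multiscale-bootstrap AU (approximately unbiased) support;
    compounds significantly enriched in supported plant clusters by
    Fisher's exact test inherit the cluster's averaged phenotype vector
    as predicted effects. Includes ranked-prediction evaluation
    (AUROC/AUPR, F1 threshold scan, rank correlation, Tanimoto overlap),
    a protein-network target-closeness baseline, and a synthetic-world
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
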