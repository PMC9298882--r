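Package: drhgnn
Title: Heterogeneous Graph Neural Network Drug Repurposing on Drug-Protein-Disease Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multi-labeled drug-protein-disease (DPD) heterogeneous
    graphs from DTINet-style network files, learns compact node features by
    random walk with restart followed by a diffusion-component-analysis style
    low-rank embedding, reduces multi-label edges to single representative
    disease labels, and trains a heterogeneous GraphSAGE (HinSAGE) edge
    classifier that scores disease-labeled drug-protein links. Includes a
    synthetic network generator with planted low-rank structure, a repeated
    shuffle-split evaluation protocol with AUC-ROC/AUPR metrics, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
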