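Package: moldistill
Title: Online Knowledge Distillation for SMILES Molecule Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Co-trains a from-scratch autoregressive SMILES generator with a
    scaffold-conditioned encoder-decoder generator by online knowledge
    distillation: a one-directional KL loss aligns the two models' next-token
    distributions and a bidirectional-LSTM discriminator adversarially aligns
    their last-layer feature maps. Ships a seeded toy-corpus generator, a
    desk-scale training loop with ablation variants, autoregressive sampling
    (unconditional and scaffold-conditioned), and the standard generative
    chemistry evaluation suite: validity, uniqueness, novelty, internal
    diversity, scaffold similarity, QED/SAS/LogP profiling and Pareto-front
    selection. Chemistry primitives (canonicalization, Bemis-Murcko scaffolds,
    Morgan fingerprints, property calculators) are delegated to RDKit through
    a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with the rdkit package, resolvable as
    'python' on PATH.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
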