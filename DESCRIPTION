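Package: molapprove
Title: Small-Molecule Approval Prediction with Comparative Retrieval and
    Group-Relative Policy Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and testing an interpretable small-molecule
    approval-prediction pipeline: physicochemical descriptor and structural
    alert featurization (OpenBabel backend), drug-likeness gates (Ghose, QED),
    a masked mean-pooling molecular-embedding contract with a deterministic
    mock encoder, gradient-boosted-tree leaf-embedding similarity retrieval
    with Hamming-distance top-k neighbors, structured comparative reasoning
    prompts with a three-field XML response schema, a five-component
    verifiable reward schedule, the group-relative policy optimization (GRPO)
    objective with a toy trainable categorical policy, and an evaluation and
    ablation bench with synthetic fixture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    xgboost,
    e1071,
    class,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
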