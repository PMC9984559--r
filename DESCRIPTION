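Package: dlrpmds
Title: Variant Classification from Ramachandran-Plot Molecular Dynamics with Deep Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies missense genetic variants from the backbone torsion-angle
    dynamics of molecular-dynamics trajectories. Builds per-variant Ramachandran
    density plots (periodic kernel density estimates on a 32x32 grid), scores
    structural deviation against a wildtype-plus-benign reference (RP-MDS),
    models the score distributions as lognormal with goodness-of-fit testing and
    an optimal cut-off scan, and combines a time-lagged autoencoder with a
    SMOTE-balanced neural-network classifier (DL-RP-MDS) to assign per-variant
    probabilities of deleterious versus unknown function. Includes stratified
    cross-validated evaluation with by-variant and by-frame grouping, a
    synthetic trajectory generator for benchmarking, and a command-line
    interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    nortest
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    pROC,
    fitdistrplus,
    withr
Config/testthat/edition: 3
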