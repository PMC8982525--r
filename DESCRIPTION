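Package: phoreqsar
Title: Pharmacophore Fitting, Docking Contact Fingerprints and GA-Driven
    Machine-Learning QSAR for Virtual Screening
Version: 0.1.0
Authors@R:
    person("Pharmacophore QSAR", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for ligand-based and structure-informed hit discovery
    against protein kinases and similar targets. Implements pharmacophore
    model representation with fit-value scoring and exclusion spheres,
    binary ligand-receptor contact fingerprints (LRCF) built from scored
    docking poses at a distance threshold, assembly of mixed descriptor
    matrices (pharmacophore fits, contact bits, physicochemical indices),
    genetic-algorithm feature selection coupled to pluggable regressors
    (multiple linear regression, nu-support-vector regression with an RBF
    kernel, random forests), cross-validated and external predictive
    statistics (leave-one-out and leave-20%-out q2, predictive r2 from
    PRESS), classification metrics for screening validation (ROC AUC,
    sensitivity, specificity, accuracy, Guner-Henry score), and seeded
    synthetic-data generators so the whole workflow is testable end to
    end without external structure or bioactivity downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    quadprog,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
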