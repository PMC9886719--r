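Package: efcontrol
Title: Structural Connectome Modal Controllability and Executive Function
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for relating the controllability of structural brain
    networks to executive function in aging cohorts. Reads streamline-count
    connectomes and atlas network-membership tables, computes per-parcel
    modal controllability from the eigenvalue-normalized adjacency matrix,
    aggregates it over networks of interest (frontoparietal control network,
    multiple demand system), scores a common executive-function factor from
    six neuropsychological tasks, and fits twin-clustered linear mixed
    models (cross-sectional, longitudinal difference, and moderation) with
    Satterthwaite degrees of freedom and Benjamini-Hochberg FDR control.
    Includes a synthetic twin-cohort generator with known ground truth so
    the whole pipeline is testable without restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
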