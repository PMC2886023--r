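Package: fleecerot
Title: Mixed-Model Microarray Normalization and SNP Association for Ovine
    Fleece-Rot Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for genomics-informed study of fleece-rot
    resistance in Merino sheep. Normalizes loop-design two-colour skin
    microarray intensities with an ANOVA mixed-effect model fitted by REML,
    calls resistant-versus-susceptible differential expression with weighted
    treatment contrasts and a standard-deviation threshold rule, performs
    hypergeometric over-representation of annotation terms, residualizes
    ordinal fleece-rot scores with a pedigree-based animal model, and runs
    per-SNP Hardy-Weinberg quality control plus additive allele-dosage
    association. A synthetic-data generator with known ground truth replaces
    the study animals and arrays so that every stage carries
    parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
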