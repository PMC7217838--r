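Package: SelfAntigenLoad
Title: Germline Self-Antigen Load from HLA Class I Presentation of
    Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates a per-patient "self-antigen load" from annotated
    germline nonsynonymous variants and HLA class I genotypes: builds
    mutant-centered 27-residue peptide windows, enumerates 8-14-mer
    candidate epitopes spanning the variant site, scores peptide-allele
    binding (via a deterministic surrogate predictor or parsed external
    prediction tables), counts strong binders per patient, and runs the
    accompanying cohort statistics: HLA allele-frequency comparison
    against a reference population, Fisher exact and Mann-Whitney group
    tests, ROC/Youden dichotomization of the load, adjusted odds ratios
    from binary logistic regression, and simulation-based power for
    two-group Fisher designs. A synthetic-cohort generator reproduces
    the statistical structure of a two-group (early/late-onset) study
    so the entire pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
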