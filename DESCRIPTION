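Package: securelogit
Title: Privacy-Preserving Multi-Institutional Logistic Regression with
    Homomorphic-Encryption Arithmetic
Version: 0.1.0
Authors@R:
    person("securelogit", "developers", email = "maintainers@securelogit.dev",
           role = c("aut", "cre"))
Description: Tools for studying privacy-preserving clinical risk prediction
    across hospitals that cannot share patient-level data in the clear.
    Provides a synthetic multi-hospital perioperative cohort generator with
    block-correlated laboratory panels, rare binary mortality outcomes and
    MCAR missingness; median-imputation / per-site standardization / one-hot
    preprocessing; a from-scratch minibatch logistic regression trainer
    (Nesterov accelerated gradient, polynomial sigmoid approximation, ridge
    penalty); a CKKS-style leveled homomorphic arithmetic contract with a toy
    reference backend (slot vectors, scale and level bookkeeping, audited
    ciphertext refresh); an encrypted trainer that mirrors the plaintext
    arithmetic operation-for-operation so ciphertext/plaintext parity is
    testable; discrimination metrics (AUROC, AUPRC, DeLong test, stratified
    bootstrap confidence intervals); and experiment drivers for cross-site
    validation matrices, incremental model-adaptation curves and parity
    studies, behind a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
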