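Package: jmccm
Title: Joint Mean and Constant Covariance Modelling of eQTL Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood joint estimation of a sparse genotype-to-expression
    coefficient matrix and a sparse precision matrix (conditional gene network)
    parametrized by the modified Cholesky decomposition. Variable selection is
    performed by consecutive stepwise stages using Rao score statistics for
    addition, Wald statistics for deletion, and GCV/BIC as stopping criteria.
    Includes a simulation framework for sparse eQTL scenarios with optional
    linkage-disequilibrium genotype blocks, and scoring of estimated networks
    by Stein loss, Frobenius distance and support-recovery metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
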