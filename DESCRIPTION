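Package: crossLeverage
Title: Cross Leverage Scores for Screening Variable Interactions in
    High-Dimensional Genetic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variable selection for interaction effects in the p >> n
    regime, aimed at SNP epistasis screening. Computes cross leverage
    scores, the off-diagonal hat-matrix entries linking each variable to
    the response in the augmented matrix [X, y]', and three scalable
    approximations: sliding windows, random windows, and a sparse
    oblivious subspace embedding (CountSketch/OSNAP-style) with a
    user-set accuracy parameter. Includes a genotype simulator under
    Hardy-Weinberg equilibrium with logistic disease models driven by
    Boolean SNP interactions, a recovery-based evaluation harness,
    readers for delimited genotype tables, PLINK .raw-style files and
    minimal VCF, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    jsonlite,
    optparse,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
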