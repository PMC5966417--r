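Package: coevolang
Title: Gene-Culture Coevolution of Language in a One-Dimensional Linguistic Space
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulator of gene-culture coevolution of language.
    Agents carry two genotypes, an innate language ability and a linguistic
    plasticity half-width; languages are points on a one-dimensional
    expressiveness axis and evolve through four cultural processes (change,
    division, extinction, fusion) driven by use in pairwise communication.
    The package also implements the two downstream analyses: evolutionary
    rates in darwins swept over measurement intervals, and directional-effect
    quantification via plug-in transfer entropy with surrogate-shuffle
    correction (effective transfer entropy) and Wilcoxon rank-sum comparison
    across replicate runs. Includes deterministic analytic fixtures, replicate
    and parameter-sweep orchestration, CSV/JSONL run output, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
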