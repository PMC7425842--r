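Package: kinerr
Title: Error Rates in Forensic Kinship Testing by Likelihood Ratio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and exact-enumeration tools for studying false
    conclusion rates in DNA familial relationship testing with autosomal
    STR panels. Simulates pedigree genotypes (standard trio, parent-child,
    full sibling, half sibling, first cousin, unrelated) by Mendelian gene
    dropping under Hardy-Weinberg equilibrium, computes kinship likelihood
    ratios (paternity index for trios, IBD-coefficient likelihood ratios
    for pairwise relationships), estimates false negative, false positive
    and inconclusive rates under inclusion/exclusion threshold policies,
    and projects expected numbers of wrongly interpreted cases under a
    global caseload model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
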