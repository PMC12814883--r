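Package: crisprarrays
Title: Comparative Analysis of Multiple CRISPR Arrays and Co-Occurring Cas Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of prokaryotic genomes that carry
    multiple CRISPR arrays and multiple CRISPR-Cas systems. Reads per-genome
    annotation tables of spacer arrays and Cas loci, assigns arrays to their
    nearest Cas locus, and computes: observed versus expected co-occurrence of
    Cas types with signed fold-changes and exact binomial tests; distance and
    orientation distributions of arrays around Cas loci; a redundancy census of
    identical consensus repeats and shared spacers; relative spacer
    insertion-rate weights under an independent deletion model together with a
    neutral multinomial null; and consensus-repeat similarity analysis via
    Levenshtein distances, metric SMACOF multidimensional scaling, and Gaussian
    kernel density estimates. Includes a synthetic cohort generator with known
    ground truth for parameter-recovery testing and a reproducible pipeline
    driver.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
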