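Package: ddradmap
Title: ddRAD-Based F2 Genetic Map Construction and Scaffold Anchoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end toolkit for building high-density F2 genetic
    linkage maps from double-digest RAD (ddRAD) genotyping data and for
    anchoring draft-genome scaffolds into pseudochromosomes. Includes in
    silico double-restriction digestion for enzyme-pair evaluation, a
    two-stage genotype filter cascade (site quality, then population-level
    criteria), EM estimation of pairwise recombination fractions with LOD
    scores, LOD-threshold grouping, marker ordering by minimum sum of
    adjacent recombination fractions with singleton-based iterative
    refinement, Kosambi map distances, co-segregation bin markers,
    chi-square tests for segregation distortion and detection of
    segregation distortion regions, and AGP/FASTA pseudochromosome
    construction. A fully parameterised F2 population simulator with a
    recorded truth set makes every stage testable against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
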