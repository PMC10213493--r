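Package: hapclean
Title: Haplotype-Informed Error Correction for Low-Coverage Genotyping Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects genotyping errors in low-coverage reduced-representation
    sequencing data (GBS, RAD-seq) from biparental and multiparental crossing
    populations. A hidden Markov model over ancestral-haplotype pairs jointly
    estimates founder and offspring genotypes from per-marker allele read
    counts, with marker-specific allele-read bias and read-mismapping rates
    learned by iterative parameter optimization. Includes a crossing-population
    read-count simulator (F2, outbred F1, 8-way RIL designs) and evaluation
    metrics (call rates, masked-call concordance, recombination-segment
    statistics, segregation distortion).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
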