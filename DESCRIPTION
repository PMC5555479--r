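Package: chiasmr
Title: Heterochiasmy and QTL Analysis for Outbred Four-Way Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects crossovers from phased offspring genotypes of an outbred
    (four-way) cross, applies a windowed even-parity correction for
    genotyping-error-induced double crossovers, and summarises sex-specific
    recombination (heterochiasmy) overall and stratified by chromosome class
    and residual-tetraploidy status, including centromere-end inference from
    the male crossover distribution. Also provides marker and sample quality
    control (segregation-distortion chi-square tests, duplicate detection,
    crossover-count outliers, phenotype outlier trimming) and a single-locus
    QTL scan with permutation-based genome- and chromosome-wide thresholds,
    1.5-LOD support intervals, multi-QTL percent-variance-explained fits and
    sex-by-genotype interaction tests. A meiosis simulator for four-way
    crosses with known ground truth (crossover positions, planted QTL,
    injected genotyping errors, residual-tetraploidy masking, a sex-linked
    chromosome) supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
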