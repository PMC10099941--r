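Package: allohybrid
Title: Dissecting Hybridization and Whole-Genome Duplication Effects on Gene
    Expression in Resynthesized Allopolyploids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for factorial hybrid/polyploid expression
    experiments in which diploid parents, diploid hybrids, autotetraploids
    and allotetraploids are profiled together. Provides TPM/CPM/TMM
    normalization, negative-binomial differential expression with pairwise
    group contrasts, a ten-category additive/nonadditive classification of
    hybrid gene expression (expression-level dominance and transgressive
    expression), per-individual extreme-expression rank counts, transposable
    element transcript-abundance tests with quasi-binomial GLMs, one-way
    ANOVA with Tukey HSD compact letter displays for phenotypes, and
    leading-log-fold-change multidimensional scaling. A synthetic-data
    generator reproduces the statistical structure of a seven-group
    (two parents, diploid hybrid, two autotetraploids, two allotetraploids)
    by two-tissue design so that every stage can be exercised and calibrated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    car,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
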