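Package: kernelreg
Title: Inheritance Modes, Cis/Trans Regulatory Divergence, and
    Co-Expression Networks for Hybrid Seed Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis stack for maize hybrid/parent seed-development
    transcriptomes. Classifies hybrid gene expression into additive and
    nonadditive (dominance, over-dominance, under-dominance) inheritance
    modes against the mid-parent value; assigns seven-way cis/trans
    regulatory-divergence patterns to SNPs and genes from allele-specific
    read counts in hybrid and parental libraries; builds weighted gene
    co-expression networks with topological-overlap module detection,
    module eigengenes, module-trait correlation and hub-gene extraction.
    Includes a synthetic-data generator with planted ground truth
    (negative-binomial allele counts under configurable cis and trans
    effects, trio expression under the four inheritance modes, and
    factor-driven module structure with kernel traits) so every stage is
    exercised end-to-end with known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
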