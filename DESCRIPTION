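Package: hemibank
Title: Design of HLA Hemizygous Stem-Cell Haplobanks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for designing immune-compatible stem-cell banks built
    from HLA-A/B hemizygous (homozygous-like) cell lines. Parses and
    compares HLA allele names at a chosen field resolution, builds
    population haplotype-frequency models (linkage-equilibrium products
    of allele frequencies or directly supplied haplotype tables, with
    Hardy-Weinberg genotype simulation), enumerates the mono-allelic
    knockout products obtainable from heterozygous parental lines,
    computes the fraction of a population immunologically matched by a
    combo library (exactly and by Monte Carlo), and greedily selects
    minimal line sets reaching a coverage threshold. Supporting modules
    design allele-discriminating CRISPR-Cas9 guides, classify amplicon
    indel patterns into frameshift/knockout calls, compute mitotic
    indices from division histograms, and generate synthetic frequency
    tables and line panels with tunable linkage disequilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
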