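Package: cnvscreen
Title: CNV, Runs-of-Homozygosity and Mosaicism Screening from SNP-Array
    Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A case-control screening pipeline for SNP-array intensity data
    (Log R Ratio and B-allele frequency). Includes a synthetic-cohort
    generator with planted copy-number variants, mosaic chromosomal
    alterations and autozygous segments; sample- and marker-level quality
    control (intensity outlier screens, Hardy-Weinberg and sex-differential
    marker tests, LD pruning, method-of-moments relatedness, ancestry PCA);
    principal-component and GC-wave intensity correction; a six-state
    distance-aware hidden Markov model for autosomal CNV calling with
    Bayes-factor confidence, probe-count filtering, adjacent-call merging
    and centromere splitting; an arm-level BAF dispersion screen and
    two-state BAF HMM for mosaic event detection with cell-fraction
    estimation; rule-based runs-of-homozygosity calling and case-control
    region scans; and label-permutation burden and segmental association
    tests with pointwise and family-wise empirical p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
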