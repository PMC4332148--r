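Package: proteoPCP
Title: Protein Correlation Profiling and AP-MS Analysis of Proteasome
    Complex Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to dissect the composition of heterogeneous supramolecular
    protein complexes from label-free quantitative mass spectrometry, using
    the proteasome as the model system. Implements internal-standard
    calibrated TOP3 protein abundance indexes (PAIs) from peptide-level
    quantification tables, chi-squared distances between normalized
    sedimentation profiles for protein correlation profiling of density
    gradient fractions, squared Pearson correlation (R2) of protein
    abundances across affinity-purified samples against reference
    sub-complexes, supervised and unsupervised (Pearson-n PCA, UPGMA)
    clustering of abundance patterns, and differential quantification of
    regulator association between conditions via core-particle-normalized
    PAIs with Student t-tests. A peptide-level synthetic data generator with
    a recorded ground truth makes every stage testable without raw MS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
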