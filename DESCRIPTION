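Package: spatGBLUP
Title: Genomic Prediction with Parametric Spatial Kernels for Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits genomic selection (GBLUP) mixed models for plant-breeding
    field trials with an optional parametric spatial kernel (Power, Gaussian
    or Spherical correlation of plot effects; isotropic or Range/Column
    directional) and optional random Range and Column effects for extraneous
    field variation. Variance components are estimated by restricted maximum
    likelihood (REML) with Fisher scoring. The best spatial structure is
    selected by repeated cross-validation over genotypes using prediction
    root-mean-squared error, with likelihood-ratio tests against chi-square
    mixture thresholds and Cullis generalized heritability. Includes a
    field-trial simulator for studying when spatial modelling improves the
    accuracy of estimated genotypic effects, plus helpers to read trial
    tables and SNP dosage matrices and to build VanRaden genomic relationship
    matrices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
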