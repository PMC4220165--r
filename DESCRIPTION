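Package: pcstrat
Title: Population Structure and Platform-Bias Control for Merged Genotype Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for controlling population stratification and
    genotyping-platform or recruitment-site batch effects when genotype data
    from multiple cohorts are merged for association analysis. Provides
    genotype readers and writers (VCF, PLINK text, dosage TSV), cross-cohort
    allele harmonization, a variant-selection checklist (autosomes, minor
    allele frequency, missingness, sliding-window LD pruning, artifact-region
    exclusion), principal component analysis of the sample covariance matrix,
    an alternative reference-panel projection that derives SNP loadings from
    an external panel and projects study samples onto them, SNP-component
    correlation diagnostics with artifact-region flagging, median-based
    ancestry assignment, logistic genome-wide association with genomic
    inflation control, and a multi-site multi-platform genotype simulator
    under the Balding-Nichols model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
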