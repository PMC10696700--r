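Package: stepcore
Title: Stepwise Core Collection Construction from Pedigree and Genomic Relationships
Version: 0.1.0
Authors@R:
    person("Fresh", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds representative core collections for plant breeding
    programs by fusing incomplete pedigree records with partial SNP
    genotyping. Provides the tabular-method additive relationship matrix
    (A), SNP dosage curation (minor-allele-frequency and missingness
    filters, mean imputation, LD pruning, cross-platform merging), the
    VanRaden genomic relationship matrix (G), single-step hybrid
    pedigree-genomic relationships (H), conversion to a scaled distance
    matrix, and stochastic subset optimization of the
    accession-to-nearest-entry (A-NE) criterion with mandatory entries and
    multi-run consensus. Includes pedigree-completeness and
    pedigree-vs-genomic concordance diagnostics, marker-subsampling
    reliability analysis, principal components of relationship matrices,
    and a gene-dropping simulator that supplies exact realized
    identity-by-descent for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Config/testthat/edition: 3
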