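Package: ibdscan
Title: Identity-by-Descent Mapping with Multi-Individual IBD Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variance-component identity-by-descent (IBD) mapping for
    quantitative traits in large outbred populations.  Local relatedness
    matrices are built from multi-individual IBD clusters obtained by
    merging haplotypes that share long identical allele sequences around a
    focal position, and a restricted-maximum-likelihood LOD-score test
    evaluates whether local IBD sharing explains phenotypic variance beyond
    genome-wide relatedness.  Genome-wide significance is assessed with a
    modified Ornstein-Uhlenbeck model of the scan-statistic autocorrelation:
    the decay parameter is estimated from null scans, given a bootstrap
    confidence interval by resampling chromosomes, and converted into a
    Monte-Carlo max-statistic threshold.  A synthetic-data module simulates
    phased populations (via the msprime coalescent simulator when
    available), phenotypes with minor-allele-frequency-classified causal
    variants, and SNP-array downsampling for type-I-error and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    data.table,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
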