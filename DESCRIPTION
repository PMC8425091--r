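Package: aselink
Title: Linkage Attacks and Re-Identification Risk Auditing for
    Allele-Specific Expression Gene Lists
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the re-identification risk carried by lists of
    allele-specific expressed (ASE) gene names. A gene can only be called
    allele-specific in an individual if that individual carries an
    accessible heterozygous SNP in its exons; aselink exploits this to
    infer candidate heterozygous SNP sets from bare gene symbols, link
    them against a multi-sample genotype panel with self-information
    (rarity) weights, and quantify linking confidence with a gap statistic
    under a permutation null and with entropy-based matching
    probabilities. Both attack directions are supported (gene list to
    anonymized genome, and known genome to anonymized gene list with its
    attached phenotype), together with gene-level risk analyses
    (prevalence, self-information, list sanitization, top-k accuracy) and
    a synthetic diploid cohort generator for end-to-end evaluation without
    access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: SNP, Genetics, Software, Sequencing
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
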