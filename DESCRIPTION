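Package: TrioCascade
Title: Family-Based Rare-Variant Prioritization for Recessive Oocyte
    Maturation Arrest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a family-based whole-exome variant
    prioritization cascade for autosomal-recessive disease gene
    discovery, modelled on the screens used for oocyte maturation
    arrest cohorts: population allele-frequency filtering against
    multiple reference databases, functional-class filtering with a
    deep-intronic rescue path, recessive inheritance-model detection in
    trios (homozygous and trans-configured compound heterozygotes),
    runs-of-homozygosity prioritization in consanguineous families,
    cross-family candidate gene intersection, and oocyte expression
    filtering. Includes transcript-model coordinate arithmetic for
    HGVS-style cDNA and protein consequence calls, a deterministic
    synthetic trio-cohort simulator with planted causal alleles for
    end-to-end validation, and reporting of per-stage filter traces and
    clinical oocyte outcome summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: VariantAnnotation, Genetics, SNP, Sequencing, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'VariantSet-methods.R'
    'roh.R'
    'gene-model.R'
    'consequence.R'
    'io-freq.R'
    'filters.R'
    'inheritance.R'
    'cohort.R'
    'simulate.R'
    'pipeline.R'
    'cli.R'
    'io-ped.R'
    'io-vcf.R'
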