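Package: sceTR
Title: Single-Cell Expression Quantitative Trait Tandem Repeat Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping tandem repeat (TR) length variation to cell
    type-specific gene expression from paired whole-genome and single-cell
    RNA sequencing cohorts. Provides TR catalog algebra (cyclic/reverse
    complement motif canonicalization, overlap-based catalog merging,
    detection of indels that re-encode TR alleles), genotype quality control
    (mode-window outlier masking, call-rate, heterozygosity and exact
    binomial Hardy-Weinberg filters), per-cohort ordinary least squares
    association of summed repeat dosage with inverse-normal transformed
    pseudobulk expression, DerSimonian-Laird random-effects meta-analysis
    with permutation calibration and a pairwise cell-type-specificity
    classifier, ACAT Cauchy-combination gene-level p-values with Storey
    q-value FDR control, single-causal-variant approximate-Bayes-factor
    fine-mapping with conditional analysis, enumeration-based colocalization
    against external trait associations, genotype-validation machinery
    (PCR fragment-to-repeat conversion, offset scoring, concordance), and a
    synthetic cohort generator under a stepwise mutation model for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, GeneExpression, SingleCell, SNP, QualityControl,
    StatisticalMethod
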