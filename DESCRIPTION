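Package: panmix
Title: Testing Within-Population Genetic Structure with Small SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether individuals sampled from putative
    subgroups of a single population (for example fish caught in littoral,
    benthic and pelagic habitats of one lake) form a panmictic unit, using a
    modest panel of unlinked biallelic SNPs. Provides genotype input/output
    (a simple TSV dialect and VCF), per-locus quality control with an exact
    Hardy-Weinberg test and composite-dosage linkage screening,
    Weir-Cockerham variance-components Fst with a forward Wright-Fisher
    island-model simulator and subsampling null distribution,
    standardized-genotype kinship matrices and their principal components,
    six pairwise coancestry estimators (moment and dyadic maximum
    likelihood) with a label-permutation test of within-group relatedness,
    a Gibbs-sampler admixture model, synthetic-data generators for all of
    the above, and a one-call pipeline producing a consolidated report.
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
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
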