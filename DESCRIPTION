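Package: rumenmine
Title: Combinatorial Case-Control Mining of Rumen Microbiome and Host Genotype Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking rumen microbiome composition, host
    genotype and methane/feed-efficiency phenotypes in dairy cattle.
    Covariate-adjusted trait residuals are binarized into cases and controls;
    taxon relative abundances are decile-binned and host genotypes
    quality-controlled (MAF, missingness, exact Hardy-Weinberg test, windowed
    LD thinning, PCA outlier removal); a layer-wise combinatorial engine mines
    feature:bin combinations validated by Fisher's exact and two-proportion
    z tests under false-discovery-rate control; mined networks are summarised
    as taxon co-occurrence graphs and differential-enrichment tables; taxon
    abundances are treated as quantitative traits for VanRaden GRM
    construction and eigendecomposition-based REML heritability, with
    single-SNP association for comparison; combinations are scored as
    classifiers via Youden's J against bootstrap nulls. A synthetic-cohort
    generator with planted signal makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
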