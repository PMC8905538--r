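#!/usr/bin/env Rscript
# Stage 3 — microbiome core filter + decile binning, and genotype QC.
#
# Taxa must be nonzero in >= 70% of animals AND >= 400 animals (the absolute
# floor scaled to this cohort from the study's 600-of-995 rule); survivors
# are binned per taxon into 10 equal-width bins. Genotypes pass PCA outlier
# removal, missingness <= 0.05, MAF >= 0.05, exact HWE p >= 0.001 and
# windowed LD thinning at r2 0.8.
#
# Output: results/03_core_taxa.tsv, results/03_bin_histogram.tsv,
#         results/03_qc_report.tsv
source("analysis/00_config.R")

coh <- build_cohort()
core <- core_taxa_filter(coh$taxa$abundance, prevalence = 0.7,
                         min_samples = 400)
message(sprintf("core filter: %d of %d taxa kept",
                ncol(core$ab), ncol(coh$taxa$abundance$ab)))
tsv(data.frame(taxon = colnames(coh$taxa$abundance$ab),
               kept = colnames(coh$taxa$abundance$ab) %in% attr(core, "kept")),
    "03_core_taxa.tsv")

bm <- bin_abundances(core, n_bins = 10)
hist_df <- as.data.frame(t(apply(bm$codes, 2, tabulate, nbins = 10)))
names(hist_df) <- paste0("bin", 1:10)
hist_df <- cbind(taxon = rownames(hist_df), hist_df)
tsv(hist_df, "03_bin_histogram.tsv")

qc <- qc_genotypes(coh$genotypes, maf = 0.05, geno = 0.05, hwe = 0.001,
                   r2 = 0.8)
message(sprintf("genotype QC: %d animals removed as PCA outliers; %d of %d SNPs kept",
                length(qc$animals_removed), ncol(qc$genotypes$geno),
                ncol(coh$genotypes$geno)))
tsv(qc$report$maf_geno, "03_qc_report.tsv")
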