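# Shared study configuration for the analysis scripts.
#
# One synthetic dairy-cow cohort is used throughout: 600 animals, 2,000 SNPs
# in HWE, 150 order-level taxa (zero-inflated, compositional). Two taxa are
# heritable (h2 0.35 and 0.55), one taxon's latent mean is shifted by 1 sd in
# prospective high-emitter animals (the planted engine signal), and the
# methane-like phenotype is driven by farm and intake covariates.
library(rumenmine)

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

cohort_config <- sim_config(
  n_animals = 600, n_snps = 2000, n_taxa = 150,
  heritable_taxa = data.frame(taxon = c(12, 30), h2 = c(0.35, 0.55)),
  # structural-zero rates spread across taxa so the core prevalence filter
  # has something to discriminate (rare taxa drop out, core taxa survive)
  zero_inflation = seq(0.05, 0.6, length.out = 150),
  covariate_effects = c(farm = 1, dm_intake = 0.3, starch_intake = 0.2,
                        ndf_intake = 0.2),
  planted_shift = list(taxon = 42, delta = 1),
  noise_sd = 1,
  seed = 2024L)

build_cohort <- function() simulate_cohort(cohort_config)

tsv <- function(df, name) {
  path <- file.path(results_dir, name)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  message("wrote ", path)
  path
}
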