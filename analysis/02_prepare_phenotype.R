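#!/usr/bin/env Rscript
# Stage 2 — covariate selection, residualization, case/control binarization.
#
# LASSO (cross-validated, 1-SE rule) screens the covariates; the survivors
# are refit by OLS; animals are labelled case/control from the residual
# z-score with the +/-0.5 sd exclusion band.
#
# Output: results/02_selected_covariates.tsv, results/02_assignment.tsv
source("analysis/00_config.R")

coh <- build_cohort()
sel <- select_covariates(coh$phenotype, coh$covariates, seed = 1)
message("LASSO-selected covariates: ", paste(sel$selected, collapse = ", "))
tsv(sel$refit, "02_selected_covariates.tsv")

res <- residualize(coh$phenotype, coh$covariates, sel$selected)
cc <- binarize_z(res, cutoff_sd = 0.5)
counts <- table(cc$label)
message(sprintf("labels: %d cases, %d controls, %d excluded (band = %.0f%%)",
                counts[["case"]], counts[["control"]], counts[["excluded"]],
                100 * counts[["excluded"]] / sum(counts)))
tsv(cc, "02_assignment.tsv")
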