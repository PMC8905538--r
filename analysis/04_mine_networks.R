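#!/usr/bin/env Rscript
# Stage 4 — layer-wise combinatorial mining, co-occurrence networks, and
# differential taxon enrichment between the two directions.
#
# Output: results/04_networks.tsv, results/04_enrichment_records.tsv,
#         results/04_enrichment_animals.tsv,
#         results/04_case_network.graphml, results/04_control_network.graphml
source("analysis/00_config.R")

coh <- build_cohort()
sel <- select_covariates(coh$phenotype, coh$covariates, seed = 1)
res <- residualize(coh$phenotype, coh$covariates, sel$selected)
cc <- binarize_z(res, cutoff_sd = 0.5)
core <- core_taxa_filter(coh$taxa$abundance, prevalence = 0.7,
                         min_samples = 400)
bm <- bin_abundances(core)

mn <- mine(bm, cc, alpha = 0.05, correction = "BH", max_layer = 3,
           beam_width = 200)
per_layer <- vapply(mn$records, nrow, integer(1))
message("significant records per layer: ",
        paste(seq_along(per_layer), per_layer, sep = ":", collapse = "  "))
write_networks_tsv(mn, file.path(results_dir, "04_networks.tsv"))

recs <- as.data.frame(mn)
top <- recs[order(recs$adjusted_p), ][1:5, c("pairs", "a", "c", "direction",
                                             "adjusted_p")]
message("top records:")
print(top, row.names = FALSE)

for (dir_ in c("case-enriched", "control-enriched")) {
  if (!any(recs$direction == dir_)) next
  g <- build_graph(mn, dir_)
  out <- file.path(results_dir, paste0(
    "04_", sub("-enriched", "", dir_), "_network.graphml"))
  write_network_graphml(g, out)
  message(dir_, " graph: ", igraph::vcount(g), " taxa, ",
          igraph::ecount(g), " edges -> ", out)
}

rc <- recs[recs$direction == "case-enriched", ]
rk <- recs[recs$direction == "control-enriched", ]
if (nrow(rc) && nrow(rk)) {
  en_rec <- taxon_enrichment(rc, rk, basis = "records")
  en_ani <- taxon_enrichment(rc, rk, basis = "animals", binned = bm,
                             labels = cc)
  message(sprintf("differentially represented taxa (animal basis): %d / %d",
                  sum(en_ani$flagged), nrow(en_ani)))
  tsv(en_rec, "04_enrichment_records.tsv")
  tsv(en_ani, "04_enrichment_animals.tsv")
}
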