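rec_df <- function(pairs, direction, layer = NULL) {
  if (is.null(layer))
    layer <- lengths(regmatches(pairs, gregexpr(";", pairs))) + 1
  data.frame(pairs = pairs, a = 1, b = 1, c = 1, d = 1, fisher_p = 0.01,
             z = 1, direction = direction, adjusted_p = 0.01, layer = layer,
             stringsAsFactors = FALSE)
}

as_networks <- function(df) {
  structure(list(records = split(df, df$layer), n_cases = 10,
                 n_controls = 10, params = list()),
            class = "mined_networks")
}

test_that("co-occurrence graphs count record pairs and classify nodes", {
  df <- rec_df(c("A:9;B:8", "A:9;C:2"), "case-enriched")
  g <- build_graph(as_networks(df), "case-enriched")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  cls <- setNames(igraph::V(g)$abundance_class, igraph::V(g)$name)
  expect_identical(cls[["A"]], "high")
  expect_identical(cls[["B"]], "high")
  expect_identical(cls[["C"]], "low")
  ew <- igraph::as_data_frame(g, "edges")
  expect_equal(nrow(ew), 2)
  expect_true(all(ew$weight == 1))

  # duplicated record doubles its edge weights
  g2 <- build_graph(as_networks(rec_df(rep("A:9;B:8", 2), "case-enriched")),
                    "case-enriched")
  expect_equal(igraph::E(g2)$weight, 2)

  # layer-1-only records give isolated nodes, zero edges
  g3 <- build_graph(as_networks(rec_df(c("A:9", "C:1"), "case-enriched")),
                    "case-enriched")
  expect_equal(igraph::ecount(g3), 0)
  expect_equal(igraph::vcount(g3), 2)
})

test_that("total edge weight equals the sum of per-record pair counts", {
  set.seed(41)
  taxa <- paste0("t", 1:8)
  mk <- function(k) paste(paste0(sample(taxa, k), ":",
                                 sample(1:10, k, TRUE)), collapse = ";")
  pairs <- vapply(sample(2:4, 30, TRUE), mk, character(1))
  df <- rec_df(pairs, "case-enriched")
  g <- build_graph(as_networks(df), "case-enriched")
  expect_equal(sum(igraph::E(g)$weight), sum(choose(df$layer, 2)))
})

test_that("taxon enrichment reproduces the pooled z test on record counts", {
  case_recs <- rec_df(c(rep("T1:9", 20), replicate(80, paste0(
    "X", sample(5, 1), ":", sample(10, 1)))), "case-enriched")
  ctrl_recs <- rec_df(c(rep("T1:2", 5), replicate(95, paste0(
    "X", sample(5, 1), ":", sample(10, 1)))), "control-enriched")
  en <- taxon_enrichment(case_recs, ctrl_recs, basis = "records")
  r <- en[en$taxon == "T1", ]
  expect_equal(r$a, 20); expect_equal(r$c, 5)
  expect_equal(r$z, two_proportion_z(20, 100, 5, 100)$z, tolerance = 1e-12)
  expect_equal(unname(r$z), 3.2071349, tolerance = 1e-6)
  expect_true(r$flagged)

  # identical representation: z = 0, never flagged
  en2 <- taxon_enrichment(rec_df(rep("T1:9", 10), "case-enriched"),
                          rec_df(rep("T1:2", 10), "control-enriched"))
  expect_equal(en2$z, 0)
  expect_false(en2$flagged)

  # swapping the directions negates every z
  en3 <- taxon_enrichment(ctrl_recs, case_recs, basis = "records")
  m <- match(en$taxon, en3$taxon)
  expect_equal(en$z, -en3$z[m], tolerance = 1e-12)
})

test_that("animal-basis enrichment counts carriers of containing records", {
  codes <- matrix(c(rep(9L, 8), rep(1L, 12)), ncol = 1,
                  dimnames = list(NULL, "T1"))
  b <- toy_binned(codes)
  lab <- toy_labels(rownames(b$codes), 10, 10)
  en <- taxon_enrichment(rec_df("T1:9", "case-enriched"),
                         rec_df("T1:1", "control-enriched"),
                         basis = "animals", binned = b, labels = lab)
  # cases s01..s10: 8 carry T1=9; controls s11..s20: all carry T1=1
  expect_equal(en$a, 8)
  expect_equal(en$c, 10)
})

test_that("an end-to-end planted taxon is flagged by animal-basis enrichment", {
  # A single upward-shifted taxon dominates the records of BOTH directions
  # (its low bins validate control-enriched, its high bins case-enriched), so
  # the record-basis proportions are near-symmetric by construction; the
  # animal basis contrasts carriage rates and detects the shift.
  hits <- 0; tried <- 0
  for (s in 1:5) {
    cfg <- sim_config(n_animals = 600, n_snps = 10, n_taxa = 40,
                      covariate_effects = c(dm_intake = 0.5),
                      planted_shift = list(taxon = 7, delta = 1.5),
                      seed = 900 + s)
    coh <- simulate_cohort(cfg)
    res <- residualize(coh$phenotype, coh$covariates, "dm_intake")
    cc <- binarize_z(res)
    bm <- bin_abundances(coh$taxa$abundance)
    recs <- as.data.frame(mine(bm, cc, max_layer = 2, beam_width = 40))
    rc <- recs[recs$direction == "case-enriched", ]
    rk <- recs[recs$direction == "control-enriched", ]
    if (!nrow(rc) || !nrow(rk)) next
    tried <- tried + 1
    en <- taxon_enrichment(rc, rk, basis = "animals", binned = bm,
                           labels = cc)
    r <- en[en$taxon == "taxon007", ]
    if (nrow(r) == 1 && r$flagged) hits <- hits + 1
  }
  expect_gte(tried, 3)
  expect_gte(hits, ceiling(0.8 * tried))
})
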