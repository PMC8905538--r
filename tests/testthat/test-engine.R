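test_that("carriers implements conjunction with missing-never-matches", {
  codes <- rbind(c(9L, 2L), c(9L, 2L), c(9L, 5L), c(1L, 2L), c(NA, 2L))
  colnames(codes) <- c("A", "B")
  b <- toy_binned(codes)
  expect_identical(carriers(b, data.frame(feature = character(0),
                                          bin = integer(0))),
                   rownames(b$codes))                     # empty conjunction
  expect_identical(carriers(b, data.frame(feature = "A", bin = 9)),
                   c("s01", "s02", "s03"))
  both <- carriers(b, data.frame(feature = c("A", "B"), bin = c(9, 2)))
  expect_identical(both,
                   intersect(carriers(b, data.frame(feature = "A", bin = 9)),
                             carriers(b, data.frame(feature = "B", bin = 2))))
  expect_identical(carriers(b, data.frame(feature = "A", bin = 1)), "s04")
  expect_error(carriers(b, data.frame(feature = "Z", bin = 1)), "unknown")
})

test_that("fisher_exact matches hand values and the brute-force oracle", {
  expect_equal(fisher_exact(5, 0, 0, 5, "greater"), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(fisher_exact(0, 8, 0, 9, "greater"), 1)
  expect_equal(fisher_exact(0, 8, 0, 9, "two.sided"), 1)
  set.seed(1)
  for (i in 1:200) {
    cell <- as.vector(stats::rmultinom(1, sample(4:20, 1), rep(0.25, 4)))
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(fisher_exact(cell[1], cell[2], cell[3], cell[4], alt),
                   oracle_fisher(cell[1], cell[2], cell[3], cell[4], alt),
                   tolerance = 1e-12)
      expect_equal(fisher_exact(cell[1], cell[2], cell[3], cell[4], alt),
                   stats::fisher.test(matrix(cell, 2, byrow = TRUE),
                                      alternative = alt)$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("two-proportion z follows the pooled formula and its symmetries", {
  expect_equal(two_proportion_z(10, 50, 10, 50)$z, 0)
  expect_equal(two_proportion_z(10, 50, 10, 50)$p, 1)
  expect_equal(two_proportion_z(30, 50, 15, 50)$z,
               0.3 / sqrt(0.45 * 0.55 * 0.04), tolerance = 1e-12)
  expect_equal(two_proportion_z(7, 20, 13, 25)$z,
               -two_proportion_z(13, 25, 7, 20)$z, tolerance = 1e-12)
  expect_equal(two_proportion_z(0, 10, 0, 15)$p, 1)   # degenerate pool
})

test_that("a perfectly separating feature yields both one-sided records", {
  codes <- matrix(c(rep(9L, 6), rep(2L, 6)), ncol = 1,
                  dimnames = list(NULL, "A"))
  b <- toy_binned(codes)
  lab <- toy_labels(rownames(b$codes), 6, 6)
  mn <- mine(b, lab, max_layer = 1, min_carriers = 1)
  r <- mn$records[[1]]
  expect_setequal(r$pairs, c("A:9", "A:2"))
  expect_equal(r$fisher_p, rep(1 / choose(12, 6), 2), tolerance = 1e-12)
  expect_identical(sort(r$direction), c("case-enriched", "control-enriched"))
})

test_that("stored counts always reproduce from carriers()", {
  set.seed(23)
  codes <- matrix(sample(1:4, 60 * 6, TRUE), 60, 6,
                  dimnames = list(NULL, paste0("f", 1:6)))
  b <- toy_binned(codes, range = c(1L, 4L))
  lab <- toy_labels(rownames(b$codes), 25, 25)
  mn <- mine(b, lab, alpha = 1, max_layer = 2, min_carriers = 1,
             beam_width = Inf)
  recs <- as.data.frame(mn)
  expect_gt(nrow(recs), 0)
  for (i in seq_len(nrow(recs))) {
    ids <- carriers(b, parse_pairs(recs$pairs[i]))
    lab_i <- lab$label[match(ids, lab$animal_id)]
    expect_identical(sum(lab_i == "case"), as.integer(recs$a[i]))
    expect_identical(sum(lab_i == "control"), as.integer(recs$c[i]))
  }
})

test_that("adding a pair never enlarges the carrier set", {
  set.seed(29)
  codes <- matrix(sample(1:5, 40 * 5, TRUE), 40, 5,
                  dimnames = list(NULL, paste0("f", 1:5)))
  b <- toy_binned(codes, range = c(1L, 5L))
  for (rep in 1:20) {
    f <- sample(colnames(codes), 3)
    bins <- sample(1:5, 3, TRUE)
    c2 <- carriers(b, data.frame(feature = f[1:2], bin = bins[1:2]))
    c3 <- carriers(b, data.frame(feature = f, bin = bins))
    expect_true(all(c3 %in% c2))
  }
})

test_that("mining pure noise rarely reports anything under BH", {
  sig <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    codes <- matrix(sample(1:10, 200 * 20, TRUE), 200, 20,
                    dimnames = list(NULL, paste0("f", 1:20)))
    b <- toy_binned(codes)
    lab <- toy_labels(rownames(b$codes), 100, 100)
    mn <- mine(b, lab, max_layer = 1)
    sig <- sig + (nrow(mn$records[[1]]) > 1)
  }
  expect_lte(sig, 2)   # at most rare false layers under the null
})

test_that("beam-disabled mining equals exhaustive enumeration", {
  set.seed(31)
  for (rep in 1:5) {
    nf <- sample(4:8, 1)
    codes <- matrix(sample(1:10, 30 * nf, TRUE), 30, nf,
                    dimnames = list(NULL, paste0("f", 1:nf)))
    # plant one informative feature so significant sets are often non-empty
    codes[1:12, 1] <- 9L
    b <- toy_binned(codes)
    lab <- toy_labels(rownames(b$codes), 12, 12)
    mn <- mine(b, lab, max_layer = 2, beam_width = Inf, min_carriers = 0)
    labs <- lab$label[match(rownames(b$codes), lab$animal_id)]
    use <- labs != "excluded"
    orc <- oracle_mine(b$codes[use, , drop = FALSE], labs[use] == "case")
    for (layer in 1:2) {
      got <- mn$records[[layer]]
      want <- list(orc$l1, orc$l2)[[layer]]
      want <- want[want$adjusted_p <= 0.05, , drop = FALSE]
      expect_setequal(got$pairs, want$pairs)
      if (nrow(got)) {
        m <- match(got$pairs, want$pairs)
        expect_equal(got$fisher_p, want$p[m], tolerance = 1e-9)
        expect_equal(got$adjusted_p, want$adjusted_p[m], tolerance = 1e-9)
        expect_identical(got$direction, want$direction[m])
      }
    }
  }
})

test_that("mine validates its inputs", {
  codes <- matrix(1L, 4, 1, dimnames = list(NULL, "f"))
  b <- toy_binned(codes)
  expect_error(mine(b, toy_labels(rownames(b$codes), 4, 0)), "control")
  expect_error(mine(b, toy_labels(rownames(b$codes), 2, 2), max_layer = 5),
               "max_layer")
})
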