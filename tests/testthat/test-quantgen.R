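sim_geno_matrix <- function(n, m, seed, maf = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  g <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
              dimnames = list(sprintf("a%04d", seq_len(n)),
                              sprintf("s%04d", seq_len(m))))
  genotype_matrix(g)
}

test_that("the GRM matches the VanRaden formula on hand examples", {
  g <- matrix(c(0L, 2L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  G <- compute_grm(genotype_matrix(g))$G
  expect_equal(G["a", "b"], (0 - 1) * (2 - 1) / (2 * 0.25), tolerance = 1e-12)

  # identical animals: off-diagonal equals both diagonals
  g2 <- rbind(a = c(0L, 1L, 2L, 1L), b = c(0L, 1L, 2L, 1L),
              c = c(2L, 0L, 0L, 1L))
  colnames(g2) <- paste0("s", 1:4)
  G2 <- compute_grm(genotype_matrix(g2))$G
  expect_equal(G2["a", "b"], G2["a", "a"], tolerance = 1e-12)
  expect_equal(G2, t(G2))
})

test_that("the GRM diagonal averages 1 under HWE", {
  gm <- sim_geno_matrix(500, 5000, seed = 71)
  G <- compute_grm(gm)$G
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("REML recovers boundary traits and flags unidentifiable models", {
  gm <- sim_geno_matrix(200, 800, seed = 73)
  grm <- compute_grm(gm)
  # trait = pure genetic value (scaled genotype sum)
  set.seed(74)
  b <- rnorm(800)
  y <- as.vector(scale(gm$geno %*% b))
  names(y) <- rownames(gm$geno)
  est <- greml(y, grm)
  expect_gte(est$h2, 0.95)
  expect_true(est$converged)

  # identity GRM: unidentifiable, must flag rather than invent an h2
  id <- structure(list(G = diag(200), ids = rownames(gm$geno), m = 1),
                  class = "grm")
  est0 <- greml(y, id)
  expect_false(est0$converged)
  expect_true(is.na(est0$h2))
})

test_that("REML h2 is invariant to affine rescaling of the trait", {
  gm <- sim_geno_matrix(150, 400, seed = 75)
  grm <- compute_grm(gm)
  set.seed(76)
  g <- as.vector(scale(gm$geno %*% rnorm(400)))
  y <- sqrt(0.5) * g + sqrt(0.5) * rnorm(150)
  names(y) <- rownames(gm$geno)
  e1 <- greml(y, grm)
  e2 <- greml(100 * y - 7, grm)
  expect_equal(e1$h2, e2$h2, tolerance = 1e-5)
  expect_equal(e2$sigma2_g / e1$sigma2_g, 1e4, tolerance = 1e-3)
})

test_that("the heritability screen keeps taxa at or above the threshold", {
  gm <- sim_geno_matrix(300, 500, seed = 77)
  grm <- compute_grm(gm)
  set.seed(78)
  # three synthetic "taxa" traits packed into an abundance-like table
  g <- as.vector(scale(gm$geno %*% rnorm(500)))
  mk <- function(h2) exp(sqrt(h2) * g + sqrt(1 - h2) * rnorm(300) - 4)
  ab <- cbind(t1 = mk(0), t2 = mk(0.6), t3 = mk(0.8))
  ab <- pmin(ab, 1)
  rownames(ab) <- rownames(gm$geno)
  tab <- abundance_table(ab)
  scr <- heritable_taxa_screen(tab, grm, h2_threshold = 0.15)
  expect_identical(scr$taxon, c("t1", "t2", "t3"))
  expect_false(scr$kept[1])
  expect_true(scr$kept[3])
  # threshold 0 keeps every converged taxon
  scr0 <- heritable_taxa_screen(tab, grm, h2_threshold = 0)
  expect_true(all(scr0$kept[scr0$converged]))
  # boundary-inclusive keep rule
  scr_b <- scr
  expect_true(all(scr$kept == (scr$h2 >= 0.15 & scr$converged)))
})

test_that("phenotypic correlations behave on complements and independence", {
  set.seed(79)
  x <- runif(200, 0.2, 0.8)
  tab <- abundance_table(cbind(t1 = x, t2 = 1 - x))
  rownames(tab$ab) <- sprintf("s%03d", 1:200)
  r <- phenotypic_correlation(tab)
  expect_equal(r["t1", "t2"], -1, tolerance = 1e-12)
  expect_equal(diag(r), c(t1 = 1, t2 = 1))

  m <- matrix(runif(1000 * 12, 0, 0.1), 1000, 12,
              dimnames = list(sprintf("s%04d", 1:1000), paste0("t", 1:12)))
  r2 <- phenotypic_correlation(abundance_table(m))
  off <- abs(r2[upper.tri(r2)])
  expect_gte(mean(off <= 0.1), 0.95)
})

test_that("single-SNP association equals the OLS oracle exactly", {
  gm <- sim_geno_matrix(20, 3, seed = 81)
  set.seed(82)
  covs <- data.frame(animal_id = rownames(gm$geno), age = rnorm(20),
                     breed = factor(sample(c("H", "N"), 20, TRUE)))
  y <- rnorm(20) + gm$geno[, 2] * 0.5
  names(y) <- rownames(gm$geno)
  gw <- gwas_linear(y, gm, covs)
  for (j in 1:3) {
    fit <- lm(y ~ gm$geno[, j] + covs$age + covs$breed)
    sm <- summary(fit)$coefficients[2, ]
    expect_equal(gw$beta[j], unname(sm[1]), tolerance = 1e-10)
    expect_equal(gw$se[j], unname(sm[2]), tolerance = 1e-10)
    expect_equal(gw$p[j], unname(sm[4]), tolerance = 1e-10)
  }
})

test_that("a marginally-confounded SNP is cleared by covariate adjustment", {
  hits <- 0
  for (s in 1:10) {
    set.seed(500 + s)
    n <- 400
    u <- rnorm(n)                       # confounder (e.g. farm effect proxy)
    g <- rbinom(n, 2, plogis(-0.5 + u)) # SNP correlated with the confounder
    y <- u + rnorm(n)                   # trait driven by the confounder only
    gm <- genotype_matrix(matrix(as.integer(g), n, 1,
                                 dimnames = list(sprintf("a%04d", 1:n), "s1")))
    names(y) <- rownames(gm$geno)
    covs <- data.frame(animal_id = names(y), u = u)
    p_adj <- gwas_linear(y, gm, covs)$p
    if (p_adj > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("null GWAS p-values are uniform", {
  gm <- sim_geno_matrix(500, 1000, seed = 83)
  set.seed(84)
  y <- rnorm(500)
  names(y) <- rownames(gm$geno)
  gw <- gwas_linear(y, gm)
  expect_gte(mean(gw$p < 0.05), 0.03)
  expect_lte(mean(gw$p < 0.05), 0.07)
  expect_gt(ks.test(gw$p, "punif")$p.value, 0.01)
})
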