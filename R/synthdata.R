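#' Simulation configuration for a synthetic cattle cohort
#'
#' Bundles every knob of the synthetic-data generator: cohort and marker panel
#' size, allele-frequency range, which taxa are heritable and how strongly,
#' zero inflation, covariate structure, planted phenotype effects and noise.
#' Defaults emulate a multi-country dairy-cow cohort profiled at the order
#' level: ~150 taxa, a few thousand SNPs in Hardy-Weinberg equilibrium, four
#' countries, ten farms, two breeds.
#'
#' @param n_animals number of animals in the cohort.
#' @param n_snps number of biallelic SNPs on the simulated array.
#' @param n_taxa number of taxa in the abundance table.
#' @param maf_range length-2 numeric in (0, 0.5]; per-SNP allele frequencies
#'   are drawn uniformly from this interval.
#' @param heritable_taxa data.frame with columns `taxon` (1-based index) and
#'   `h2` (target narrow-sense heritability in \[0, 1)); taxa not listed get
#'   h2 = 0.
#' @param causal_fraction fraction of SNPs carrying a nonzero effect in each
#'   heritable taxon's polygenic score.
#' @param zero_inflation either a single probability applied to every taxon or
#'   a length `n_taxa` vector of structural-zero probabilities in \[0, 1).
#' @param n_countries,n_farms,n_breeds level counts for the categorical
#'   covariates.
#' @param phenotype_effects data.frame with columns `taxon` and `beta` giving
#'   planted taxon effects on the phenotype, in residual-sd units of the
#'   taxon's latent scale.
#' @param covariate_effects named numeric vector of effects for continuous
#'   covariates and/or per-level effects for categoricals (see
#'   [simulate_phenotype()]).
#' @param noise_sd residual standard deviation of the phenotype.
#' @param planted_shift optional list(taxon=, delta=) shifting that taxon's
#'   latent mean by `delta` latent-sd units in case-designated animals (see
#'   [simulate_cohort()]); creates a known ground-truth feature:bin enrichment
#'   for engine power tests.
#' @param taxon_base_sd sd of the fixed per-taxon baseline log-abundance;
#'   controls how uneven the composition is across taxa.
#' @param seed integer seed controlling all randomness of the generator.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_animals = 1000, n_snps = 2000, n_taxa = 150,
                       maf_range = c(0.05, 0.5),
                       heritable_taxa = NULL,
                       causal_fraction = 0.1,
                       zero_inflation = 0.2,
                       n_countries = 4, n_farms = 10, n_breeds = 2,
                       phenotype_effects = NULL,
                       covariate_effects = NULL,
                       noise_sd = 1,
                       planted_shift = NULL,
                       taxon_base_sd = 1.5,
                       seed = 1L) {
  stopifnot(n_animals >= 1, n_snps >= 1, n_taxa >= 1)
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be (lo, hi) with 0 < lo <= hi <= 0.5")
  if (is.null(heritable_taxa))
    heritable_taxa <- data.frame(taxon = integer(0), h2 = numeric(0))
  stopifnot(all(c("taxon", "h2") %in% names(heritable_taxa)))
  if (anyDuplicated(heritable_taxa$taxon))
    stop("heritable taxon indices must be unique")
  if (any(heritable_taxa$taxon < 1 | heritable_taxa$taxon > n_taxa))
    stop("heritable taxon index out of range")
  if (any(heritable_taxa$h2 < 0 | heritable_taxa$h2 >= 1))
    stop("target h2 must lie in [0, 1)")
  zi <- rep_len(zero_inflation, n_taxa)
  if (any(zi < 0 | zi >= 1))
    stop("zero_inflation must lie in [0, 1): a taxon with rate 1 would be all-zero")
  if (is.null(phenotype_effects))
    phenotype_effects <- data.frame(taxon = integer(0), beta = numeric(0))
  stopifnot(noise_sd > 0, causal_fraction > 0, causal_fraction <= 1)
  structure(list(
    n_animals = as.integer(n_animals), n_snps = as.integer(n_snps),
    n_taxa = as.integer(n_taxa), maf_range = maf_range,
    heritable_taxa = heritable_taxa, causal_fraction = causal_fraction,
    zero_inflation = zi, n_countries = n_countries, n_farms = n_farms,
    n_breeds = n_breeds, phenotype_effects = phenotype_effects,
    covariate_effects = covariate_effects, noise_sd = noise_sd,
    planted_shift = planted_shift, taxon_base_sd = taxon_base_sd,
    seed = as.integer(seed)), class = "sim_config")
}

animal_ids <- function(n) sprintf("cow%04d", seq_len(n))

#' Simulate array genotypes in Hardy-Weinberg equilibrium
#'
#' Each SNP gets an allele frequency p drawn uniformly from
#' `config$maf_range`; each animal's genotype is Binomial(2, p), i.e. HWE.
#' SNPs are laid out on a single pseudo-chromosome at 1 kb spacing (positions
#' matter only for LD-thinning order downstream).
#'
#' @param config a [sim_config()].
#' @return a `genotype_matrix`: list with `geno` (animals x SNPs integer
#'   matrix of alt-allele dosages 0/1/2), `snp_info` (id, chr, pos, ref, alt),
#'   `counted_allele = "alt"`, and `freq` (the true simulated frequencies).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_animals; m <- config$n_snps
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  geno <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  rownames(geno) <- animal_ids(n)
  ids <- sprintf("snp%05d", seq_len(m))
  colnames(geno) <- ids
  genotype_matrix(geno,
    snp_info = data.frame(id = ids, chr = "1", pos = seq_len(m) * 1000L,
                          ref = "A", alt = "B"),
    counted_allele = "alt", freq = p)
}

#' Construct a genotype_matrix container
#'
#' @param geno integer matrix, animals in rows, SNPs in columns, values in
#'   \{0,1,2,NA\}.
#' @param snp_info data.frame with columns id, chr, pos, ref, alt.
#' @param counted_allele which allele the dosage counts ("alt" for VCF ALT /
#'   PLINK A1).
#' @param freq optional true allele frequencies (simulation only).
#' @export
genotype_matrix <- function(geno, snp_info = NULL, counted_allele = "alt",
                            freq = NULL) {
  if (is.null(snp_info))
    snp_info <- data.frame(id = colnames(geno), chr = "1",
                           pos = seq_len(ncol(geno)), ref = "A", alt = "B")
  stopifnot(nrow(snp_info) == ncol(geno), !anyDuplicated(snp_info$id),
            all(snp_info$pos >= 0))
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  structure(list(geno = geno, snp_info = snp_info,
                 counted_allele = counted_allele, freq = freq),
            class = "genotype_matrix")
}

#' Simulate taxon relative abundances with host-genetic control
#'
#' Heritable taxa get a latent value `sqrt(h2) * g + sqrt(1 - h2) * e` where g
#' is the standardized additive polygenic score over a random causal SNP
#' subset and e is standard-normal environment; non-heritable taxa are pure
#' environment. The latent value plus a fixed per-taxon baseline passes
#' through an exponential link (right-skewed, strictly positive, resembling
#' 16S relative abundances); structural zeros are inserted with the configured
#' per-taxon probability before each sample is closed to sum 1.
#'
#' @param genotypes a `genotype_matrix` (from [simulate_genotypes()]).
#' @param config a [sim_config()].
#' @param latent_shift optional numeric vector (n_animals x 1) added to one
#'   taxon's latent values, or NULL; used internally by [simulate_cohort()]
#'   for planted-signal cohorts (list(taxon=, shift=vector)).
#' @return list with `abundance` (an `abundance_table`) and `truth` (per-taxon
#'   latent values, genetic values, realized h2 = Var(genetic)/Var(latent),
#'   causal effects).
#' @export
simulate_taxa <- function(genotypes, config, latent_shift = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_matrix"))
  set.seed(config$seed + 1L)
  G <- genotypes$geno
  n <- nrow(G); K <- config$n_taxa
  h2 <- numeric(K)
  h2[config$heritable_taxa$taxon] <- config$heritable_taxa$h2
  latent <- matrix(stats::rnorm(n * K), n, K,
                   dimnames = list(rownames(G), sprintf("taxon%03d", seq_len(K))))
  genval <- matrix(0, n, K)
  effects <- vector("list", K)
  n_causal <- max(1L, round(config$causal_fraction * ncol(G)))
  for (k in which(h2 > 0)) {
    causal <- sample.int(ncol(G), n_causal)
    beta <- stats::rnorm(n_causal)
    g <- as.vector(G[, causal, drop = FALSE] %*% beta)
    sg <- stats::sd(g)
    if (sg < 1e-12) stop("degenerate polygenic score (monomorphic causal set)")
    g <- (g - mean(g)) / sg
    genval[, k] <- sqrt(h2[k]) * g
    latent[, k] <- genval[, k] + sqrt(1 - h2[k]) * latent[, k]
    effects[[k]] <- data.frame(snp = colnames(G)[causal], beta = beta)
  }
  if (!is.null(latent_shift))
    latent[, latent_shift$taxon] <- latent[, latent_shift$taxon] + latent_shift$shift
  realized_h2 <- vapply(seq_len(K), function(k)
    if (h2[k] > 0) stats::var(genval[, k]) / stats::var(latent[, k]) else 0,
    numeric(1))
  base <- stats::rnorm(K, 0, config$taxon_base_sd)
  raw <- exp(sweep(latent, 2, base, `+`))
  zero <- matrix(stats::runif(n * K) < rep(config$zero_inflation, each = n), n, K)
  raw[zero] <- 0
  rs <- rowSums(raw)
  if (any(rs == 0)) stop("a sample lost all taxa to zero inflation; lower the rate")
  ab <- raw / rs
  dimnames(ab) <- list(rownames(G), sprintf("taxon%03d", seq_len(K)))
  list(abundance = abundance_table(ab, level = "order"),
       truth = list(target_h2 = h2, realized_h2 = realized_h2,
                    latent = latent, genetic = genval, effects = effects,
                    base = base))
}

#' Construct an abundance_table container
#'
#' @param ab numeric matrix, samples x taxa, relative abundances in \[0,1\].
#' @param level taxonomic level tag.
#' @export
abundance_table <- function(ab, level = "order") {
  stopifnot(is.matrix(ab), all(ab >= 0), all(ab <= 1 + 1e-9))
  if (anyDuplicated(rownames(ab))) stop("duplicate sample IDs")
  structure(list(ab = ab, level = level), class = "abundance_table")
}

#' Simulate covariates for a synthetic cohort
#'
#' Categorical country/farm/breed (farms nested arbitrarily), Gaussian age,
#' Poisson parity, and Gaussian intake variables (dry-matter, starch, NDF,
#' crude-protein) loosely correlated through a shared intake factor.
#'
#' @param config a [sim_config()].
#' @return data.frame keyed by `animal_id`.
#' @export
simulate_covariates <- function(config) {
  set.seed(config$seed + 2L)
  n <- config$n_animals
  intake <- stats::rnorm(n)                           # shared appetite factor
  data.frame(
    animal_id = animal_ids(n),
    country = factor(sample(paste0("C", seq_len(config$n_countries)), n, TRUE)),
    farm = factor(sample(paste0("F", seq_len(config$n_farms)), n, TRUE)),
    breed = factor(sample(paste0("B", seq_len(config$n_breeds)), n, TRUE)),
    age = stats::rnorm(n, 4, 1.5),
    parity = stats::rpois(n, 2),
    dm_intake = 20 + 2 * intake + stats::rnorm(n, 0, 1),
    starch_intake = 4 + 0.8 * intake + stats::rnorm(n, 0, 0.5),
    ndf_intake = 7 + 1.1 * intake + stats::rnorm(n, 0, 0.7),
    cp_intake = 3 + 0.5 * intake + stats::rnorm(n, 0, 0.4),
    stringsAsFactors = FALSE)
}

#' Simulate a phenotype from taxa, covariates and noise
#'
#' phenotype = sum of planted taxon effects (on the latent scale recorded in
#' `truth`) + covariate effects + Gaussian noise. Covariate effects are a
#' named vector: names matching continuous covariates multiply the covariate;
#' names of the form "farm" (a categorical) draw one effect per level from
#' N(0, beta^2) so the factor explains variance without hand-listing levels.
#'
#' @param taxa result of [simulate_taxa()] (the latent values are used so the
#'   planted effect size is in latent-sd units).
#' @param covariates data.frame from [simulate_covariates()].
#' @param config a [sim_config()].
#' @return data.frame animal_id, trait (named "methane"), plus a `truth`
#'   attribute recording the planted effects.
#' @export
simulate_phenotype <- function(taxa, covariates, config) {
  set.seed(config$seed + 3L)
  ids <- rownames(taxa$truth$latent)
  if (is.null(ids)) ids <- animal_ids(nrow(taxa$truth$latent))
  if (!identical(sort(ids), sort(covariates$animal_id))) {
    d <- union(setdiff(ids, covariates$animal_id),
               setdiff(covariates$animal_id, ids))
    stop("animal IDs differ between taxa and covariates: ",
         paste(utils::head(d, 5), collapse = ", "))
  }
  covariates <- covariates[match(ids, covariates$animal_id), ]
  n <- length(ids)
  y <- stats::rnorm(n, 0, config$noise_sd)
  pe <- config$phenotype_effects
  for (i in seq_len(nrow(pe)))
    y <- y + pe$beta[i] * scale(taxa$truth$latent[, pe$taxon[i]])[, 1]
  ce <- config$covariate_effects
  lv_effects <- list()
  for (nm in names(ce)) {
    v <- covariates[[nm]]
    if (is.null(v)) stop("unknown covariate in covariate_effects: ", nm)
    if (is.factor(v)) {
      lev_eff <- stats::rnorm(nlevels(v), 0, abs(ce[[nm]]))
      y <- y + lev_eff[as.integer(v)]
      lv_effects[[nm]] <- lev_eff
    } else {
      y <- y + ce[[nm]] * v
    }
  }
  out <- data.frame(animal_id = ids, trait = y)
  attr(out, "truth") <- list(taxon_effects = pe, covariate_effects = ce,
                             level_effects = lv_effects)
  out
}

#' Simulate a full cohort, optionally with a planted case-enriched taxon
#'
#' Runs the three generator stages and, when `config$planted_shift` is set,
#' designates prospective cases/controls from the phenotype's
#' covariate-adjusted residual (the noise component, z-scored) and re-draws
#' the taxa with the planted taxon's latent mean shifted by `delta` in the
#' case-designated animals. Downstream case/control labels derived by the
#' pipeline then carry a known taxon:bin enrichment.
#'
#' @param config a [sim_config()].
#' @param cutoff_sd z cutoff used for the internal case designation (matches
#'   the pipeline default 0.5).
#' @return list: genotypes, covariates, taxa (abundance + truth), phenotype,
#'   and `designation` (true case/control/excluded labels, only meaningful
#'   with a planted shift).
#' @export
simulate_cohort <- function(config, cutoff_sd = 0.5) {
  geno <- simulate_genotypes(config)
  covs <- simulate_covariates(config)
  taxa <- simulate_taxa(geno, config)
  phen <- simulate_phenotype(taxa, covs, config)
  designation <- NULL
  if (!is.null(config$planted_shift)) {
    # the phenotype's non-covariate part defines who will be labelled a case
    resid <- phenotype_noise_residual(phen, covs, config)
    z <- (resid - mean(resid)) / stats::sd(resid)
    designation <- ifelse(z > cutoff_sd, "case",
                          ifelse(z < -cutoff_sd, "control", "excluded"))
    shift <- ifelse(designation == "case", config$planted_shift$delta, 0)
    taxa <- simulate_taxa(geno, config,
                          latent_shift = list(taxon = config$planted_shift$taxon,
                                              shift = shift))
    phen <- simulate_phenotype(taxa, covs, config)
  }
  list(genotypes = geno, covariates = covs, taxa = taxa, phenotype = phen,
       designation = designation)
}

# The part of the simulated phenotype not explained by covariates (noise +
# planted taxon effects), reconstructed from the recorded truth.
phenotype_noise_residual <- function(phen, covariates, config) {
  tr <- attr(phen, "truth")
  y <- phen$trait
  covariates <- covariates[match(phen$animal_id, covariates$animal_id), ]
  for (nm in names(tr$covariate_effects)) {
    v <- covariates[[nm]]
    if (is.factor(v)) y <- y - tr$level_effects[[nm]][as.integer(v)]
    else y <- y - tr$covariate_effects[[nm]] * v
  }
  y
}
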