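#' VanRaden genomic relationship matrix
#'
#' G\[i,j\] = (1/m) * sum_k (x_ik - 2 p_k)(x_jk - 2 p_k) / (2 p_k (1 - p_k)),
#' with p_k the observed counted-allele frequency. Missing genotypes are
#' imputed to the per-SNP mean; monomorphic SNPs carry no information and are
#' skipped with a warning.
#'
#' @param genotypes a `genotype_matrix`.
#' @return list of class `grm`: `G` (symmetric n x n), `ids`, `m` (SNPs used).
#' @export
compute_grm <- function(genotypes) {
  X <- genotypes$geno
  stopifnot(nrow(X) >= 2)
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs")
  if (any(!poly)) warning(sum(!poly), " monomorphic SNP(s) skipped")
  X <- X[, poly, drop = FALSE]; p <- p[poly]
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- 2 * p[j]
  Z <- sweep(X, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), `/`)
  G <- tcrossprod(Z) / ncol(Z)
  G <- (G + t(G)) / 2
  structure(list(G = G, ids = rownames(X), m = ncol(Z)), class = "grm")
}

#' REML heritability of a quantitative trait with one genomic random effect
#'
#' Fits y = X beta + g + e with g ~ N(0, G sigma2_g), e ~ N(0, I sigma2_e) by
#' restricted maximum likelihood. The model is rotated onto the
#' eigenvectors of G once, after which the REML log-likelihood profiles the
#' total variance and leaves a one-dimensional optimization over
#' h2 = sigma2_g / (sigma2_g + sigma2_e) on \[0, 1) — exact for a single
#' random effect, deterministic, and robust at this scale. The standard error
#' comes from the curvature (observed information) of the profile REML
#' log-likelihood at the optimum.
#'
#' @param trait named numeric vector (names = animal IDs) or data.frame
#'   animal_id/value.
#' @param grm a `grm` object.
#' @param fixed optional data.frame of fixed-effect covariates keyed by
#'   `animal_id` (categoricals one-hot with first level dropped, continuous
#'   standardized); an intercept is always included.
#' @return data.frame of class `h2_estimate`: sigma2_g, sigma2_e, h2, se,
#'   converged, n, plus attribute `fixed_terms`.
#' @export
greml <- function(trait, grm, fixed = NULL) {
  y <- as_trait_vector(trait)
  ids <- intersect(grm$ids, names(y))
  if (length(ids) < 50) stop("need n >= 50 aligned animals")
  y <- y[ids]
  G <- grm$G[match(ids, grm$ids), match(ids, grm$ids)]
  X <- fixed_design(fixed, ids)
  n <- length(y); p <- ncol(X)
  eg <- eigen(G, symmetric = TRUE)
  if (max(eg$values) - min(eg$values) < 1e-8) {
    return(h2_row(NA, NA, NA, NA, FALSE, n,
                  note = "GRM proportional to identity: h2 unidentifiable"))
  }
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  # profile REML deviance in h2; total variance profiled out analytically
  dev <- function(h2) {
    w <- h2 * d + (1 - h2)
    wi <- 1 / w
    XtWX <- crossprod(Xs, Xs * wi)
    XtWy <- crossprod(Xs, ys * wi)
    ch <- chol(XtWX)
    beta <- backsolve(ch, backsolve(ch, XtWy, transpose = TRUE))
    r <- ys - Xs %*% beta
    s2 <- sum(r^2 * wi) / (n - p)
    (n - p) * log(s2) + sum(log(w)) + 2 * sum(log(diag(ch)))
  }
  opt <- stats::optimize(dev, interval = c(0, 1 - 1e-6), tol = 1e-8)
  h2 <- opt$minimum
  # boundary polish: optimize() cannot land exactly on 0
  if (dev(0) <= opt$objective + 1e-10) h2 <- 0
  w <- h2 * d + (1 - h2)
  wi <- 1 / w
  XtWX <- crossprod(Xs, Xs * wi)
  beta <- solve(XtWX, crossprod(Xs, ys * wi))
  r <- ys - Xs %*% beta
  s2 <- sum(r^2 * wi) / (n - p)
  # observed information of the profile deviance (dev = -2 logLik)
  eps <- 1e-3
  h0 <- min(max(h2, eps), 1 - 1e-4 - eps)
  info <- (dev(h0 + eps) - 2 * dev(h0) + dev(h0 - eps)) / eps^2 / 2
  se <- if (is.finite(info) && info > 0) sqrt(1 / info) else NA_real_
  h2_row(h2 * s2, (1 - h2) * s2, h2, se, TRUE, n)
}

h2_row <- function(s2g, s2e, h2, se, converged, n, note = "") {
  structure(data.frame(sigma2_g = s2g, sigma2_e = s2e, h2 = h2, se = se,
                       converged = converged, n = n, note = note,
                       stringsAsFactors = FALSE),
            class = c("h2_estimate", "data.frame"))
}

as_trait_vector <- function(trait) {
  if (is.data.frame(trait)) {
    v <- trait[[setdiff(names(trait), "animal_id")[1]]]
    names(v) <- trait$animal_id
    v
  } else {
    stopifnot(!is.null(names(trait)))
    trait
  }
}

fixed_design <- function(fixed, ids) {
  if (is.null(fixed)) return(matrix(1, length(ids), 1,
                                    dimnames = list(ids, "(Intercept)")))
  fixed <- fixed[match(ids, fixed$animal_id), , drop = FALSE]
  vars <- setdiff(names(fixed), "animal_id")
  for (v in vars) if (!is.factor(fixed[[v]]) && !is.numeric(fixed[[v]]))
    fixed[[v]] <- factor(fixed[[v]])
  for (v in vars) if (is.numeric(fixed[[v]]) && stats::sd(fixed[[v]]) > 0)
    fixed[[v]] <- as.numeric(scale(fixed[[v]]))
  X <- stats::model.matrix(stats::reformulate(vars, intercept = TRUE),
                           data = fixed)
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  rownames(X) <- ids
  X
}

#' Heritability screen over a panel of taxa
#'
#' Runs [greml()] on each taxon's abundance (log-transformed with a
#' pseudocount of half the smallest nonzero value, since relative abundances
#' are right-skewed on the observed scale) and flags taxa whose estimated h2
#' meets the threshold. One taxon's failure is caught and reported, never
#' fatal for the screen.
#'
#' @param taxa an `abundance_table` (already core-filtered).
#' @param grm a `grm`.
#' @param fixed optional fixed-effect data.frame.
#' @param h2_threshold keep threshold, boundary-inclusive (the study used
#'   h2 >= 0.15).
#' @param transform trait scale for the abundance: "log" (default;
#'   pseudocount of half the smallest nonzero value), "int" (rank-based
#'   inverse-normal, robust to outliers and spikes), or "none" (raw
#'   abundance, the scale the reference GREML tooling is usually fed).
#'   Structural zeros are non-genetic, so every observed-scale estimate is
#'   attenuated relative to the latent heritability when zeros are common;
#'   "log" is most sensitive to that (the pseudocount spike dominates the
#'   variance), "none" least.
#' @return data.frame: taxon, sigma2_g, sigma2_e, h2, se, converged, kept.
#' @export
heritable_taxa_screen <- function(taxa, grm, fixed = NULL,
                                  h2_threshold = 0.15,
                                  transform = c("log", "int", "none")) {
  transform <- match.arg(transform)
  ab <- taxa$ab
  out <- lapply(colnames(ab), function(tn) {
    x <- ab[, tn]
    if (transform == "log") {
      nz <- x[x > 0]
      eps <- if (length(nz)) min(nz) / 2 else 1
      x <- log(x + eps)
    } else if (transform == "int") {
      x <- stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
    }
    names(x) <- rownames(ab)
    est <- tryCatch(greml(x, grm, fixed), error = function(e)
      h2_row(NA, NA, NA, NA, FALSE, length(x), note = conditionMessage(e)))
    cbind(taxon = tn, est)
  })
  res <- do.call(rbind, out)
  res$kept <- !is.na(res$h2) & res$converged & res$h2 >= h2_threshold
  res
}

#' Pairwise phenotypic correlations of taxon abundances
#'
#' @param taxa an `abundance_table` (typically the heritable subset).
#' @return symmetric Pearson correlation matrix, diagonal 1; pairs involving
#'   a constant taxon are NA.
#' @export
phenotypic_correlation <- function(taxa) {
  ab <- taxa$ab
  stopifnot(ncol(ab) >= 2)
  sds <- apply(ab, 2, stats::sd)
  r <- suppressWarnings(stats::cor(ab))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  diag(r) <- ifelse(sds == 0, NA, 1)
  r
}

#' Single-SNP linear association scan
#'
#' Per SNP, OLS of the trait on the additive genotype code plus fixed
#' covariates, with a t test on the genotype coefficient. Implemented by
#' projecting the covariates out of both trait and genotypes
#' (Frisch-Waugh-Lovell), which reproduces the full-model t test exactly and
#' scans thousands of SNPs in one pass. Monomorphic SNPs get NA.
#'
#' @param trait named numeric vector or animal_id/value data.frame.
#' @param genotypes a `genotype_matrix` (QC'd).
#' @param fixed optional covariate data.frame keyed by animal_id.
#' @return data.frame: snp, chr, pos, beta, se, t, p, n.
#' @export
gwas_linear <- function(trait, genotypes, fixed = NULL) {
  y <- as_trait_vector(trait)
  ids <- intersect(rownames(genotypes$geno), names(y))
  y <- y[ids]
  G <- genotypes$geno[ids, , drop = FALSE]
  mu <- colMeans(G, na.rm = TRUE)
  for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- mu[j]
  X <- fixed_design(fixed, ids)
  qx <- qr(X)
  ry <- qr.resid(qx, y)
  RG <- qr.resid(qx, G)
  df <- length(y) - ncol(X) - 1
  gss <- colSums(RG^2)
  beta <- colSums(RG * ry) / gss
  rss <- sum(ry^2) - beta^2 * gss
  se <- sqrt(rss / df / gss)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  mono <- apply(G, 2, function(g) stats::sd(g) == 0)
  beta[mono] <- NA; se[mono] <- NA; tstat[mono] <- NA; p[mono] <- NA
  data.frame(snp = genotypes$snp_info$id, chr = genotypes$snp_info$chr,
             pos = genotypes$snp_info$pos, beta = beta, se = se, t = tstat,
             p = p, n = length(y), row.names = NULL,
             stringsAsFactors = FALSE)
}
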