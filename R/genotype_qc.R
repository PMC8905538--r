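#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on one SNP's genotype counts: conditional on the
#' observed allele counts, the number of heterozygotes under HWE follows a
#' hypergeometric-type distribution over heterozygote counts of the same
#' parity; the p-value sums the probabilities of all heterozygote counts no
#' more probable than the observed one. Preferred over the chi-square test
#' because small genotype classes near the MAF threshold make the asymptotic
#' test anti-conservative.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (nonnegative, total >= 1).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  stopifnot(n >= 1)
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa          # copies of the rarer allele
  if (n_rare == 0) return(1)                    # monomorphic: one configuration
  # heterozygote counts share the parity of the rare allele count
  het <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # P(n_Aa = h | allele counts) up to a constant: 2^h / (h! * nAA! * naa!)
  log_p <- het * log(2) - lfactorial(het) -
    lfactorial((n_rare - het) / 2) - lfactorial(n - (n_rare + het) / 2)
  p <- exp(log_p - max(log_p))
  p <- p / sum(p)
  obs <- p[match(n_Aa, het)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

#' Remove animals with outlier genetic background by PCA
#'
#' Principal components of the column-standardized genotype matrix (missing
#' values imputed to the per-SNP mean); an animal is flagged when any of its
#' first `n_pcs` scores lies more than `outlier_sd` sample standard
#' deviations from that PC's mean.
#'
#' @param genotypes a `genotype_matrix`.
#' @param n_pcs number of leading components examined (the study used 5).
#' @param outlier_sd flagging threshold in sd units.
#' @return list: `retained` (animal IDs), `flagged`, `scores` (n x n_pcs).
#' @export
pca_outlier_removal <- function(genotypes, n_pcs = 5, outlier_sd = 3) {
  G <- genotypes$geno
  stopifnot(nrow(G) >= n_pcs + 1, ncol(G) >= 2)
  X <- impute_standardize(G)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = n_pcs)
  S <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  Z <- scale(S)
  flag <- apply(abs(Z) > outlier_sd, 1, any)
  if (all(flag)) stop("every animal flagged: degenerate outlier threshold")
  list(retained = rownames(G)[!flag], flagged = rownames(G)[flag], scores = S)
}

impute_standardize <- function(G) {
  mu <- colMeans(G, na.rm = TRUE)
  for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- mu[j]
  sdv <- apply(G, 2, stats::sd)
  sdv[sdv == 0] <- 1
  scale(G, center = mu, scale = sdv)
}

snp_maf <- function(G) {
  p <- colMeans(G, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Filter SNPs on missingness and minor allele frequency
#'
#' Drops SNPs with missingness above the `geno` threshold, then SNPs with MAF
#' (from non-missing calls) below the `maf` threshold. Boundaries are kept:
#' a SNP at exactly MAF = maf or missingness = geno survives.
#'
#' @param genotypes a `genotype_matrix`.
#' @param maf minimum minor allele frequency (default 0.05).
#' @param geno maximum per-SNP missing fraction (default 0.05).
#' @return the filtered `genotype_matrix`; per-SNP stats and drop reasons in
#'   attribute `report`.
#' @export
filter_maf_geno <- function(genotypes, maf = 0.05, geno = 0.05) {
  G <- genotypes$geno
  miss <- colMeans(is.na(G))
  mafs <- snp_maf(G)
  reason <- rep("", ncol(G))
  reason[mafs < maf] <- "maf"
  reason[miss > geno] <- "missingness"    # missingness filter applies first
  keep <- reason == ""
  if (!any(keep)) warning("all SNPs dropped by maf/geno filters")
  rep_df <- data.frame(id = genotypes$snp_info$id, maf = mafs, miss = miss,
                       dropped = reason)
  out <- genotype_matrix(G[, keep, drop = FALSE],
                         genotypes$snp_info[keep, , drop = FALSE],
                         genotypes$counted_allele)
  attr(out, "report") <- rep_df
  out
}

#' Filter SNPs on exact HWE p-value
#'
#' @param genotypes a `genotype_matrix`.
#' @param hwe minimum exact-test p-value (default 0.001); SNPs with p below
#'   the threshold are dropped, p = hwe exactly is kept.
#' @export
filter_hwe <- function(genotypes, hwe = 0.001) {
  G <- genotypes$geno
  p <- apply(G, 2, function(g) {
    g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  keep <- p >= hwe
  out <- genotype_matrix(G[, keep, drop = FALSE],
                         genotypes$snp_info[keep, , drop = FALSE],
                         genotypes$counted_allele)
  attr(out, "hwe_p") <- p
  out
}

#' LD-thin SNPs with a sliding window on genotype correlation
#'
#' Within each window of `window_snps` SNPs (advancing by `step`), any pair of
#' retained SNPs with squared genotype correlation above `r2` loses its
#' later-positioned member (a deterministic tie-break). Passes repeat until no
#' within-window pair exceeds the threshold, so the result is stable under
#' re-thinning.
#'
#' @param genotypes a `genotype_matrix` with SNPs sorted by (chr, pos).
#' @param r2 correlation-squared threshold (default 0.8; pairs at exactly the
#'   threshold are kept).
#' @param window_snps,step window geometry in SNP counts.
#' @return the thinned `genotype_matrix`.
#' @export
ld_thin <- function(genotypes, r2 = 0.8, window_snps = 50, step = 5) {
  info <- genotypes$snp_info
  o <- order(info$chr, info$pos)
  if (!identical(o, seq_len(nrow(info))))
    stop("SNPs must be sorted by (chromosome, position)")
  G <- genotypes$geno
  mu <- colMeans(G, na.rm = TRUE)
  for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- mu[j]
  keep <- rep(TRUE, ncol(G))
  repeat {
    removed <- FALSE
    for (chr in unique(info$chr)) {
      idx <- which(info$chr == chr & keep)
      if (length(idx) < 2) next
      starts <- seq(1, length(idx), by = step)
      for (s in starts) {
        w <- idx[s:min(s + window_snps - 1, length(idx))]
        w <- w[keep[w]]
        if (length(w) < 2) next
        cc <- suppressWarnings(stats::cor(G[, w, drop = FALSE]))^2
        cc[is.na(cc)] <- 0
        for (a in seq_len(length(w) - 1)) {
          if (!keep[w[a]]) next
          hits <- which(cc[a, ] > r2)
          hits <- hits[hits > a & keep[w[hits]]]
          if (length(hits)) {
            keep[w[hits]] <- FALSE           # drop the later-positioned SNP
            removed <- TRUE
          }
        }
      }
    }
    if (!removed) break
  }
  genotype_matrix(genotypes$geno[, keep, drop = FALSE],
                  info[keep, , drop = FALSE], genotypes$counted_allele)
}

#' Full genotype QC chain
#'
#' PCA outlier removal, then missingness/MAF, exact HWE, and windowed LD
#' thinning, in that order. Per-SNP MAF is computed after outlier animals are
#' removed, so the order matters and is recorded in the returned report.
#'
#' @param genotypes a `genotype_matrix`.
#' @param maf,geno,hwe,r2,window_snps,step,n_pcs,outlier_sd thresholds; see
#'   the individual filters.
#' @return list: `genotypes` (QC'd matrix), `animals_removed`, `report`.
#' @export
qc_genotypes <- function(genotypes, maf = 0.05, geno = 0.05, hwe = 0.001,
                         r2 = 0.8, window_snps = 50, step = 5,
                         n_pcs = 5, outlier_sd = 3) {
  pca <- pca_outlier_removal(genotypes, n_pcs, outlier_sd)
  g <- genotype_matrix(
    genotypes$geno[pca$retained, , drop = FALSE], genotypes$snp_info,
    genotypes$counted_allele)
  g1 <- filter_maf_geno(g, maf, geno)
  g2 <- filter_hwe(g1, hwe)
  g3 <- ld_thin(g2, r2, window_snps, step)
  list(genotypes = g3, animals_removed = pca$flagged,
       report = list(maf_geno = attr(g1, "report"), hwe_p = attr(g2, "hwe_p"),
                     order = c("pca", "missingness", "maf", "hwe", "ld")))
}
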