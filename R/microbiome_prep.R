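#' Core-taxon prevalence filter
#'
#' Keeps a taxon only if it is nonzero in at least `prevalence` of samples AND
#' in at least `min_samples` samples — both clauses bind independently, so a
#' high absolute floor can discard a taxon that clears the percentage on a
#' small cohort.
#'
#' @param table an `abundance_table`.
#' @param prevalence required nonzero fraction (the study screens at 0.7 or
#'   0.9), in (0, 1].
#' @param min_samples required absolute nonzero sample count (the study used
#'   600 animals).
#' @return the filtered `abundance_table` with attributes `kept` and
#'   `discarded` (taxon name vectors).
#' @export
core_taxa_filter <- function(table, prevalence = 0.7, min_samples = 600) {
  stopifnot(inherits(table, "abundance_table"),
            prevalence > 0, prevalence <= 1, min_samples >= 0)
  nz <- colSums(table$ab > 0)
  n <- nrow(table$ab)
  keep <- nz >= prevalence * n & nz >= min_samples
  if (!any(keep)) warning("no taxon passes the core filter")
  out <- abundance_table(table$ab[, keep, drop = FALSE], level = table$level)
  attr(out, "kept") <- colnames(table$ab)[keep]
  attr(out, "discarded") <- colnames(table$ab)[!keep]
  out
}

#' Bin relative abundances into ordinal deciles
#'
#' Per taxon, equal-width intervals over the observed range, following base
#' R's `cut(x, breaks = n)` convention: the range is extended by 0.1% of its
#' width at both ends, intervals are left-open/right-closed, and codes run 1
#' (lowest) to `n_bins` (highest), so the minimum always lands in bin 1 and
#' the maximum in bin `n_bins`. A constant taxon cannot form distinct
#' intervals and is assigned bin 1 everywhere with a warning. Zeros
#' participate like any other value (they anchor bin 1).
#'
#' @param table an `abundance_table`.
#' @param n_bins number of bins (>= 2; the study used 10).
#' @param method "width" for equal-width (the default, matching `cut`), or
#'   "frequency" for equal-frequency bins (quantile edges) as a sensitivity
#'   option.
#' @param pooled if TRUE, bin over the pooled value distribution of all taxa
#'   instead of per taxon (sensitivity option).
#' @return a `binned_matrix`: list with `codes` (samples x features integer
#'   matrix, NA for missing), `range` = c(1, n_bins), and `edges` (per-feature
#'   break vectors).
#' @export
bin_abundances <- function(table, n_bins = 10, method = c("width", "frequency"),
                           pooled = FALSE) {
  stopifnot(inherits(table, "abundance_table"), n_bins >= 2)
  method <- match.arg(method)
  ab <- table$ab
  edges_for <- function(x) {
    rx <- range(x, na.rm = TRUE)
    if (method == "width") {
      dx <- diff(rx)
      if (dx == 0) return(NULL)
      seq(rx[1] - dx / 1000, rx[2] + dx / 1000, length.out = n_bins + 1)
    } else {
      br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                   na.rm = TRUE, names = FALSE))
      if (length(br) < 2) return(NULL)
      br[1] <- br[1] - abs(br[1]) / 1000 - 1e-12
      br
    }
  }
  codes <- matrix(NA_integer_, nrow(ab), ncol(ab), dimnames = dimnames(ab))
  edges <- vector("list", ncol(ab)); names(edges) <- colnames(ab)
  pooled_edges <- if (pooled) edges_for(as.vector(ab)) else NULL
  for (j in seq_len(ncol(ab))) {
    e <- if (pooled) pooled_edges else edges_for(ab[, j])
    if (is.null(e)) {
      warning("constant taxon '", colnames(ab)[j], "': all samples in bin 1")
      codes[, j] <- 1L
      next
    }
    codes[, j] <- as.integer(cut(ab[, j], breaks = e, labels = FALSE,
                                 include.lowest = TRUE, right = TRUE))
    edges[[j]] <- e
  }
  binned_matrix(codes, range = c(1L, n_bins), edges = edges)
}

#' Construct a binned_matrix container
#'
#' Samples x features ordinal codes: taxa carry bins 1..n_bins, genotypes
#' carry 0/1/2; NA is the missing code and never matches any feature:bin pair.
#'
#' @param codes integer matrix with sample rownames and feature colnames.
#' @param range c(lo, hi) legal code range.
#' @param edges optional per-feature bin-edge list (provenance).
#' @export
binned_matrix <- function(codes, range = c(1L, 10L), edges = NULL) {
  stopifnot(is.matrix(codes), !is.null(colnames(codes)))
  v <- codes[!is.na(codes)]
  if (length(v) && (min(v) < range[1] || max(v) > range[2]))
    stop("codes outside declared range [", range[1], ", ", range[2], "]")
  structure(list(codes = codes, range = as.integer(range), edges = edges),
            class = "binned_matrix")
}

#' Binned view of a genotype matrix (codes 0/1/2)
#' @param genotypes a `genotype_matrix`.
#' @export
bin_genotypes <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  binned_matrix(genotypes$geno, range = c(0L, 2L))
}

#' Combine binned feature matrices on shared samples
#' @param ... `binned_matrix` objects with identical sample rownames.
#' @export
cbind_binned <- function(...) {
  ms <- list(...)
  ids <- rownames(ms[[1]]$codes)
  for (m in ms) stopifnot(identical(rownames(m$codes), ids))
  binned_matrix(do.call(cbind, lapply(ms, `[[`, "codes")),
                range = range(vapply(ms, `[[`, integer(2), "range")))
}
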