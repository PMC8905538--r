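# Shared fixture builders: everything is generated in code at test time.

# A tiny binned matrix with named samples and features.
toy_binned <- function(codes, range = c(1L, 10L)) {
  rownames(codes) <- sprintf("s%02d", seq_len(nrow(codes)))
  binned_matrix(codes, range = range)
}

# Labels for the first n_case samples as cases, next n_ctrl as controls.
toy_labels <- function(ids, n_case, n_ctrl) {
  lab <- rep("excluded", length(ids))
  lab[seq_len(n_case)] <- "case"
  lab[n_case + seq_len(n_ctrl)] <- "control"
  structure(data.frame(animal_id = ids, residual = 0, z = 0, label = lab,
                       method = "z", cutoff = 0.5, stringsAsFactors = FALSE),
            class = c("case_control", "data.frame"))
}

# Independent brute-force one/two-sided Fisher p via explicit binomial
# coefficients (no calls into the package or into dhyper/phyper).
oracle_fisher <- function(a, b, c, d, alternative) {
  n1 <- a + b; K <- a + c; N <- a + b + c + d
  ks <- max(0, K - (N - n1)):min(K, n1)
  logp <- lchoose(n1, ks) + lchoose(N - n1, K - ks) - lchoose(N, K)
  pr <- exp(logp)
  obs <- pr[match(a, ks)]
  switch(alternative,
         greater = sum(pr[ks >= a]),
         less = sum(pr[ks <= a]),
         two.sided = sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Independent exact HWE p by enumerating every heterozygote count compatible
# with the observed allele counts, with closed-form conditional probabilities.
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logpr <- vapply(hets, function(h) {
    n1 <- (nA - h) / 2; n2 <- n - n1 - h
    lfactorial(n) - lfactorial(n1) - lfactorial(h) - lfactorial(n2) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logpr - max(logpr))
  pr <- pr / sum(pr)                     # guard against float drift
  obs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Exhaustive layer-1 + layer-2 miner used as the oracle for mine(): evaluates
# every feature:bin pair and every two-feature pair combination directly with
# stats::fisher.test, BH-corrects within each layer.
oracle_mine <- function(codes, is_case, alpha = 0.05) {
  feats <- colnames(codes)
  cand1 <- list()
  for (f in feats) for (v in sort(unique(codes[!is.na(codes[, f]), f])))
    cand1[[length(cand1) + 1]] <- list(name = paste0(f, ":", v),
                                       carrier = !is.na(codes[, f]) & codes[, f] == v)
  score <- function(cands) {
    if (!length(cands)) return(data.frame())
    rows <- lapply(cands, function(cn) {
      a <- sum(cn$carrier & is_case); c_ <- sum(cn$carrier & !is_case)
      b <- sum(is_case) - a; d <- sum(!is_case) - c_
      m <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
      pg <- stats::fisher.test(m, alternative = "greater")$p.value
      pl <- stats::fisher.test(m, alternative = "less")$p.value
      data.frame(pairs = cn$name, p = min(pg, pl),
                 direction = if (pg <= pl) "case-enriched" else "control-enriched",
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$adjusted_p <- stats::p.adjust(df$p, "BH")
    df
  }
  l1 <- score(cand1)
  cand2 <- list()
  if (length(cand1) >= 2) {
    feat_of <- sub(":[^:]*$", "", vapply(cand1, `[[`, character(1), "name"))
    for (i in seq_along(cand1)) for (j in seq_along(cand1)) {
      if (j <= i || feat_of[i] == feat_of[j]) next
      nm <- paste(sort(c(cand1[[i]]$name, cand1[[j]]$name)), collapse = ";")
      cand2[[nm]] <- list(name = nm,
                          carrier = cand1[[i]]$carrier & cand1[[j]]$carrier)
    }
  }
  l2 <- score(unname(cand2))
  list(l1 = l1, l2 = l2)
}
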