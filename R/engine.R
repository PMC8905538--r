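#' Samples carrying a feature:bin combination
#'
#' A sample carries a combination when, for every pair, its code equals the
#' pair's bin. Missing codes never match, so missingness shrinks carriage.
#' The empty combination is carried by every sample (empty conjunction).
#'
#' @param binned a `binned_matrix`.
#' @param combination data.frame with columns `feature`, `bin`.
#' @return character vector of sample IDs.
#' @export
carriers <- function(binned, combination) {
  codes <- binned$codes
  unknown <- setdiff(combination$feature, colnames(codes))
  if (length(unknown)) stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(codes))
  for (i in seq_len(nrow(combination))) {
    v <- codes[, combination$feature[i]]
    keep <- keep & !is.na(v) & v == combination$bin[i]
  }
  rownames(codes)[keep]
}

#' Fisher's exact test for a 2x2 carriage table
#'
#' Exact hypergeometric tail probability for the table
#' \[cases: a carrying / b not; controls: c carrying / d not\].
#' `alternative = "greater"` tests case-enrichment of carriage, `"less"`
#' control-enrichment; `"two.sided"` sums all tables with point probability
#' no larger than the observed one.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @param alternative "greater", "less" or "two.sided".
#' @return exact p-value in (0, 1].
#' @export
fisher_exact <- function(a, b, c, d, alternative = c("greater", "less",
                                                     "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  K <- a + c                      # carriers overall
  n1 <- a + b                     # cases
  N <- a + b + c + d
  if (alternative == "greater")
    return(min(1, stats::phyper(a - 1, K, N - K, n1, lower.tail = FALSE)))
  if (alternative == "less")
    return(min(1, stats::phyper(a, K, N - K, n1)))
  x <- max(0, K - (N - n1)):min(K, n1)
  dp <- stats::dhyper(x, K, N - K, n1)
  min(1, sum(dp[dp <= stats::dhyper(a, K, N - K, n1) * (1 + 1e-7)]))
}

#' Two-proportion z test
#'
#' z = (a/n1 - c/n2) / sqrt(p(1-p)(1/n1 + 1/n2)) with the pooled proportion
#' p = (a+c)/(n1+n2); two-sided p from the standard normal. When the pooled
#' proportion is 0 or 1 the statistic is defined as z = 0, p = 1.
#'
#' @param a successes in group 1 of size `n1`; `c` successes in group 2 of
#'   size `n2`.
#' @param n1,n2 group sizes (>= 1).
#' @return list(z, p).
#' @export
two_proportion_z <- function(a, n1, c, n2) {
  stopifnot(n1 >= 1, n2 >= 1, a >= 0, a <= n1, c >= 0, c <= n2)
  pooled <- (a + c) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- ifelse(se == 0, 0, (a / n1 - c / n2) / se)
  list(z = z, p = ifelse(se == 0, 1, 2 * stats::pnorm(-abs(z))))
}

#' Mine statistically validated feature:bin combinations layer by layer
#'
#' Layer 1 evaluates every feature:bin pair against the case/control labels
#' with one-sided Fisher's exact tests in both directions; the better
#' direction is kept per candidate and p-values are corrected across all
#' candidates evaluated in the layer. Each subsequent layer extends
#' combinations by one new feature:bin pair (no feature reused; canonical
#' sorted order so set-equal candidates are evaluated once), re-tests and
#' re-corrects within the layer. Because statistical significance is not
#' anti-monotone in the combination, extension proceeds from the top
#' `beam_width` candidates of the previous layer ranked by adjusted p (all of
#' them when `beam_width = Inf`), while each layer REPORTS only the records
#' whose adjusted p is at or below `alpha`. With the beam disabled the search
#' is exhaustive.
#'
#' @param binned a `binned_matrix` of ordinal codes.
#' @param labels a `case_control` assignment; excluded animals are ignored.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param correction "BH" (default) or "bonferroni", applied per layer.
#' @param max_layer maximum combination size (<= 4).
#' @param beam_width search beam per layer (default 1000; `Inf` disables).
#' @param min_carriers minimum number of labelled animals carrying a
#'   candidate for it to be tested (support floor, default 5).
#' @return a `mined_networks` object: list with `records` (one data.frame per
#'   layer: pairs, layer, a, b, c, d, fisher_p, z, adjusted_p, direction),
#'   `params`, `n_cases`, `n_controls`.
#' @export
mine <- function(binned, labels, alpha = 0.05,
                 correction = c("BH", "bonferroni"), max_layer = 2,
                 beam_width = 1000, min_carriers = 5) {
  correction <- match.arg(correction)
  stopifnot(inherits(binned, "binned_matrix"), max_layer >= 1, max_layer <= 4)
  codes <- binned$codes
  lab <- labels$label[match(rownames(codes), labels$animal_id)]
  use <- !is.na(lab) & lab != "excluded"
  codes <- codes[use, , drop = FALSE]
  lab <- lab[use]
  n_cases <- sum(lab == "case"); n_controls <- sum(lab == "control")
  if (n_cases < 1 || n_controls < 1) stop("need at least 1 case and 1 control")
  if (ncol(codes) < 1) stop("need at least 1 feature")
  is_case <- lab == "case"

  # carrier indicator for every single feature:bin pair observed in the data
  pair_feat <- integer(0); pair_bin <- integer(0)
  for (j in seq_len(ncol(codes))) {
    vals <- sort(unique(codes[!is.na(codes[, j]), j]))
    pair_feat <- c(pair_feat, rep(j, length(vals)))
    pair_bin <- c(pair_bin, vals)
  }
  P <- length(pair_feat)
  pair_lab <- paste0(colnames(codes)[pair_feat], ":", pair_bin)
  pairC <- matrix(0, nrow(codes), P)
  for (i in seq_len(P)) {
    v <- codes[, pair_feat[i]]
    pairC[, i] <- as.numeric(!is.na(v) & v == pair_bin[i])
  }
  pairC_case <- pairC[is_case, , drop = FALSE]
  pairC_ctrl <- pairC[!is_case, , drop = FALSE]

  name_of <- function(ids) {
    vapply(ids, function(v) paste(sort(pair_lab[v]), collapse = ";"),
           character(1))
  }
  score <- function(a, c_) {
    K <- a + c_
    p_gr <- stats::phyper(a - 1, K, n_cases + n_controls - K, n_cases,
                          lower.tail = FALSE)
    p_le <- stats::phyper(a, K, n_cases + n_controls - K, n_cases)
    case_dir <- p_gr <= p_le
    data.frame(a = a, b = n_cases - a, c = c_, d = n_controls - c_,
               fisher_p = pmin(1, ifelse(case_dir, p_gr, p_le)),
               z = two_proportion_z_vec(a, n_cases, c_, n_controls),
               direction = ifelse(case_dir, "case-enriched",
                                  "control-enriched"),
               stringsAsFactors = FALSE)
  }

  records <- vector("list", max_layer)
  # frontier at layer 1: every single pair
  sets <- lapply(seq_len(P), identity)
  a <- colSums(pairC_case); c_ <- colSums(pairC_ctrl)
  keys <- as.character(seq_len(P))

  for (layer in seq_len(max_layer)) {
    ok <- (a + c_) >= min_carriers
    sets <- sets[ok]; a <- a[ok]; c_ <- c_[ok]; keys <- keys[ok]
    if (!length(sets)) {
      for (l in layer:max_layer) records[[l]] <- empty_records()
      break
    }
    df <- score(a, c_)
    df$adjusted_p <- stats::p.adjust(df$fisher_p, method = correction)
    ord <- order(df$adjusted_p, df$fisher_p, keys)
    sig_idx <- ord[df$adjusted_p[ord] <= alpha]
    sig <- df[sig_idx, , drop = FALSE]
    if (nrow(sig)) {
      sig$pairs <- name_of(sets[sig_idx])
      sig$layer <- layer
      # report sorted by adjusted p, ties by the canonical pair string
      sig <- sig[order(sig$adjusted_p, sig$pairs),
                 c("pairs", "a", "b", "c", "d", "fisher_p", "z",
                   "direction", "adjusted_p", "layer")]
      rownames(sig) <- NULL
      records[[layer]] <- sig
    } else records[[layer]] <- empty_records()
    if (layer == max_layer) break

    # ---- extend: parents are the beam (top candidates by adjusted p)
    keep <- ord
    if (is.finite(beam_width) && length(keep) > beam_width)
      keep <- keep[seq_len(beam_width)]
    par_sets <- sets[keep]
    n_par <- length(par_sets)
    parC <- matrix(0, nrow(codes), n_par)
    for (i in seq_len(n_par))
      parC[, i] <- as.numeric(rowSums(pairC[, par_sets[[i]], drop = FALSE]) ==
                                length(par_sets[[i]]))
    A <- crossprod(parC[is_case, , drop = FALSE], pairC_case)
    C <- crossprod(parC[!is_case, , drop = FALSE], pairC_ctrl)
    valid <- matrix(TRUE, n_par, P)
    for (i in seq_len(n_par))
      valid[i, pair_feat %in% pair_feat[par_sets[[i]]]] <- FALSE
    idx <- which(valid, arr.ind = TRUE)
    if (!nrow(idx)) {
      for (l in (layer + 1):max_layer) records[[l]] <- empty_records()
      break
    }
    cand_sets <- mapply(function(i, j) sort(c(par_sets[[i]], j)),
                        idx[, 1], idx[, 2], SIMPLIFY = FALSE)
    cand_keys <- vapply(cand_sets, paste, character(1), collapse = "_")
    dup <- duplicated(cand_keys)
    sets <- cand_sets[!dup]
    keys <- cand_keys[!dup]
    a <- A[idx][!dup]
    c_ <- C[idx][!dup]
  }
  for (l in seq_len(max_layer)) if (is.null(records[[l]]))
    records[[l]] <- empty_records()
  structure(list(records = records, n_cases = n_cases,
                 n_controls = n_controls,
                 params = list(alpha = alpha, correction = correction,
                               max_layer = max_layer, beam_width = beam_width,
                               min_carriers = min_carriers)),
            class = "mined_networks")
}

two_proportion_z_vec <- function(a, n1, c, n2) {
  pooled <- (a + c) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  ifelse(se == 0, 0, (a / n1 - c / n2) / se)
}

empty_records <- function() {
  data.frame(pairs = character(0), a = integer(0), b = integer(0),
             c = integer(0), d = integer(0), fisher_p = numeric(0),
             z = numeric(0), direction = character(0),
             adjusted_p = numeric(0), layer = integer(0),
             stringsAsFactors = FALSE)
}

#' All significant records of a mined network set as one data.frame
#' @param x a `mined_networks` object.
#' @param ... unused.
#' @export
as.data.frame.mined_networks <- function(x, ...) {
  do.call(rbind, x$records)
}

#' Parse a canonical "feature:bin;feature:bin" string into a pair data.frame
#' @param pairs semicolon-joined feature:bin string.
#' @export
parse_pairs <- function(pairs) {
  parts <- strsplit(pairs, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexpr(":[^:]*$", parts))
  data.frame(feature = substr(parts, 1, nchar(parts) - nchar(m)),
             bin = as.integer(sub(":", "", m, fixed = TRUE)),
             stringsAsFactors = FALSE)
}
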