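#' Score a combination as a case/control classifier with Youden's J
#'
#' Predict "case" for every animal that carries the combination; sensitivity
#' = TP/(TP+FN), specificity = TN/(TN+FP), J = sensitivity + specificity - 1.
#' Excluded animals are ignored.
#'
#' @param combination data.frame feature/bin (see [parse_pairs()]).
#' @param binned a `binned_matrix`.
#' @param labels a `case_control` assignment.
#' @return data.frame sensitivity, specificity, J, TP, FN, TN, FP.
#' @export
youden_j <- function(combination, binned, labels) {
  lab <- labels$label[match(rownames(binned$codes), labels$animal_id)]
  is_case <- !is.na(lab) & lab == "case"
  is_ctrl <- !is.na(lab) & lab == "control"
  if (!any(is_case) || !any(is_ctrl)) stop("need >= 1 case and >= 1 control")
  carried <- rownames(binned$codes) %in% carriers(binned, combination)
  TP <- sum(carried & is_case); FN <- sum(!carried & is_case)
  TN <- sum(!carried & is_ctrl); FP <- sum(carried & is_ctrl)
  sens <- TP / (TP + FN); spec <- TN / (TN + FP)
  data.frame(sensitivity = sens, specificity = spec, J = sens + spec - 1,
             TP = TP, FN = FN, TN = TN, FP = FP)
}

#' Bootstrap null distribution of Youden's J for random combinations
#'
#' Draws `n_draws` combinations of `layer` distinct features uniformly at
#' random, each feature paired with a bin drawn uniformly from its observed
#' codes, and scores each with [youden_j()]. The resulting empirical
#' distribution is the reference against which mined combinations are judged.
#'
#' @param binned a `binned_matrix`.
#' @param labels a `case_control` assignment.
#' @param layer combination size.
#' @param n_draws number of random combinations.
#' @param seed RNG seed.
#' @return list: `J` (numeric vector), `quantile(q)` helper, and
#'   `percentile(j)` giving the fraction of null draws at or below `j`.
#' @export
bootstrap_null_j <- function(binned, labels, layer = 1, n_draws = 1000,
                             seed = 1L) {
  codes <- binned$codes
  if (layer > ncol(codes)) stop("layer exceeds the number of features")
  set.seed(seed)
  obs_codes <- lapply(seq_len(ncol(codes)), function(j) {
    v <- unique(codes[, j]); v[!is.na(v)]
  })
  J <- vapply(seq_len(n_draws), function(i) {
    f <- sample.int(ncol(codes), layer)
    b <- vapply(f, function(j) {
      oc <- obs_codes[[j]]
      oc[sample.int(length(oc), 1)]
    }, numeric(1))
    youden_j(data.frame(feature = colnames(codes)[f], bin = b), binned,
             labels)$J
  }, numeric(1))
  list(J = J,
       quantile = function(q) stats::quantile(J, q, names = FALSE, type = 7),
       percentile = function(j) mean(J <= j))
}

#' Compare top mined combinations with top GWAS SNPs on the J scale
#'
#' Engine side: the `k` layer-1 records with smallest adjusted p, each scored
#' with [youden_j()]. GWAS side: the `k` SNPs with smallest p, each converted
#' to its best single-genotype classifier (the genotype value 0/1/2 that
#' maximizes J — a construction needed to place single-SNP associations on
#' the same scale as mined combinations). Reports the best J per side and
#' their difference.
#'
#' @param engine a `mined_networks` object (layer-1 records are used; if none
#'   are significant the layer-1 candidate ranking cannot be recovered, so
#'   supply a mine() run whose alpha admits at least one record or use
#'   `engine_records` directly).
#' @param gwas a data.frame from [gwas_linear()].
#' @param binned a `binned_matrix` holding the genotype codes.
#' @param labels a `case_control` assignment.
#' @param k number of top features per side (truncated with a warning when
#'   fewer are available).
#' @param engine_records optional data.frame overriding the engine side
#'   (columns pairs, adjusted_p).
#' @return list: `engine` and `gwas` per-feature J tables, `best_engine_j`,
#'   `best_gwas_j`, `difference` (engine minus GWAS).
#' @export
compare_top_features <- function(engine, gwas, binned, labels, k = 100,
                                 engine_records = NULL) {
  if (is.null(engine_records)) {
    stopifnot(inherits(engine, "mined_networks"))
    engine_records <- engine$records[[1]]
  }
  if (nrow(gwas) == 0) stop("empty GWAS results")
  if (nrow(engine_records) == 0) stop("no engine layer-1 records to score")
  ke <- min(k, nrow(engine_records))
  kg <- min(k, nrow(gwas))
  if (ke < k || kg < k)
    warning("fewer than k = ", k, " features available; using ", ke, "/", kg)
  er <- engine_records[order(engine_records$adjusted_p,
                             engine_records$pairs), , drop = FALSE][seq_len(ke), ]
  ej <- vapply(er$pairs, function(p)
    youden_j(parse_pairs(p), binned, labels)$J, numeric(1))
  gw <- gwas[order(gwas$p), , drop = FALSE][seq_len(kg), ]
  gj <- vapply(gw$snp, function(s) {
    vals <- unique(binned$codes[, s]); vals <- vals[!is.na(vals)]
    max(vapply(vals, function(v)
      youden_j(data.frame(feature = s, bin = v), binned, labels)$J,
      numeric(1)))
  }, numeric(1))
  list(engine = data.frame(pairs = er$pairs, J = ej, row.names = NULL),
       gwas = data.frame(snp = gw$snp, J = gj, row.names = NULL),
       best_engine_j = max(ej), best_gwas_j = max(gj),
       difference = max(ej) - max(gj))
}
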