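#' Select trait covariates by L1-penalized regression
#'
#' Fits a linear LASSO of the trait on all covariates (categoricals one-hot
#' encoded, design standardized), picks the penalty by k-fold cross-validation
#' with the one-standard-error rule, and returns every original covariate
#' with at least one nonzero coefficient. The selected subset is then refit by
#' OLS and reported with effect p-values (aliased columns dropped with a
#' warning).
#'
#' @param pheno data.frame with columns `animal_id`, `trait`.
#' @param covars data.frame keyed by `animal_id`; all other columns are
#'   candidate covariates (factors or numerics).
#' @param cv_folds number of cross-validation folds.
#' @param seed seed for the fold assignment.
#' @return list: `selected` (character vector of covariate names), `refit`
#'   (data.frame term/estimate/p from the OLS refit), `cvfit` (the cv.glmnet
#'   object).
#' @export
select_covariates <- function(pheno, covars, cv_folds = 10, seed = 1L) {
  d <- merge(pheno, covars, by = "animal_id")
  d <- d[stats::complete.cases(d), ]
  y <- d$trait
  if (stats::sd(y) == 0) stop("constant phenotype: nothing to select for")
  vars <- setdiff(names(covars), "animal_id")
  if (length(vars) < 2) stop("need at least 2 candidate covariates")
  X <- stats::model.matrix(
    stats::reformulate(vars, intercept = TRUE), data = d)[, -1, drop = FALSE]
  set.seed(seed)
  cvfit <- glmnet::cv.glmnet(X, y, family = "gaussian", alpha = 1,
                             nfolds = cv_folds, standardize = TRUE)
  co <- as.matrix(stats::coef(cvfit, s = "lambda.1se"))[-1, 1]
  nz <- names(co)[co != 0]
  # map dummy columns back to the original covariate names
  assign_map <- attr(stats::model.matrix(
    stats::reformulate(vars, intercept = TRUE), data = d), "assign")[-1]
  colvar <- vars[assign_map]
  selected <- unique(colvar[colnames(X) %in% nz])
  refit <- NULL
  if (length(selected) > 0) {
    fit <- stats::lm(stats::reformulate(selected, response = "trait"), data = d)
    if (any(is.na(stats::coef(fit)))) {
      warning("rank-deficient refit: dropping aliased columns")
      fit <- stats::lm(stats::reformulate(selected, response = "trait"),
                       data = d, singular.ok = TRUE)
    }
    sm <- summary(fit)$coefficients
    refit <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        p = sm[, 4], row.names = NULL)
  }
  list(selected = selected, refit = refit, cvfit = cvfit)
}

#' Residualize a trait on selected covariates
#'
#' OLS of the trait on the selected covariates (intercept always included;
#' empty selection gives mean-centering). Animals with missing covariates are
#' dropped with a warning. Residuals have mean zero and are orthogonal to
#' every design column.
#'
#' @param pheno data.frame with `animal_id`, `trait`.
#' @param covars covariate data.frame keyed by `animal_id`.
#' @param selected character vector of covariate names (possibly empty).
#' @return data.frame animal_id, residual.
#' @export
residualize <- function(pheno, covars, selected = character(0)) {
  d <- merge(pheno, covars, by = "animal_id")
  keep <- stats::complete.cases(d[, c("trait", selected), drop = FALSE])
  if (!all(keep)) {
    warning(sum(!keep), " animal(s) dropped for missing covariates")
    d <- d[keep, ]
  }
  if (length(selected) == 0) {
    r <- d$trait - mean(d$trait)
  } else {
    X <- stats::model.matrix(stats::reformulate(selected), data = d)
    if (qr(X)$rank < ncol(X)) stop("singular design after drops")
    r <- stats::lm.fit(X, d$trait)$residuals
  }
  data.frame(animal_id = d$animal_id, residual = as.numeric(r))
}

#' Binarize residuals into cases and controls by z-score
#'
#' z = (residual - mean) / sd (sample sd, n-1). Animals with z strictly above
#' +cutoff are cases, strictly below -cutoff controls, and the middle band
#' (|z| <= cutoff, boundary included) is excluded — the conservative reading
#' of a +/-0.5 sd exclusion band.
#'
#' @param residuals data.frame animal_id, residual (from [residualize()]), or
#'   a named/plain numeric vector.
#' @param cutoff_sd the half-width of the exclusion band in sd units.
#' @return a `case_control` data.frame: animal_id, residual, z, label
#'   (case/control/excluded), method, cutoff.
#' @export
binarize_z <- function(residuals, cutoff_sd = 0.5) {
  d <- as_residual_df(residuals)
  if (nrow(d) < 3) stop("need at least 3 animals")
  s <- stats::sd(d$residual)
  if (s == 0) stop("zero residual variance")
  z <- (d$residual - mean(d$residual)) / s
  label <- ifelse(z > cutoff_sd, "case", ifelse(z < -cutoff_sd, "control",
                                                "excluded"))
  structure(data.frame(animal_id = d$animal_id, residual = d$residual, z = z,
                       label = label, method = "z", cutoff = cutoff_sd,
                       stringsAsFactors = FALSE),
            class = c("case_control", "data.frame"))
}

#' Binarize residuals into cases and controls by percentiles
#'
#' Controls are animals at or below the `lower_q` empirical quantile, cases at
#' or above the `upper_q` quantile (type-7 linear-interpolation quantiles,
#' boundary-inclusive); the rest are excluded. An animal matching both cutoffs
#' (degenerate split) is labelled case.
#'
#' @param residuals as in [binarize_z()].
#' @param lower_q,upper_q quantile cutoffs, 0 < lower_q <= upper_q < 1.
#' @return a `case_control` data.frame (columns as [binarize_z()]; z holds the
#'   residual's empirical quantile rank).
#' @export
binarize_percentile <- function(residuals, lower_q = 0.2, upper_q = 0.8) {
  stopifnot(lower_q > 0, upper_q < 1, lower_q <= upper_q)
  d <- as_residual_df(residuals)
  qs <- stats::quantile(d$residual, c(lower_q, upper_q), type = 7, names = FALSE)
  if (lower_q < upper_q && qs[1] == qs[2])
    stop("ties make the lower and upper quantiles coincide (", qs[1],
         "); cannot split")
  label <- rep("excluded", nrow(d))
  label[d$residual <= qs[1]] <- "control"
  label[d$residual >= qs[2]] <- "case"   # degenerate overlap resolves to case
  ec <- stats::ecdf(d$residual)
  structure(data.frame(animal_id = d$animal_id, residual = d$residual,
                       z = ec(d$residual), label = label,
                       method = "percentile",
                       cutoff = paste0(lower_q, "/", upper_q),
                       stringsAsFactors = FALSE),
            class = c("case_control", "data.frame"))
}

as_residual_df <- function(residuals) {
  if (is.data.frame(residuals)) {
    stopifnot(all(c("animal_id", "residual") %in% names(residuals)))
    residuals
  } else {
    ids <- names(residuals)
    if (is.null(ids)) ids <- sprintf("s%04d", seq_along(residuals))
    data.frame(animal_id = ids, residual = as.numeric(residuals))
  }
}
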