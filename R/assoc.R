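#' Specify a covariate-adjusted association analysis
#'
#' @param outcome outcome column name.
#' @param family "binary" (logistic) or "continuous" (least squares).
#' @param predictor score column name; standardized to unit SD within the
#'   analysis subset before fitting, so exp(beta) is the per-SD odds ratio.
#' @param covariates character vector of covariate column names.
#' @param subset "all" or "cases-only".
#' @param reference_levels named list, categorical covariate -> reference
#'   level (e.g. diagnosis = "BP", cluster = "3").
#' @return An `assoc_spec` list.
#' @export
assoc_spec <- function(outcome, family = c("binary", "continuous"), predictor,
                       covariates = character(0), subset = c("all", "cases-only"),
                       reference_levels = list()) {
  family <- match.arg(family)
  subset <- match.arg(subset)
  if (outcome %in% covariates) stop("outcome cannot appear among covariates")
  structure(list(outcome = outcome, family = family, predictor = predictor,
                 covariates = covariates, subset = subset,
                 reference_levels = reference_levels),
            class = "assoc_spec")
}

apply_reference_levels <- function(df, reference_levels) {
  for (nm in names(reference_levels)) {
    if (nm %in% names(df))
      df[[nm]] <- stats::relevel(factor(df[[nm]]), ref = reference_levels[[nm]])
  }
  df
}

#' Fit a covariate-adjusted score association
#'
#' Logistic (binary outcome) or least-squares (continuous outcome) regression
#' of the outcome on the standardized predictor plus covariates. Reports the
#' raw and standardized coefficient with Wald 95% CI, the per-SD odds ratio
#' for binary outcomes together with Nagelkerke's R-squared, and applies the
#' Cook's-distance outlier rule (observations with distance >=
#' `cooks_exclude` are dropped and the model refit once).
#'
#' @param data data.frame holding outcome, predictor, covariates; a `status`
#'   column is required when `spec$subset == "cases-only"`.
#' @param spec an [assoc_spec()].
#' @param cooks_exclude Cook's-distance exclusion threshold (default 1.0;
#'   `Inf` disables the refit).
#' @param cooks_flag flag-only threshold (default 0.5).
#' @return An `assoc_result` list: beta (standardized), se, p, ci (95%), or
#'   (binary), r2_nagelkerke (binary), r2_adj (continuous), n, outliers
#'   (excluded sample indices), flagged.
#' @export
fit_association <- function(data, spec, cooks_exclude = 1.0, cooks_flag = 0.5) {
  df <- data
  if (spec$subset == "cases-only") {
    if (!"status" %in% names(df)) stop("cases-only subset needs a 'status' column")
    df <- df[df$status == 1, , drop = FALSE]
  }
  use <- stats::complete.cases(df[, c(spec$outcome, spec$predictor,
                                      spec$covariates), drop = FALSE])
  df <- df[use, , drop = FALSE]
  if (!nrow(df)) stop("no complete observations for ", spec$outcome)
  y <- df[[spec$outcome]]
  if (length(unique(y[!is.na(y)])) < 2)
    stop("outcome '", spec$outcome, "' is constant in the analysis subset")
  df <- apply_reference_levels(df, spec$reference_levels)
  sdp <- stats::sd(df[[spec$predictor]])
  if (!is.finite(sdp) || sdp == 0)
    stop("predictor '", spec$predictor, "' is constant")
  df$.pred_std <- (df[[spec$predictor]] - mean(df[[spec$predictor]])) / sdp
  rhs <- paste(c(".pred_std", spec$covariates), collapse = " + ")
  fml <- stats::as.formula(paste(spec$outcome, "~", rhs))

  fit_once <- function(d) {
    if (spec$family == "binary") {
      fit <- stats::glm(fml, data = d, family = stats::binomial())
      if (!fit$converged) stop("logistic fit did not converge (separation?)")
    } else fit <- stats::lm(fml, data = d)
    mm <- stats::model.matrix(fit)
    if (qr(mm)$rank < ncol(mm)) {
      alias <- colnames(mm)[is.na(stats::coef(fit))]
      stop("rank-deficient design; collinear columns: ",
           paste(alias, collapse = ", "))
    }
    fit
  }
  fit <- fit_once(df)
  cd <- stats::cooks.distance(fit)
  flagged <- which(cd >= cooks_flag & cd < cooks_exclude)
  outliers <- which(cd >= cooks_exclude)
  outlier_ids <- rownames(df)[outliers]
  if (length(outliers)) {
    df <- df[-outliers, , drop = FALSE]
    fit <- fit_once(df)
  }
  sm <- summary(fit)$coefficients
  est <- sm[".pred_std", 1]; se <- sm[".pred_std", 2]; p <- sm[".pred_std", 4]
  ci <- est + c(-1, 1) * stats::qnorm(0.975) * se
  out <- list(beta = est, se = se, p = p, ci = ci, n = nrow(df),
              outcome = spec$outcome, predictor = spec$predictor,
              family = spec$family,
              outliers = outlier_ids,
              n_outliers = length(outliers), flagged = length(flagged),
              fit = fit)
  if (spec$family == "binary") {
    null_fml <- stats::as.formula(paste(
      spec$outcome, "~", if (length(spec$covariates))
        paste(spec$covariates, collapse = " + ") else "1"))
    null_fit <- stats::glm(null_fml, data = df, family = stats::binomial())
    out$or <- exp(est)
    out$or_ci <- exp(ci)
    out$r2_nagelkerke <- nagelkerke_r2(fit, null_fit)
  } else {
    out$r2_adj <- summary(fit)$adj.r.squared
    # standardized beta (predictor already unit-SD): scale by outcome SD
    out$beta_std <- est / stats::sd(df[[spec$outcome]])
    out$beta_std_ci <- ci / stats::sd(df[[spec$outcome]])
  }
  class(out) <- "assoc_result"
  out
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s ~ %s (%s, n=%d): beta=%.3f [%.3f, %.3f], p=%.3g\n",
              x$outcome, x$predictor, x$family, x$n, x$beta, x$ci[1], x$ci[2],
              x$p))
  if (!is.null(x$or))
    cat(sprintf("  per-SD OR=%.3f [%.3f, %.3f], Nagelkerke R2=%.4f\n",
                x$or, x$or_ci[1], x$or_ci[2], x$r2_nagelkerke))
  invisible(x)
}

#' Nagelkerke's pseudo R-squared
#'
#' R2_CS = 1 - exp((2/n)(ll_null - ll_full)); Nagelkerke rescales by the
#' maximum attainable value 1 - exp((2/n) ll_null).
#'
#' @param fitted full model (a `glm`).
#' @param null intercept/covariate-only model on the same outcome and subset.
#' @return Value in [0, 1].
#' @export
nagelkerke_r2 <- function(fitted, null) {
  n <- stats::nobs(fitted)
  if (n != stats::nobs(null))
    stop("full and null models were fit on different subsets")
  ll_full <- as.numeric(stats::logLik(fitted))
  ll_null <- as.numeric(stats::logLik(null))
  if (ll_full < ll_null - 1e-8)
    stop("full-model likelihood below the null's; fit failure")
  r2_cs <- 1 - exp((2 / n) * (ll_null - ll_full))
  r2_cs / (1 - exp((2 / n) * ll_null))
}

#' Cook's-distance outlier report
#'
#' @param fit a fitted `lm`/`glm`.
#' @param flag_at flag threshold (default 0.5).
#' @param exclude_at exclusion threshold (default 1.0).
#' @return list(distance, flagged, excluded) with observation indices.
#' @export
cooks_outliers <- function(fit, flag_at = 0.5, exclude_at = 1.0) {
  cd <- stats::cooks.distance(fit)
  list(distance = cd,
       flagged = which(cd >= flag_at & cd < exclude_at),
       excluded = which(cd >= exclude_at))
}

#' Galwey effective number of independent tests
#'
#' meff = (sum sqrt(lambda))^2 / sum(lambda) over the eigenvalues (clipped at
#' zero) of the test-statistic correlation matrix; lies in [1, m] and equals
#' m only for the identity.
#'
#' @param corr_matrix symmetric correlation matrix with unit diagonal.
#' @return Effective test count (not rounded).
#' @export
galwey_meff <- function(corr_matrix) {
  corr_matrix <- as.matrix(corr_matrix)
  if (!isSymmetric(unname(corr_matrix), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  ev <- pmax(eigen(corr_matrix, symmetric = TRUE, only.values = TRUE)$values, 0)
  sum(sqrt(ev))^2 / sum(ev)
}

#' Effective multiple-testing budget
#'
#' Rounds each effective count half-up to an integer, multiplies them, and
#' adds `extra_tests` standalone tests.
#'
#' @param meff_predictors,meff_outcomes effective counts (e.g. from
#'   [galwey_meff()]).
#' @param extra_tests standalone tests added to the product (default 1).
#' @return Integer total budget.
#' @export
effective_test_budget <- function(meff_predictors, meff_outcomes,
                                  extra_tests = 1) {
  stopifnot(meff_predictors > 0, meff_outcomes > 0, extra_tests >= 0)
  half_up <- function(x) floor(x + 0.5)
  half_up(meff_predictors) * half_up(meff_outcomes) + extra_tests
}

#' Benjamini-Hochberg FDR with an effective-test budget
#'
#' Standard step-up with monotone q-values; `m_override` corrects against an
#' effective budget (e.g. 61) instead of the list length.
#'
#' @param p_values vector of p-values in (0, 1].
#' @param q FDR level (default 0.10).
#' @param m_override effective number of tests (default `length(p_values)`).
#' @return list(q_values, discovery) aligned with the input order.
#' @export
bh_fdr <- function(p_values, q = 0.10, m_override = length(p_values)) {
  stopifnot(all(p_values > 0 & p_values <= 1, na.rm = TRUE))
  k <- length(p_values)
  ord <- order(p_values)
  qv <- p_values[ord] * m_override / seq_len(k)
  qv <- rev(cummin(rev(qv)))
  qv <- pmin(qv, 1)
  out <- numeric(k)
  out[ord] <- qv
  list(q_values = out, discovery = out <= q)
}

#' Pairwise-complete Pearson correlation matrix
#'
#' Convenience wrapper used for the score and endophenotype correlation
#' matrices fed to [galwey_meff()]; NA diagonals (zero-variance columns) are
#' set to 1 and off-diagonal NAs to 0 so the matrix stays usable.
#'
#' @param x numeric matrix/data.frame (samples x variables).
#' @return Correlation matrix.
#' @export
pairwise_corr <- function(x) {
  r <- suppressWarnings(stats::cor(as.matrix(x), use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r
}
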