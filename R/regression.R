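# Multiple linear regression of RBC endpoints on clinical and genetic
# covariates, with standardized coefficients and the standard diagnostics.

#' Durbin-Watson statistic
#'
#' `DW = sum(diff(e)^2) / sum(e^2)`, with a flag for the conventional
#' acceptable range of 1.50-2.50 for independent residuals.
#'
#' @param residuals numeric residual vector (n >= 2).
#' @return list: `statistic`, `in_range` (1.50-2.50), `flags`.
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2L) stop("need >= 2 residuals", call. = FALSE)
  ss <- sum(residuals^2)
  if (ss == 0) {
    return(list(statistic = NA_real_, in_range = NA,
                flags = "zero residual sum of squares"))
  }
  dw <- sum(diff(residuals)^2) / ss
  list(statistic = dw, in_range = dw >= 1.5 && dw <= 2.5,
       flags = character(0))
}

#' Breusch-Pagan heteroscedasticity test
#'
#' Classic Lagrange-multiplier form: regress the squared residuals on the
#' design, `LM = n * R^2_aux`, p from chi-square with df = number of
#' design columns.
#'
#' @param residuals residuals of the fitted model.
#' @param design numeric matrix or data.frame of the covariates as fitted
#'   (no intercept column).
#' @return `qv_test` result.
#' @export
breusch_pagan <- function(residuals, design) {
  design <- as.matrix(design)
  stopifnot(nrow(design) == length(residuals))
  e2 <- residuals^2
  if (stats::var(e2) == 0) {
    return(qv_test_result(NA_real_, NA_real_, "Breusch-Pagan",
                          flags = "degenerate auxiliary fit"))
  }
  aux <- stats::lm(e2 ~ design)
  r2 <- summary(aux)$r.squared
  lm_stat <- length(residuals) * r2
  df <- ncol(design)
  qv_test_result(lm_stat, stats::pchisq(lm_stat, df = df, lower.tail = FALSE),
                 sprintf("Breusch-Pagan (df = %d)", df))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing covariate j on the remaining
#' covariates. Perfectly collinear covariates get `Inf`.
#'
#' @param design numeric matrix or data.frame with >= 2 covariate columns.
#' @param flag_at threshold for the `flagged` indicator (default 5).
#' @return data.frame: `covariate`, `vif`, `flagged`.
#' @export
vif <- function(design, flag_at = 5) {
  design <- as.matrix(design)
  if (ncol(design) < 2L) stop("need >= 2 covariates", call. = FALSE)
  out <- vapply(seq_len(ncol(design)), function(j) {
    fit <- stats::lm(design[, j] ~ design[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  nm <- colnames(design)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(design)))
  data.frame(covariate = nm, vif = out, flagged = out >= flag_at,
             stringsAsFactors = FALSE)
}

#' Fit a multiple linear regression with standardized coefficients
#'
#' Ordinary least squares of one dependent variable on a set of covariates.
#' The dependent variable and continuous covariates are z-scored before
#' fitting; dummy-coded covariates enter as coded, so coefficients of
#' continuous covariates are standardized betas. Reports R-squared with its
#' overall-F p-value, per-covariate betas with t-based confidence
#' intervals and two-sided p-values, and the diagnostics panel
#' (Durbin-Watson, Breusch-Pagan, VIF, Shapiro-Wilk on residuals).
#'
#' Fits with fewer than 10 observations per variable are flagged (not
#' refused); normality violations are reported, never gating.
#'
#' @param data data.frame containing all variables.
#' @param dependent name of the dependent variable.
#' @param covariates names of continuous covariates (z-scored).
#' @param dummy_covariates names of dummy-coded covariates (entered raw).
#' @param family_id FDR family label carried into [model_screen()].
#' @param label model label (defaults to the dependent name).
#' @param conf_level confidence level for coefficient intervals.
#' @return list of class `mlr_result`: `label`, `family_id`, `n`,
#'   `r_squared`, `r2_p`, `coefficients` (data.frame `term`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `p`, `standardized`), `diagnostics` (list
#'   `durbin_watson`, `breusch_pagan_p`, `vif`, `max_vif`,
#'   `shapiro_wilk_p`), `flags`.
#' @export
fit_mlr <- function(data, dependent, covariates, dummy_covariates = character(0),
                    family_id = "default", label = dependent,
                    conf_level = 0.95) {
  vars <- c(dependent, covariates, dummy_covariates)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0L) {
    stop("data lacks variable(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  df <- stats::na.omit(data[vars])
  n <- nrow(df)
  k <- length(covariates) + length(dummy_covariates)
  flags <- character(0)
  if (n <= 10 * k) flags <- c(flags, "fewer than 10 observations per variable")
  zscore <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("constant variable cannot be z-scored", call. = FALSE)
    (v - mean(v)) / s
  }
  y <- zscore(df[[dependent]])
  x <- df[c(covariates, dummy_covariates)]
  for (v in covariates) x[[v]] <- zscore(x[[v]])
  xm <- as.matrix(x)
  fit <- stats::lm(y ~ xm)
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) {
    bad <- sub("^xm", "", names(coefs)[is.na(coefs)])
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients[-1, , drop = FALSE]  # drop intercept
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  coef_df <- data.frame(
    term = sub("^xm", "", rownames(ct)),
    beta = ct[, 1], se = ct[, 2],
    ci_low = ct[, 1] - tcrit * ct[, 2],
    ci_high = ct[, 1] + tcrit * ct[, 2],
    p = ct[, 4],
    standardized = sub("^xm", "", rownames(ct)) %in% covariates,
    stringsAsFactors = FALSE)
  rownames(coef_df) <- NULL
  fstat <- sm$fstatistic
  r2_p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  resid <- stats::residuals(fit)
  vif_tab <- if (ncol(xm) >= 2L) vif(xm) else NULL
  diag <- list(
    durbin_watson = durbin_watson(resid)$statistic,
    breusch_pagan_p = breusch_pagan(resid, xm)$p_value,
    vif = vif_tab,
    max_vif = if (is.null(vif_tab)) NA_real_ else max(vif_tab$vif),
    shapiro_wilk_p = if (n >= 3 && n <= 5000) shapiro_wilk(resid)$p_value
                     else NA_real_)
  structure(list(label = label, family_id = family_id, n = n,
                 r_squared = sm$r.squared, r2_p = unname(r2_p),
                 coefficients = coef_df, diagnostics = diag, flags = flags),
            class = "mlr_result")
}

#' @export
print.mlr_result <- function(x, ...) {
  cat("MLR:", x$label, " (n =", x$n, ")\n")
  cat("  R-squared =", format(x$r_squared), " overall-F p =",
      format(x$r2_p), "\n")
  print(x$coefficients, row.names = FALSE)
  cat("  DW =", format(x$diagnostics$durbin_watson),
      " BP p =", format(x$diagnostics$breusch_pagan_p),
      " max VIF =", format(x$diagnostics$max_vif),
      " SW p =", format(x$diagnostics$shapiro_wilk_p), "\n")
  invisible(x)
}

#' Screen a collection of regression models by FDR
#'
#' Benjamini-Hochberg adjustment applied within each FDR family,
#' separately for the model R-squared p-values and for the per-covariate
#' p-values (the two screens the regression analysis reports).
#'
#' @param results list of `mlr_result` objects from [fit_mlr()].
#' @param r2_fdr FDR level for R-squared p-values (default 0.1).
#' @param beta_fdr FDR level for covariate p-values (default 0.1).
#' @return list with `models` (data.frame `label`, `family_id`,
#'   `r_squared`, `r2_p`, `r2_q`, `r2_significant`) and `coefficients`
#'   (data.frame `label`, `family_id`, `term`, `beta`, `ci_low`,
#'   `ci_high`, `p`, `q`, `significant`).
#' @export
model_screen <- function(results, r2_fdr = 0.1, beta_fdr = 0.1) {
  stopifnot(all(vapply(results, inherits, logical(1), "mlr_result")))
  models <- do.call(rbind, lapply(results, function(r) {
    data.frame(label = r$label, family_id = r$family_id,
               r_squared = r$r_squared, r2_p = r$r2_p,
               stringsAsFactors = FALSE)
  }))
  coefs <- do.call(rbind, lapply(results, function(r) {
    cbind(data.frame(label = r$label, family_id = r$family_id,
                     stringsAsFactors = FALSE),
          r$coefficients[c("term", "beta", "ci_low", "ci_high", "p")])
  }))
  models$r2_q <- NA_real_; models$r2_significant <- NA
  for (fam in unique(models$family_id)) {
    idx <- models$family_id == fam
    fdr <- bh_fdr(models$r2_p[idx], r2_fdr)
    models$r2_q[idx] <- fdr$q
    models$r2_significant[idx] <- fdr$reject
  }
  coefs$q <- NA_real_; coefs$significant <- NA
  for (fam in unique(coefs$family_id)) {
    idx <- coefs$family_id == fam
    fdr <- bh_fdr(coefs$p[idx], beta_fdr)
    coefs$q[idx] <- fdr$q
    coefs$significant[idx] <- fdr$reject
  }
  rownames(models) <- rownames(coefs) <- NULL
  list(models = models, coefficients = coefs)
}
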