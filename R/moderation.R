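#' Specify an age-moderated regression model
#'
#' Describes one model of the analysis battery: an outcome (MA at Time 1 or
#' Time 2), one or more focal neurochemical predictors, the age moderator,
#' and optional covariates. Every focal predictor enters both as a main
#' effect and as a product with the moderator; the parents of each
#' interaction are always present.
#'
#' @param outcome Column name of the outcome.
#' @param focal Character vector of focal predictor column names.
#' @param moderator Column name of the moderator (age in months).
#' @param covariates Optional covariate column names (e.g. matrix reasoning,
#'   gender, age at Time 2 in prediction models).
#' @param label Optional model label used in reports.
#' @param vif_exempt Covariates exempt from the multicollinearity gate (the
#'   follow-up age in prediction models, which is near-collinear with
#'   baseline age by design).
#' @return An object of class `ma_model_spec`.
#' @seealso [fit_moderation()]
#' @export
model_spec <- function(outcome, focal, moderator, covariates = character(),
                       label = NULL, vif_exempt = character()) {
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(focal), length(focal) >= 1L,
            is.character(moderator), length(moderator) == 1L,
            is.character(covariates))
  if (outcome %in% c(focal, moderator, covariates))
    stop_named("mrsma_validation_error", "outcome cannot also be a predictor")
  if (anyDuplicated(c(focal, moderator, covariates)))
    stop_named("mrsma_validation_error", "duplicated predictor in model spec")
  structure(list(outcome = outcome, focal = focal, moderator = moderator,
                 covariates = covariates,
                 label = label %||% paste0(outcome, " ~ (",
                                           paste(focal, collapse = " + "),
                                           ") * ", moderator),
                 vif_exempt = vif_exempt),
            class = "ma_model_spec")
}

#' Add a covariate to an existing model specification
#'
#' Convenience for the covariate-adjusted variants of the battery:
#' `"matrix_reasoning"` resolves to the matrix column of the outcome's
#' timepoint, `"gender"` to the gender column; any other string is used as a
#' column name directly. Covariates enter as main effects only.
#'
#' @param spec An `ma_model_spec`.
#' @param covariate `"matrix_reasoning"`, `"gender"`, or a column name.
#' @return A new `ma_model_spec`.
#' @export
covariate_variant <- function(spec, covariate) {
  stopifnot(inherits(spec, "ma_model_spec"))
  tp <- if (grepl("_t2$", spec$outcome)) "t2" else "t1"
  col <- switch(covariate,
                matrix_reasoning = paste0("matrix_", tp),
                gender = "gender",
                covariate)
  model_spec(spec$outcome, spec$focal, spec$moderator,
             covariates = c(spec$covariates, col),
             label = paste0(spec$label, " + ", col),
             vif_exempt = spec$vif_exempt)
}

# Standardize one variable for the analysis sample: numeric variables are
# z-scored; binary variables (two unique values, or non-numeric) become a
# mean-centred 0/1 indicator.
standardize_var <- function(x, name) {
  if (!is.numeric(x)) x <- as.numeric(factor(x)) - 1
  ux <- unique(x)
  if (length(ux) < 2)
    stop_named("mrsma_degenerate_error", "variable '%s' is constant", name)
  if (length(ux) == 2) {
    x <- (x - min(x)) / diff(range(x))  # 0/1
    return(x - mean(x))
  }
  zscore(x, name)
}

#' Fit an age-moderated regression with standardized coefficients and HC0
#' robust inference
#'
#' Ordinary least squares on standardized variables: the outcome, the
#' moderator, each focal predictor and each numeric covariate are z-scored
#' over the analysis sample (listwise-complete cases for the model's
#' variables); binary covariates are mean-centred indicators. Each
#' interaction regressor is the product of the standardized parents (set
#' `standardize_product = TRUE` to re-standardize the product itself).
#' Reported per-term: standardized beta, classical SE, HC0 robust SE,
#' `t = beta / robust SE`, and the two-sided P value from the t distribution
#' on the residual degrees of freedom. Model-level: adjusted R-squared and
#' its change versus the model omitting the interaction terms.
#'
#' @param data data.frame holding the model's columns (e.g. from
#'   [analysis_frame()]).
#' @param spec An [model_spec()] object.
#' @param standardize_product Re-standardize product regressors (default
#'   `FALSE`; the conventional product-of-standardized-parents form).
#' @return An object of class `ma_fit`; see Details for its fields.
#' @details The returned list contains `coefficients` (a per-term
#'   data.frame: `term`, `beta`, `se`, `se_hc0`, `t`, `df`, `p_hc0`), `n`,
#'   `df_residual`, `vcov_classical`, `vcov_hc0`, `residuals`, `fitted`,
#'   `r2`, `r2_adj`, `dr2_adj`, `lm` (the underlying fit on the standardized
#'   frame), `terms` (name bookkeeping incl. interaction columns),
#'   `moderator_stats` (raw-unit mean, SD, range) and `spec`.
#' @export
fit_moderation <- function(data, spec, standardize_product = FALSE) {
  stopifnot(inherits(spec, "ma_model_spec"))
  vars <- c(spec$outcome, spec$focal, spec$moderator, spec$covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop_named("mrsma_validation_error", "fit_moderation: missing columns: %s",
               paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  p <- 2L + 2L * length(spec$focal) + length(spec$covariates)
  n <- nrow(d)
  if (n < p + 2L)
    stop_named("mrsma_validation_error",
               "only %d complete cases for %d parameters (need >= %d)", n, p, p + 2L)

  mod_raw <- d[[spec$moderator]]
  z <- data.frame(row.names = seq_len(n))
  y <- standardize_var(d[[spec$outcome]], spec$outcome)
  for (v in c(spec$focal, spec$moderator, spec$covariates))
    z[[v]] <- standardize_var(d[[v]], v)
  for (v in spec$covariates)
    if (abs(stats::cor(z[[v]], y)) > 1 - 1e-12)
      stop_named("mrsma_degenerate_error",
                 "covariate '%s' duplicates the outcome; fit degenerate", v)
  inter <- paste0(spec$focal, "_x_", spec$moderator)
  for (i in seq_along(spec$focal)) {
    prod <- z[[spec$focal[i]]] * z[[spec$moderator]]
    z[[inter[i]]] <- if (standardize_product) zscore(prod, inter[i]) else prod
  }

  X <- cbind(`(Intercept)` = 1, as.matrix(z))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_named("mrsma_rank_error", "rank-deficient design; aliased term(s): %s",
               paste(aliased, collapse = ", "))
  }

  zfit <- z
  zfit$.y <- y
  lmfit <- stats::lm(.y ~ ., data = zfit)
  beta <- stats::coef(lmfit)
  names(beta) <- colnames(X)  # lm backticks some names; restore ours
  e <- stats::residuals(lmfit)
  dfres <- n - ncol(X)
  # summary.lm warns on exact fits, a legitimate input here
  sm <- suppressWarnings(summary(lmfit))
  vc_cl <- suppressWarnings(stats::vcov(lmfit))
  dimnames(vc_cl) <- list(colnames(X), colnames(X))
  vc_hc0 <- hc0_covariance(X, e)

  reduced <- zfit[, setdiff(names(zfit), inter), drop = FALSE]
  sm_red <- suppressWarnings(summary(stats::lm(.y ~ ., data = reduced)))
  r2_adj_reduced <- sm_red$adj.r.squared
  r2_reduced <- sm_red$r.squared

  se_cl <- sqrt(diag(vc_cl))
  se_h <- sqrt(diag(vc_hc0))
  tstat <- beta / se_h
  pval <- 2 * stats::pt(-abs(tstat), dfres)
  coefs <- data.frame(term = colnames(X), beta = unname(beta),
                      se = unname(se_cl), se_hc0 = unname(se_h),
                      t = unname(tstat), df = dfres, p_hc0 = unname(pval),
                      stringsAsFactors = FALSE)

  structure(list(
    coefficients = coefs, n = n, df_residual = dfres,
    vcov_classical = vc_cl, vcov_hc0 = vc_hc0,
    residuals = unname(e), fitted = unname(stats::fitted(lmfit)),
    r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
    r2_reduced = r2_reduced,
    dr2_adj = sm$adj.r.squared - r2_adj_reduced,
    lm = lmfit, X = X,
    terms = list(outcome = spec$outcome, focal = spec$focal,
                 moderator = spec$moderator, covariates = spec$covariates,
                 interaction = stats::setNames(inter, spec$focal)),
    moderator_stats = list(mean = mean(mod_raw), sd = stats::sd(mod_raw),
                           range = range(mod_raw)),
    spec = spec
  ), class = "ma_fit")
}

#' @export
print.ma_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Age-moderated regression: %s\n", x$spec$label))
  cat(sprintf("  n = %d, residual df = %d, R2_adj = %.3f, dR2_adj = %.3f\n",
              x$n, x$df_residual, x$r2_adj, x$dr2_adj))
  tab <- x$coefficients
  tab$beta <- round(tab$beta, digits); tab$se <- round(tab$se, digits)
  tab$se_hc0 <- round(tab$se_hc0, digits); tab$t <- round(tab$t, 2)
  tab$p_hc0 <- signif(tab$p_hc0, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Per-term results table of a fitted model
#'
#' @param fit An `ma_fit`.
#' @param interaction_only Keep only the focal-by-moderator interaction rows.
#' @return data.frame of per-term results with model-level `r2_adj` and
#'   `dr2_adj` columns appended.
#' @export
coef_table <- function(fit, interaction_only = FALSE) {
  stopifnot(inherits(fit, "ma_fit"))
  tab <- fit$coefficients
  if (interaction_only)
    tab <- tab[tab$term %in% fit$terms$interaction, , drop = FALSE]
  tab$n <- fit$n
  tab$r2_adj <- fit$r2_adj
  tab$dr2_adj <- fit$dr2_adj
  tab$model <- fit$spec$label
  rownames(tab) <- NULL
  tab
}

#' White's HC0 heteroscedasticity-consistent covariance
#'
#' The sandwich `(X'X)^-1 X' diag(e^2) X (X'X)^-1` with no small-sample
#' scaling.
#'
#' @param X Design matrix (n x p, full column rank).
#' @param residuals OLS residuals (length n).
#' @return p x p covariance matrix (symmetric, positive semi-definite).
#' @export
hc0_covariance <- function(X, residuals) {
  X <- as.matrix(X)
  if (nrow(X) != length(residuals))
    stop_named("mrsma_validation_error",
               "hc0_covariance: X has %d rows but %d residuals",
               nrow(X), length(residuals))
  XtX <- crossprod(X)
  if (qr(XtX)$rank < ncol(X))
    stop_named("mrsma_rank_error", "hc0_covariance: design not full rank")
  bread <- solve(XtX)
  meat <- crossprod(X * residuals)
  V <- bread %*% meat %*% bread
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Joint specificity model: all four neurochemical measures at one timepoint
#'
#' One regression with the four metabolite-by-region measures (glutamate and
#' GABA in IPS and MFG), age, and all four measure-by-age interactions,
#' testing whether each measure explains unique variance in MA.
#'
#' @param data Analysis frame (see [analysis_frame()]).
#' @param timepoint 1 or 2.
#' @param covariates Optional extra covariates.
#' @return An `ma_fit`.
#' @export
specificity_model <- function(data, timepoint = 1, covariates = character()) {
  tp <- paste0("t", timepoint)
  focal <- paste0(measure_keys(), "_", tp)
  miss <- setdiff(focal, names(data))
  if (length(miss))
    stop_named("mrsma_validation_error",
               "specificity_model: missing measure columns: %s",
               paste(miss, collapse = ", "))
  spec <- model_spec(paste0("ma_", tp), focal, paste0("age_months_", tp),
                     covariates = covariates,
                     label = sprintf("specificity T%d", timepoint))
  fit_moderation(data, spec)
}

#' Predict future achievement from baseline neurochemistry
#'
#' Outcome MA at Time 2; predictors are the Time-1 concentration, Time-1
#' age, their product, and Time-2 age as a covariate. Time-2 age is exempt
#' from the multicollinearity gate (it is near-collinear with Time-1 age by
#' design of the follow-up).
#'
#' @param data Analysis frame.
#' @param metabolite,region Focal measure (defaults IPS glutamate); ignored
#'   when `all_measures = TRUE`.
#' @param all_measures Fit the prediction specificity model with all four
#'   measures at once.
#' @param covariates Optional extra covariates.
#' @return An `ma_fit`.
#' @export
predict_future_ma <- function(data, metabolite = "Glutamate", region = "IPS",
                              all_measures = FALSE, covariates = character()) {
  focal <- if (all_measures) paste0(measure_keys(), "_t1")
           else paste0(metabolite, "_", region, "_t1")
  miss <- setdiff(c(focal, "ma_t2", "age_months_t2"), names(data))
  if (length(miss))
    stop_named("mrsma_validation_error",
               "predict_future_ma: missing columns: %s", paste(miss, collapse = ", "))
  spec <- model_spec("ma_t2", focal, "age_months_t1",
                     covariates = c("age_months_t2", covariates),
                     label = if (all_measures) "prediction specificity"
                             else sprintf("prediction %s %s", region, metabolite),
                     vif_exempt = "age_months_t2")
  fit_moderation(data, spec)
}
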