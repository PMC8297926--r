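#' Breusch-Pagan test for heteroscedasticity
#'
#' Auxiliary regression of the (scaled) squared residuals on the model's
#' predictors. The default is the studentized (Koenker) variant,
#' `LM = n * R2_aux` with the squared residuals as the auxiliary outcome,
#' which is robust to non-normality and invariant to rescaling the outcome.
#' The classic variant regresses `e^2 / mean(e^2)` and uses `LM = ESS / 2`.
#' P values come from the chi-square distribution on k df (k = number of
#' non-intercept predictors).
#'
#' @param fit An `ma_fit`.
#' @param studentized Use the Koenker variant (default `TRUE`).
#' @return list with `statistic`, `df`, `p`, `variant`.
#' @export
breusch_pagan <- function(fit, studentized = TRUE) {
  stopifnot(inherits(fit, "ma_fit"))
  e <- fit$residuals
  X <- fit$X[, setdiff(colnames(fit$X), "(Intercept)"), drop = FALSE]
  n <- length(e)
  k <- ncol(X)
  if (fit$df_residual < 2)
    stop_named("mrsma_validation_error", "too few residual df for the auxiliary regression")
  if (stats::sd(e) == 0)
    stop_named("mrsma_degenerate_error", "residuals are constant; test undefined")
  e2 <- e^2
  if (stats::sd(e2) == 0)
    return(list(statistic = 0, df = k, p = 1,
                variant = if (studentized) "studentized" else "classic"))
  if (studentized) {
    aux <- stats::lm(e2 ~ X)
    lm_stat <- n * summary(aux)$r.squared
  } else {
    g <- e2 / mean(e2)
    aux <- stats::lm(g ~ X)
    lm_stat <- sum((stats::fitted(aux) - mean(g))^2) / 2
  }
  list(statistic = lm_stat, df = k,
       p = stats::pchisq(lm_stat, k, lower.tail = FALSE),
       variant = if (studentized) "studentized" else "classic")
}

#' Shapiro-Wilk test of residual normality
#'
#' Thin wrapper around the standard Shapiro-Wilk routine applied to the raw
#' model residuals.
#'
#' @param fit An `ma_fit`, or a numeric vector of residuals.
#' @return list with `W`, `p`, `n`.
#' @export
residual_normality <- function(fit) {
  e <- if (inherits(fit, "ma_fit")) fit$residuals else fit
  if (length(e) < 3)
    stop_named("mrsma_validation_error", "Shapiro-Wilk needs n >= 3 (got %d)", length(e))
  if (stats::sd(e) == 0)
    stop_named("mrsma_degenerate_error", "residuals are constant; W undefined")
  sw <- stats::shapiro.test(e)
  list(W = unname(sw$statistic), p = sw$p.value, n = length(e))
}

#' Variance inflation factors with term exemptions
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor j
#' on the remaining predictors (intercept included). Perfect collinearity is
#' reported as an infinite VIF with the offending term named, not an error.
#' Exempt terms (the follow-up age covariate in prediction models, which is
#' near-collinear with baseline age by construction) are removed from the
#' screen entirely: they are neither candidates for the maximum nor part of
#' the auxiliary regressor pool when screening the substantive predictors
#' (otherwise baseline age would inherit the deliberate collinearity and the
#' gate would always fire). Their own VIF against the full predictor set is
#' still reported for transparency. Exemptions recorded in the model spec
#' are applied automatically.
#'
#' @param fit An `ma_fit`.
#' @param exempt Additional term names to exempt.
#' @return list with `vif` (named vector over non-intercept, non-exempt
#'   terms, computed within the non-exempt pool), `vif_exempt_terms` (the
#'   exempt terms' VIF against the full set), `max_vif`, `max_term`,
#'   `exempt`.
#' @export
vif <- function(fit, exempt = character()) {
  stopifnot(inherits(fit, "ma_fit"))
  exempt <- union(exempt, fit$spec$vif_exempt)
  X <- fit$X[, setdiff(colnames(fit$X), "(Intercept)"), drop = FALSE]
  one_vif <- function(j_col, others) {
    if (ncol(others) == 0) return(1)
    # perfect fits are expected here (that is what an infinite VIF means)
    r2 <- suppressWarnings(summary(stats::lm(j_col ~ others))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  pool <- setdiff(colnames(X), exempt)
  out <- stats::setNames(
    vapply(pool, function(nm) {
      one_vif(X[, nm], X[, setdiff(pool, nm), drop = FALSE])
    }, numeric(1)), pool)
  ex_out <- stats::setNames(
    vapply(intersect(exempt, colnames(X)), function(nm) {
      one_vif(X[, nm], X[, setdiff(colnames(X), nm), drop = FALSE])
    }, numeric(1)), intersect(exempt, colnames(X)))
  mx <- which.max(out)
  list(vif = out, vif_exempt_terms = ex_out,
       max_vif = unname(out[mx]), max_term = names(out)[mx],
       exempt = exempt)
}

#' Assumption diagnostics for one fitted model
#'
#' Bundles the heteroscedasticity, residual-normality and multicollinearity
#' checks for a model into one report row. Both Breusch-Pagan variants are
#' computed. Diagnostics never mutate the fit; repeated calls give identical
#' results.
#'
#' @param fit An `ma_fit`.
#' @return An object of class `ma_diagnostics`: a one-row data.frame with
#'   columns `model`, `n`, `bp_stat`, `bp_df`, `bp_p`, `bp_stat_classic`,
#'   `bp_p_classic`, `sw_W`, `sw_p`, `max_vif`, `max_vif_term`,
#'   `vif_exempt`.
#' @export
diagnostics_report <- function(fit) {
  stopifnot(inherits(fit, "ma_fit"))
  bp_s <- breusch_pagan(fit, studentized = TRUE)
  bp_c <- breusch_pagan(fit, studentized = FALSE)
  sw <- residual_normality(fit)
  vf <- vif(fit)
  out <- data.frame(
    model = fit$spec$label, n = fit$n,
    bp_stat = bp_s$statistic, bp_df = bp_s$df, bp_p = bp_s$p,
    bp_stat_classic = bp_c$statistic, bp_p_classic = bp_c$p,
    sw_W = sw$W, sw_p = sw$p,
    max_vif = vf$max_vif, max_vif_term = vf$max_term,
    vif_exempt = paste(vf$exempt, collapse = ","),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ma_diagnostics", "data.frame")
  out
}
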