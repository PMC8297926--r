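#' Tissue-fraction correction of an absolute metabolite concentration
#'
#' Rescales a water-referenced absolute concentration by the voxel's gray
#' matter (GM), white matter (WM) and cerebrospinal fluid (CSF) fractions:
#' \deqn{((43300/55556\,GM + 35880/55556\,WM + 1\,CSF) / (1 - CSF)) \times conc}
#' The two rational constants are the water-visibility scaling factors for
#' parenchyma relative to pure water (43300 and 35880 vs 55556 mmol/kg).
#' The operation is linear in the concentration; for fixed fractions the
#' corrected/absolute ratio is a participant-independent constant.
#'
#' Vectorized over all arguments.
#'
#' @param absolute_concentration Non-negative concentration (institutional
#'   units).
#' @param gm_fraction,wm_fraction,csf_fraction Voxel tissue fractions, each
#'   in `[0, 1]`, summing to 1 within `tol`.
#' @param tol Tolerance on the fraction sum (default 1e-6).
#' @return Corrected concentration, same length as the inputs.
#' @examples
#' tissue_correct(1, gm_fraction = 1, wm_fraction = 0, csf_fraction = 0)
#' @export
tissue_correct <- function(absolute_concentration, gm_fraction, wm_fraction,
                           csf_fraction, tol = 1e-6) {
  k <- pmax(length(absolute_concentration), length(gm_fraction))
  frs <- cbind(gm_fraction, wm_fraction, csf_fraction)
  if (any(!is.finite(frs)) || any(frs < 0) || any(frs > 1))
    stop_named("mrsma_validation_error", "tissue fractions must lie in [0, 1]")
  if (any(abs(rowSums(frs) - 1) > tol))
    stop_named("mrsma_validation_error",
               "GM + WM + CSF fractions must sum to 1 (tolerance %g)", tol)
  if (any(frs[, 3] >= 1 - tol))
    stop_named("mrsma_degenerate_voxel_error",
               "csf_fraction = 1: voxel contains no parenchyma, correction undefined")
  if (any(!is.finite(absolute_concentration)) || any(absolute_concentration < 0))
    stop_named("mrsma_validation_error", "absolute_concentration must be >= 0")
  factor <- (43300 / 55556 * frs[, 1] + 35880 / 55556 * frs[, 2] + 1 * frs[, 3]) /
    (1 - frs[, 3])
  unname(factor * absolute_concentration)
}

#' T2 relaxation adjustment of a tissue-corrected concentration
#'
#' Scales a tissue-corrected concentration by the transverse-relaxation decay
#' factor at the acquisition echo time. The published convention multiplies by
#' `exp(-TE/T2)`; note that this attenuates rather than restores the signal.
#' The alternative `convention = "physical"` divides by the decay factor,
#' which is what a relaxation-loss correction would do. The default follows
#' the printed formula.
#'
#' @param tissue_corrected Tissue-corrected concentration.
#' @param te_ms Echo time in ms (>= 0).
#' @param t2_ms T2 relaxation time in ms (> 0).
#' @param convention `"as_published"` multiplies by `exp(-TE/T2)`;
#'   `"physical"` divides.
#' @return Adjusted concentration.
#' @examples
#' t2_correct(1, te_ms = 32, t2_ms = 100)  # exp(-0.32)
#' @export
t2_correct <- function(tissue_corrected, te_ms, t2_ms,
                       convention = c("as_published", "physical")) {
  convention <- match.arg(convention)
  if (any(!is.finite(t2_ms)) || any(t2_ms <= 0))
    stop_named("mrsma_validation_error", "t2_ms must be positive")
  if (any(!is.finite(te_ms)) || any(te_ms < 0))
    stop_named("mrsma_validation_error", "te_ms must be >= 0")
  fac <- exp(-te_ms / t2_ms)
  if (convention == "as_published") tissue_corrected * fac
  else tissue_corrected / fac
}

#' Fit a mono-exponential T2 decay to a multi-echo-time series
#'
#' Least-squares fit of `S(TE) = S0 * exp(-TE/T2)`, initialized by a
#' log-linear regression on the positive signals and refined by
#' Levenberg-Marquardt nonlinear least squares.
#'
#' @param te_ms Echo times in ms (>= 3 distinct values).
#' @param signal Signal values; positive signals are required for the
#'   log-linear initialization.
#' @return A list with `t2_ms`, `s0`, `residuals`, `sigma` (residual SD) and
#'   `fitted`.
#' @examples
#' ser <- generate_multi_te_series(150, s0 = 100, noise_sd = 0)
#' fit_t2(ser$te_ms, ser$signal)$t2_ms
#' @export
fit_t2 <- function(te_ms, signal) {
  if (is.data.frame(te_ms)) { signal <- te_ms$signal; te_ms <- te_ms$te_ms }
  ok <- is.finite(te_ms) & is.finite(signal)
  te_ms <- te_ms[ok]; signal <- signal[ok]
  if (length(unique(te_ms)) < 3)
    stop_named("mrsma_validation_error",
               "T2 fit needs >= 3 distinct echo times (got %d)", length(unique(te_ms)))
  pos <- signal > 0
  if (sum(pos) < 3)
    stop_named("mrsma_fit_error", "T2 fit needs >= 3 positive signals")
  ll <- stats::lm(log(signal[pos]) ~ te_ms[pos])
  slope <- unname(stats::coef(ll)[2])
  if (!is.finite(slope) || slope >= -1e-10)
    stop_named("mrsma_fit_error",
               "series does not decay with TE; mono-exponential T2 fit failed")
  start <- list(s0 = exp(unname(stats::coef(ll)[1])), t2 = -1 / slope)
  df <- data.frame(te = te_ms, s = signal)
  nl <- tryCatch(
    minpack.lm::nlsLM(s ~ s0 * exp(-te / t2), data = df, start = start,
                      lower = c(s0 = 1e-12, t2 = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_named("mrsma_fit_error",
                                   "T2 fit did not converge: %s",
                                   conditionMessage(e)))
  est <- stats::coef(nl)
  fitted <- est[["s0"]] * exp(-te_ms / est[["t2"]])
  res <- signal - fitted
  list(t2_ms = est[["t2"]], s0 = est[["s0"]], residuals = res,
       sigma = sqrt(sum(res^2) / max(1, length(res) - 2)), fitted = fitted)
}

#' Quality control of neurochemical records
#'
#' Applies the exclusion rules in a single, non-iterative pass:
#' * `crlb_fail` - CRLB strictly greater than `crlb_max` (default 50%,
#'   "not detectable");
#' * `snr_outlier` / `conc_outlier` - SNR or concentration beyond `sd_k`
#'   (default 3) standard deviations of its cell mean, cells being
#'   age-group x region x metabolite (x timepoint when present).
#'
#' Cell means/SDs are computed once on all (pre-exclusion) records; cells
#' with fewer than 3 members skip the outlier screen (recorded in the
#' `skipped_cells` attribute). A record is retained iff it has no reasons.
#'
#' @param records data.frame with columns `age_group`, `region`,
#'   `metabolite`, `absolute_concentration`, `crlb_percent`, `snr` (and
#'   optionally `id`, `timepoint`).
#' @param crlb_max CRLB exclusion threshold in percent.
#' @param sd_k Outlier threshold in SD units.
#' @return The input data.frame plus `retained` (logical) and `qc_reasons`
#'   (comma-joined codes, `""` when retained), with attribute
#'   `skipped_cells`.
#' @export
apply_qc <- function(records, crlb_max = 50, sd_k = 3) {
  need <- c("age_group", "region", "metabolite", "absolute_concentration",
            "crlb_percent", "snr")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_named("mrsma_validation_error", "apply_qc: missing columns: %s",
               paste(miss, collapse = ", "))
  cell <- interaction(records$age_group, records$region, records$metabolite,
                      if (!is.null(records$timepoint)) records$timepoint else "",
                      drop = TRUE)
  flag_outlier <- function(x) {
    out <- logical(length(x))
    skipped <- character(0)
    for (lv in levels(cell)) {
      i <- which(cell == lv)
      if (length(i) < 3) { skipped <- c(skipped, lv); next }
      m <- mean(x[i]); s <- stats::sd(x[i])
      if (is.finite(s) && s > 0) out[i] <- abs(x[i] - m) > sd_k * s
    }
    attr(out, "skipped") <- skipped
    out
  }
  snr_out <- flag_outlier(records$snr)
  conc_out <- flag_outlier(records$absolute_concentration)
  crlb_fail <- records$crlb_percent > crlb_max
  reasons <- mapply(function(a, b, c) {
    paste(c(if (a) "crlb_fail", if (b) "snr_outlier", if (c) "conc_outlier"),
          collapse = ",")
  }, crlb_fail, snr_out, conc_out)
  records$retained <- reasons == ""
  records$qc_reasons <- unname(reasons)
  attr(records, "skipped_cells") <-
    unique(c(attr(snr_out, "skipped"), attr(conc_out, "skipped")))
  records
}

#' Spectral-fit cross-correlation gate
#'
#' Checks that the mean spectral-fit cross-correlation for the
#' glutamate-glutamine and glutamate-GABA pairs stays below .5 in each region
#' of interest, the condition under which the concentrations can be reported
#' as separate measures.
#'
#' @param fit_correlations data.frame with columns `pair`, `region`,
#'   `correlation` (one row per spectrum).
#' @param pairs Pairs that must be present.
#' @param threshold Gate threshold on the absolute mean (default 0.5).
#' @return data.frame with one row per pair x region: `pair`, `region`,
#'   `mean_correlation`, `n`, `pass`; attribute `pass` is the overall gate.
#' @export
cross_correlation_gate <- function(fit_correlations,
                                   pairs = c("Glutamate-Glutamine", "Glutamate-GABA"),
                                   threshold = 0.5) {
  need <- c("pair", "region", "correlation")
  miss <- setdiff(need, names(fit_correlations))
  if (length(miss))
    stop_named("mrsma_validation_error",
               "cross_correlation_gate: missing columns: %s", paste(miss, collapse = ", "))
  absent <- setdiff(pairs, unique(fit_correlations$pair))
  if (length(absent))
    stop_named("mrsma_missing_input_error",
               "no fit correlations for pair(s): %s", paste(absent, collapse = ", "))
  sub <- fit_correlations[fit_correlations$pair %in% pairs, , drop = FALSE]
  agg <- stats::aggregate(correlation ~ pair + region, data = sub,
                          FUN = mean)
  names(agg)[names(agg) == "correlation"] <- "mean_correlation"
  cnt <- stats::aggregate(correlation ~ pair + region, data = sub, FUN = length)
  agg$n <- cnt$correlation[match(paste(agg$pair, agg$region),
                                 paste(cnt$pair, cnt$region))]
  agg$pass <- abs(agg$mean_correlation) < threshold
  attr(agg, "pass") <- all(agg$pass)
  agg
}
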