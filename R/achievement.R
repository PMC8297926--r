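#' Proportion of correct responses
#'
#' @param correct Number correct (0 <= correct <= attempted).
#' @param attempted Number attempted (> 0).
#' @return `correct / attempted`, in `[0, 1]`. Vectorized.
#' @export
proportion_correct <- function(correct, attempted) {
  if (any(!is.finite(attempted)) || any(attempted <= 0))
    stop_named("mrsma_validation_error", "'attempted' must be > 0")
  if (any(!is.finite(correct)) || any(correct < 0) || any(correct > attempted))
    stop_named("mrsma_validation_error", "'correct' must lie in [0, attempted]")
  correct / attempted
}

#' Timed arithmetic-fluency efficiency score
#'
#' Proportion correct on the first two columns of the timed arithmetic test,
#' divided by the relative solving time:
#' `(correct/attempted) / (solving_time_s / total_time_s)`.
#' The score exceeds the raw proportion whenever the participant finished
#' early (`solving_time_s < total_time_s`); it is strictly decreasing in
#' solving time and increasing in the correct count. The divisor uses the
#' full 300 s at disposal even though only the first two 60-s columns are
#' scored - kept verbatim from the scoring definition being reproduced (see
#' the methods vignette).
#'
#' @param correct,attempted Counts for the scored columns.
#' @param solving_time_s Individual solving time in seconds (> 0).
#' @param total_time_s Total time at disposal (default 300 s).
#' @return Efficiency score. Vectorized.
#' @examples
#' tempo_efficiency(40, 40, 150)  # 2.0
#' @export
tempo_efficiency <- function(correct, attempted, solving_time_s,
                             total_time_s = 300) {
  p <- proportion_correct(correct, attempted)
  if (any(!is.finite(solving_time_s)) || any(solving_time_s <= 0))
    stop_named("mrsma_validation_error", "'solving_time_s' must be > 0")
  if (any(!is.finite(total_time_s)) || any(total_time_s <= 0))
    stop_named("mrsma_validation_error", "'total_time_s' must be > 0")
  p / (solving_time_s / total_time_s)
}

#' Composite mathematical-achievement (MA) score
#'
#' For each timepoint, computes the proportion correct on the two untimed
#' subtests and the timed efficiency score, z-scores each of the three
#' components over the participants with a non-missing value at that
#' timepoint, and averages the available z components into a single MA score.
#'
#' @param cognitive data.frame with columns `id`, `timepoint`,
#'   `numops_correct`, `numops_attempted`, `reasoning_correct`,
#'   `reasoning_attempted`, `tempo_correct`, `tempo_attempted`,
#'   `tempo_time_s` (optionally `matrix_raw`, carried through).
#' @param total_time_s Total time at disposal for the timed test.
#' @param na_policy `"available"` (default) averages whichever z components
#'   are present, reporting `n_components`; `"complete"` sets the composite
#'   to `NA` unless all three are present.
#' @param pool_timepoints If `TRUE`, z-scoring pools both timepoints instead
#'   of standardizing within each (default `FALSE`: scores are relative to
#'   the sample tested at the same occasion).
#' @return data.frame with one row per participant x timepoint: `id`,
#'   `timepoint`, `z_numops`, `z_reasoning`, `z_tempo_efficiency`,
#'   `ma_composite`, `n_components` (plus `matrix_raw` if supplied).
#' @export
composite_ma <- function(cognitive, total_time_s = 300,
                         na_policy = c("available", "complete"),
                         pool_timepoints = FALSE) {
  na_policy <- match.arg(na_policy)
  need <- c("id", "timepoint", "numops_correct", "numops_attempted",
            "reasoning_correct", "reasoning_attempted", "tempo_correct",
            "tempo_attempted", "tempo_time_s")
  miss <- setdiff(need, names(cognitive))
  if (length(miss))
    stop_named("mrsma_validation_error", "composite_ma: missing columns: %s",
               paste(miss, collapse = ", "))
  df <- cognitive
  df$p_numops <- with(df, numops_correct / numops_attempted)
  df$p_reasoning <- with(df, reasoning_correct / reasoning_attempted)
  df$eff_tempo <- with(df, (tempo_correct / tempo_attempted) /
                         (tempo_time_s / total_time_s))
  bad <- with(df, !is.na(numops_attempted) & numops_attempted <= 0)
  if (any(bad, na.rm = TRUE))
    stop_named("mrsma_validation_error", "attempted counts must be > 0")
  if (any(df$tempo_time_s <= 0, na.rm = TRUE))
    stop_named("mrsma_validation_error", "tempo_time_s must be > 0")

  zgroup <- if (pool_timepoints) rep(1L, nrow(df)) else df$timepoint
  zcol <- function(x, comp) {
    out <- rep(NA_real_, length(x))
    for (g in unique(zgroup)) {
      i <- which(zgroup == g & !is.na(x))
      if (length(i) < 2)
        stop_named("mrsma_validation_error",
                   "component '%s' has < 2 non-missing values at timepoint %s", comp, g)
      s <- stats::sd(x[i])
      if (!is.finite(s) || s == 0)
        stop_named("mrsma_degenerate_error",
                   "component '%s' has zero variance at timepoint %s; z-score undefined",
                   comp, g)
      out[i] <- (x[i] - mean(x[i])) / s
    }
    out
  }
  z <- cbind(z_numops = zcol(df$p_numops, "numerical operations"),
             z_reasoning = zcol(df$p_reasoning, "mathematical reasoning"),
             z_tempo_efficiency = zcol(df$eff_tempo, "tempo efficiency"))
  n_comp <- rowSums(!is.na(z))
  comp <- rowMeans(z, na.rm = TRUE)
  comp[n_comp == 0] <- NA_real_
  if (na_policy == "complete") comp[n_comp < 3] <- NA_real_
  out <- data.frame(id = df$id, timepoint = df$timepoint, z,
                    ma_composite = comp, n_components = n_comp,
                    stringsAsFactors = FALSE)
  if ("matrix_raw" %in% names(cognitive)) out$matrix_raw <- cognitive$matrix_raw
  out
}

#' Relations between achievement and matrix reasoning
#'
#' Spearman correlation between the MA composite and the raw
#' matrix-reasoning score, and the Pearson partial correlation with age
#' linearly removed from both variables (residual-on-residual form).
#' Degrees of freedom are reported as `n - 2` and `n - 3` respectively.
#'
#' @param ma MA composite scores.
#' @param matrix_reasoning Raw matrix-reasoning scores.
#' @param age_months Age in months.
#' @return list with `spearman_r`, `spearman_df`, `partial_r`, `partial_df`,
#'   `n`.
#' @export
matrix_relations <- function(ma, matrix_reasoning, age_months) {
  ok <- stats::complete.cases(ma, matrix_reasoning, age_months)
  ma <- ma[ok]; mr <- matrix_reasoning[ok]; age <- age_months[ok]
  n <- length(ma)
  if (n < 4)
    stop_named("mrsma_validation_error",
               "matrix_relations needs >= 4 complete cases (got %d)", n)
  if (stats::sd(ma) == 0 || stats::sd(mr) == 0 || stats::sd(age) == 0)
    stop_named("mrsma_degenerate_error",
               "constant input: correlation undefined")
  rs <- stats::cor(ma, mr, method = "spearman")
  r1 <- stats::residuals(stats::lm(ma ~ age))
  r2 <- stats::residuals(stats::lm(mr ~ age))
  if (stats::sd(r1) == 0 || stats::sd(r2) == 0)
    stop_named("mrsma_degenerate_error",
               "a variable is an exact linear function of age; partial correlation undefined")
  list(spearman_r = rs, spearman_df = n - 2L,
       partial_r = stats::cor(r1, r2), partial_df = n - 3L, n = n)
}
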