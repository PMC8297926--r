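# Internal: locate the focal main-effect and interaction coefficients and
# the relevant 2x2 covariance block for a fitted moderation model.
jn_parts <- function(fit, focal = NULL, vcov = c("HC0", "classical")) {
  stopifnot(inherits(fit, "ma_fit"))
  vcov <- match.arg(vcov)
  focal <- focal %||% fit$terms$focal[1]
  if (!focal %in% fit$terms$focal)
    stop_named("mrsma_validation_error", "'%s' is not a focal term of this fit", focal)
  inter <- fit$terms$interaction[[focal]]
  b <- stats::setNames(fit$coefficients$beta, fit$coefficients$term)
  if (!inter %in% names(b))
    stop_named("mrsma_validation_error", "fit has no interaction term for '%s'", focal)
  V <- if (vcov == "HC0") fit$vcov_hc0 else fit$vcov_classical
  list(b1 = b[[focal]], b3 = b[[inter]],
       v11 = V[focal, focal], v13 = V[focal, inter], v33 = V[inter, inter],
       focal = focal, inter = inter, vcov = vcov)
}

# moderator months <-> standardized units
mod_to_z <- function(fit, m) (m - fit$moderator_stats$mean) / fit$moderator_stats$sd
z_to_mod <- function(fit, z) fit$moderator_stats$mean + z * fit$moderator_stats$sd

#' Conditional effect of the focal predictor at a moderator value
#'
#' The simple slope `b1 + b3 * z(m)` of the focal predictor at moderator
#' value `m` (age in months), with its standard error from the quadratic
#' form `var(b1) + 2 z cov(b1,b3) + z^2 var(b3)` under the selected
#' covariance, the t statistic on the model's residual df, and the
#' two-sided P value. Vectorized over `m`.
#'
#' @param fit An `ma_fit`.
#' @param m Moderator value(s) in raw units (months).
#' @param focal Focal term (default: the fit's first focal predictor).
#' @param vcov `"HC0"` (default) or `"classical"`.
#' @return data.frame with columns `m`, `effect`, `se`, `t`, `df`, `p`.
#' @export
conditional_effect <- function(fit, m, focal = NULL,
                               vcov = c("HC0", "classical")) {
  pr <- jn_parts(fit, focal, vcov)
  zm <- mod_to_z(fit, m)
  eff <- pr$b1 + pr$b3 * zm
  v <- pr$v11 + 2 * zm * pr$v13 + zm^2 * pr$v33
  se <- sqrt(pmax(v, 0))
  tt <- eff / se
  data.frame(m = m, effect = eff, se = se, t = tt, df = fit$df_residual,
             p = 2 * stats::pt(-abs(tt), fit$df_residual))
}

#' Johnson-Neyman significance boundaries for a continuous interaction
#'
#' Solves `(b1 + b3 z)^2 = t_crit^2 (v11 + 2 z v13 + z^2 v33)` for the
#' moderator values at which the conditional effect's test statistic equals
#' the two-sided critical t on the model's residual df, under the selected
#' covariance (HC0 by default, consistent with the robust inferential
#' framework). Zero, one or two real boundaries may exist; each is reported
#' in months and years, flagged when it falls outside the observed moderator
#' range, and the significance of the conditional effect is evaluated on
#' each side. When the quadratic is fully degenerate (`b3 = 0` and
#' `v33 = 0`) the result is a no-boundary region, not an error.
#'
#' @param fit An `ma_fit`.
#' @param alpha Two-sided significance level (default .05).
#' @param focal Focal term (default: first).
#' @param vcov `"HC0"` (default) or `"classical"`.
#' @return An object of class `jn_region`: list with `boundaries` (data.frame
#'   `months`, `years`, `in_range`), `lower_months`, `upper_months` (NA when
#'   absent), `significant_below`, `significant_between`,
#'   `significant_above` (directions -1/0/+1 of the conditional effect where
#'   significant, 0 where not), `alpha`, `t_crit`, `vcov`,
#'   `moderator_range`, and `significance_at_midrange`.
#' @export
jn_boundaries <- function(fit, alpha = 0.05, focal = NULL,
                          vcov = c("HC0", "classical")) {
  pr <- jn_parts(fit, focal, vcov)
  check_scalar(alpha, "alpha", lower = 0, upper = 1,
               allow_equal_lower = FALSE, allow_equal_upper = FALSE)
  tc <- stats::qt(1 - alpha / 2, fit$df_residual)
  a <- pr$b3^2 - tc^2 * pr$v33
  bq <- 2 * (pr$b1 * pr$b3 - tc^2 * pr$v13)
  cq <- pr$b1^2 - tc^2 * pr$v11
  roots <- numeric(0)
  scale <- max(abs(c(a, bq, cq)), 1e-300)
  if (abs(a) / scale < 1e-14) {
    if (abs(bq) / scale >= 1e-14) roots <- -cq / bq
    # else: fully degenerate (b3 = 0 and v33 = 0 up to scale) -> no boundary
  } else {
    disc <- bq^2 - 4 * a * cq
    if (disc >= 0) {
      # numerically stable quadratic roots
      q <- -(bq + sign(bq + (bq == 0)) * sqrt(disc)) / 2
      roots <- sort(unique(c(q / a, if (q != 0) cq / q else -bq / a - q / a)))
      roots <- roots[is.finite(roots)]
    }
  }
  months <- z_to_mod(fit, roots)
  rng <- fit$moderator_stats$range
  bnd <- data.frame(months = months, years = months / 12,
                    in_range = months >= rng[1] & months <= rng[2])

  # significance direction on each side, evaluated between/beyond boundaries
  probe <- function(m) {
    ce <- conditional_effect(fit, m, pr$focal, pr$vcov)
    if (ce$p < alpha) sign(ce$effect) else 0
  }
  span <- max(diff(rng), fit$moderator_stats$sd)
  if (length(months) == 2) {
    dirs <- c(probe(months[1] - 0.05 * span),
              probe(mean(months)),
              probe(months[2] + 0.05 * span))
  } else if (length(months) == 1) {
    dirs <- c(probe(months - 0.05 * span), NA, probe(months + 0.05 * span))
  } else {
    mid <- mean(rng)
    dirs <- c(NA, probe(mid), NA)
  }

  structure(list(
    boundaries = bnd,
    lower_months = if (length(months)) min(months) else NA_real_,
    upper_months = if (length(months)) max(months) else NA_real_,
    significant_below = dirs[1], significant_between = dirs[2],
    significant_above = dirs[3],
    alpha = alpha, t_crit = tc, vcov = pr$vcov, focal = pr$focal,
    moderator_range = rng,
    significance_at_midrange = probe(mean(rng)),
    df = fit$df_residual
  ), class = "jn_region")
}

#' @export
print.jn_region <- function(x, ...) {
  cat(sprintf("Johnson-Neyman region (%s covariance, alpha = %g, df = %d)\n",
              x$vcov, x$alpha, x$df))
  if (nrow(x$boundaries) == 0) {
    verdict <- if (x$significance_at_midrange != 0) "significant everywhere"
               else "significant nowhere"
    cat(sprintf("  no boundaries; conditional effect %s within the data\n", verdict))
  } else {
    for (i in seq_len(nrow(x$boundaries)))
      cat(sprintf("  boundary: %.2f months (%.1f years)%s\n",
                  x$boundaries$months[i], round(x$boundaries$years[i], 1),
                  if (x$boundaries$in_range[i]) "" else " [outside data range]"))
  }
  invisible(x)
}

#' Simple slopes at mean and +/- 1 SD of the moderator
#'
#' Conditional effects of the focal predictor at the moderator's mean and at
#' one SD below/above it, plus exportable fitted-line coordinates with 95%
#' confidence bands for each anchor (the plotting data behind the classic
#' two-line interaction figure).
#'
#' @param fit An `ma_fit`.
#' @param focal Focal term (default: first).
#' @param vcov `"HC0"` (default) or `"classical"`.
#' @param level Confidence level of the bands (default 0.95).
#' @param grid_n Number of focal-axis points per line (default 41, spanning
#'   +/- 2 SD of the standardized focal predictor).
#' @return list with `slopes` (data.frame: `anchor`, `m`, `effect`, `se`,
#'   `t`, `df`, `p`) and `lines` (data.frame: `anchor`, `x`, `fit`, `lwr`,
#'   `upr`) of class `ma_simple_slopes`.
#' @export
simple_slopes <- function(fit, focal = NULL, vcov = c("HC0", "classical"),
                          level = 0.95, grid_n = 41) {
  pr <- jn_parts(fit, focal, vcov)
  mu <- fit$moderator_stats$mean
  sdv <- fit$moderator_stats$sd
  if (!is.finite(sdv) || sdv <= 0)
    stop_named("mrsma_degenerate_error", "moderator SD is zero; anchors collapse")
  anchors <- c(`mean - 1 SD` = mu - sdv, mean = mu, `mean + 1 SD` = mu + sdv)
  ce <- conditional_effect(fit, unname(anchors), pr$focal, pr$vcov)
  slopes <- cbind(anchor = names(anchors), ce, stringsAsFactors = FALSE)

  V <- if (pr$vcov == "HC0") fit$vcov_hc0 else fit$vcov_classical
  b <- stats::setNames(fit$coefficients$beta, fit$coefficients$term)
  terms <- fit$coefficients$term
  tc <- stats::qt(1 - (1 - level) / 2, fit$df_residual)
  xs <- seq(-2, 2, length.out = grid_n)
  lines <- do.call(rbind, lapply(seq_along(anchors), function(i) {
    zm <- mod_to_z(fit, anchors[i])
    g0 <- stats::setNames(numeric(length(terms)), terms)
    g0["(Intercept)"] <- 1
    g0[fit$terms$moderator] <- zm
    fitv <- sev <- numeric(length(xs))
    for (j in seq_along(xs)) {
      g <- g0
      g[pr$focal] <- xs[j]
      g[pr$inter] <- xs[j] * zm
      fitv[j] <- sum(g * b)
      sev[j] <- sqrt(max(0, drop(t(g) %*% V %*% g)))
    }
    data.frame(anchor = names(anchors)[i], x = xs, fit = fitv,
               lwr = fitv - tc * sev, upr = fitv + tc * sev,
               stringsAsFactors = FALSE)
  }))
  structure(list(slopes = slopes, lines = lines, focal = pr$focal,
                 vcov = pr$vcov, level = level),
            class = "ma_simple_slopes")
}

#' @export
print.ma_simple_slopes <- function(x, ...) {
  cat(sprintf("Simple slopes of %s (%s covariance)\n", x$focal, x$vcov))
  print(x$slopes, row.names = FALSE)
  invisible(x)
}
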