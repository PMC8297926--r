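#' Default age bands for the developmental cohort
#'
#' Five non-overlapping age bands spanning primary school to university,
#' expressed in months. Band means/SDs are package choices (only group labels
#' exist in the study design being emulated); draws are truncated normal
#' within `[lower, upper]`.
#'
#' @return A data.frame with columns `label`, `mean_months`, `sd_months`,
#'   `lower`, `upper`.
#' @export
default_age_bands <- function() {
  data.frame(
    label       = c("6y", "10y", "14y", "16y", "18+"),
    mean_months = c(80, 126, 172, 197, 240),
    sd_months   = c(4, 5, 5, 4, 16),
    lower       = c(70, 112, 158, 188, 216),
    upper       = c(90, 140, 186, 206, 300),
    stringsAsFactors = FALSE
  )
}

#' The 13-echo-time acquisition schedule (ms)
#'
#' Echo times used for mono-exponential T2 estimation, from 32 ms to
#' 4,040 ms.
#'
#' @return Numeric vector of 13 echo times in milliseconds.
#' @export
default_te_schedule <- function() {
  c(32, 42, 52, 85, 100, 115, 150, 250, 450, 850, 1650, 3250, 4040)
}

# The four modelled neurochemical measures (metabolite_region keys), in the
# fixed order used throughout the package.
measure_keys <- function() {
  c("Glutamate_IPS", "GABA_IPS", "Glutamate_MFG", "GABA_MFG")
}

# Expand a scalar coefficient to the named 4-measure vector: a scalar is a
# single-measure simulation (applied to Glutamate_IPS, all others zero).
expand_measure_coef <- function(x, name) {
  keys <- measure_keys()
  out <- stats::setNames(numeric(4), keys)
  if (length(x) == 1L && is.null(names(x))) {
    check_scalar(x, name)
    out["Glutamate_IPS"] <- x
    return(out)
  }
  if (is.null(names(x)) || !all(names(x) %in% keys))
    stop_named("mrsma_validation_error",
               "'%s' must be a scalar or a vector named among: %s",
               name, paste(keys, collapse = ", "))
  if (any(!is.finite(x)))
    stop_named("mrsma_validation_error", "'%s' contains non-finite values", name)
  out[names(x)] <- x
  out
}

#' Configuration for the synthetic developmental cohort generator
#'
#' Defines the study conditions the generator emulates: five age bands,
#' 255 participants at Time 1, ~31% attrition at a follow-up ~20.97 (SD 3.83)
#' months later, neurochemical-by-age interactions of opposite sign for
#' glutamate versus GABA in the intraparietal sulcus (IPS), a null GABA-by-age
#' effect in the middle frontal gyrus (MFG), age-dependent residual spread,
#' and a matrix-reasoning score sharing a latent factor with achievement.
#'
#' The achievement latent for timepoint *t* is drawn as
#' \deqn{A = \beta_0 + \beta_{age} z(age) + \sum_m [\beta_{met,m} z_m +
#'   \beta_{int,m} z_m z(age)] + \epsilon,\quad
#'   sd(\epsilon) = base (1 + hetero\_slope\,|z(age)|)}
#' with `base` solved so the latent has unit variance; the standardized
#' generating coefficients are then directly recoverable as standardized
#' regression betas downstream.
#'
#' @param n_per_group Participants per age band (5 bands; default 51, so 255).
#' @param age_bands Data.frame as returned by [default_age_bands()].
#' @param beta0 Intercept of the achievement latent (standardized scale).
#' @param beta_age Standardized age effect on achievement.
#' @param beta_met Main effects of the neurochemical measures: a named vector
#'   over `Glutamate_IPS`, `GABA_IPS`, `Glutamate_MFG`, `GABA_MFG`, or a
#'   scalar for a single-measure simulation (applied to `Glutamate_IPS`).
#' @param beta_int Neurochemical-by-age interaction effects, same convention
#'   as `beta_met`. Defaults carry the developmental sign reversal: positive
#'   glutamate-by-age and negative GABA-by-age in the IPS, weaker positive
#'   glutamate-by-age in the MFG, null MFG GABA-by-age.
#' @param beta_age_t2 Age effect used when drawing the Time-2 achievement
#'   latent (defaults to `beta_age`).
#' @param hetero_slope Unitless scaling of residual SD with `|z(age)|`;
#'   0 gives homoscedastic residuals.
#' @param attrition_rate Fraction lost at Time 2, missing completely at
#'   random, in `[0, 1)`.
#' @param followup_mean_months,followup_sd_months Follow-up gap distribution
#'   (truncated below at 6 months).
#' @param test_retest_r Within-participant Time-1 to Time-2 stability of the
#'   age-independent concentration component (free parameter of the design).
#' @param met_age_r Magnitude of the cross-sectional age association of
#'   concentrations (glutamate decreases, GABA increases with age).
#' @param conc_cv Coefficient of variation of concentrations in institutional
#'   units.
#' @param missing_rate Per-voxel (participant x region x timepoint)
#'   missing-completely-at-random rate: a failed acquisition loses all
#'   metabolites of that voxel together, which is how spectra fail in
#'   practice and what the listwise-deletion df pattern of multi-measure
#'   models implies.
#' @param crlb_shape,crlb_scale Gamma parameters of the CRLB (%) distribution.
#' @param snr_mean,snr_sd Normal parameters of the SNR distribution.
#' @param matrix_loading Loading of matrix reasoning on the achievement
#'   latent.
#' @param t2_true_ms Named vector of true T2 values (ms) per metabolite used
#'   for the group-level multi-TE decay series.
#' @param te_noise_sd Gaussian noise SD of the multi-TE series signals.
#' @param seed Master seed; every table draws from its own stream derived
#'   from it.
#' @return An object of class `mrsma_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_per_group = 51L,
                          age_bands = default_age_bands(),
                          beta0 = 0,
                          beta_age = 0.9,
                          beta_met = c(Glutamate_IPS = 0.05, GABA_IPS = 0.05,
                                       Glutamate_MFG = 0.05, GABA_MFG = 0.05),
                          beta_int = c(Glutamate_IPS = 0.13, GABA_IPS = -0.14,
                                       Glutamate_MFG = 0.11, GABA_MFG = 0),
                          beta_age_t2 = beta_age,
                          hetero_slope = 0.5,
                          attrition_rate = 0.31,
                          followup_mean_months = 20.97,
                          followup_sd_months = 3.83,
                          test_retest_r = 0.9,
                          met_age_r = 0.3,
                          conc_cv = 0.12,
                          missing_rate = 0.06,
                          crlb_shape = 2, crlb_scale = 4,
                          snr_mean = 40, snr_sd = 8,
                          matrix_loading = 0.8,
                          t2_true_ms = c(Glutamate = 180, GABA = 150, Glutamine = 170),
                          te_noise_sd = 1,
                          seed = 1L) {
  check_scalar(n_per_group, "n_per_group", lower = 2)
  if (!is.data.frame(age_bands) ||
      !all(c("label", "mean_months", "sd_months", "lower", "upper") %in% names(age_bands)))
    stop_named("mrsma_validation_error",
               "'age_bands' must be a data.frame like default_age_bands()")
  if (any(diff(age_bands$mean_months) <= 0))
    stop_named("mrsma_validation_error", "age bands must be strictly increasing in mean")
  if (any(age_bands$sd_months <= 0))
    stop_named("mrsma_validation_error", "age band SDs must be positive")
  if (any(utils::head(age_bands$upper, -1) > utils::tail(age_bands$lower, -1)))
    stop_named("mrsma_validation_error", "age bands must not overlap")
  check_scalar(beta0, "beta0")
  check_scalar(beta_age, "beta_age")
  check_scalar(beta_age_t2, "beta_age_t2")
  check_scalar(hetero_slope, "hetero_slope", lower = 0)
  check_scalar(attrition_rate, "attrition_rate", lower = 0, upper = 1,
               allow_equal_upper = FALSE)
  check_scalar(followup_mean_months, "followup_mean_months", lower = 0,
               allow_equal_lower = FALSE)
  check_scalar(followup_sd_months, "followup_sd_months", lower = 0,
               allow_equal_lower = FALSE)
  check_scalar(test_retest_r, "test_retest_r", lower = -1, upper = 1)
  check_scalar(met_age_r, "met_age_r", lower = 0, upper = 0.95)
  check_scalar(conc_cv, "conc_cv", lower = 0, upper = 0.5,
               allow_equal_lower = FALSE)
  check_scalar(missing_rate, "missing_rate", lower = 0, upper = 0.9)
  check_scalar(crlb_shape, "crlb_shape", lower = 0, allow_equal_lower = FALSE)
  check_scalar(crlb_scale, "crlb_scale", lower = 0, allow_equal_lower = FALSE)
  check_scalar(snr_mean, "snr_mean", lower = 0, allow_equal_lower = FALSE)
  check_scalar(snr_sd, "snr_sd", lower = 0, allow_equal_lower = FALSE)
  check_scalar(matrix_loading, "matrix_loading", lower = 0, upper = 1)
  check_scalar(te_noise_sd, "te_noise_sd", lower = 0)
  check_scalar(seed, "seed")
  if (!all(c("Glutamate", "GABA", "Glutamine") %in% names(t2_true_ms)) ||
      any(t2_true_ms <= 0))
    stop_named("mrsma_validation_error",
               "'t2_true_ms' must name positive values for Glutamate, GABA, Glutamine")
  bm <- expand_measure_coef(beta_met, "beta_met")
  bi <- expand_measure_coef(beta_int, "beta_int")
  pop_explained <- max(beta_age, beta_age_t2)^2 + sum(bm^2) +
    sum(bi^2) * (1 + 2 * met_age_r^2)
  if (pop_explained >= 0.95)
    stop_named("mrsma_validation_error",
               "generating coefficients would explain ~%.0f%% of achievement variance; keep below 95%%",
               100 * pop_explained)

  cfg <- list(
    n_per_group = as.integer(n_per_group),
    age_bands = age_bands,
    beta0 = beta0,
    beta_age = beta_age,
    beta_met = expand_measure_coef(beta_met, "beta_met"),
    beta_int = expand_measure_coef(beta_int, "beta_int"),
    beta_age_t2 = beta_age_t2,
    hetero_slope = hetero_slope,
    attrition_rate = attrition_rate,
    followup_mean_months = followup_mean_months,
    followup_sd_months = followup_sd_months,
    test_retest_r = test_retest_r,
    met_age_r = met_age_r,
    conc_cv = conc_cv,
    missing_rate = missing_rate,
    crlb_shape = crlb_shape, crlb_scale = crlb_scale,
    snr_mean = snr_mean, snr_sd = snr_sd,
    matrix_loading = matrix_loading,
    t2_true_ms = t2_true_ms,
    te_noise_sd = te_noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "mrsma_config"
  cfg
}

# Concentration scale (institutional units) and age-association sign per
# metabolite: glutamate declines with age, GABA rises, glutamine is flat.
metabolite_scales <- function() {
  data.frame(
    metabolite = c("Glutamate", "GABA", "Glutamine"),
    mu = c(10.5, 1.8, 3.5),
    age_sign = c(-1, 1, 0),
    stringsAsFactors = FALSE
  )
}

# Tissue-fraction composition factor of MRS-Eq-1 form (internal twin of
# tissue_correct(), used to back-compute the raw "absolute" concentration
# from the generated tissue-level value).
composition_factor <- function(gm, wm, csf) {
  (43300 / 55556 * gm + 35880 / 55556 * wm + 1 * csf) / (1 - csf)
}

#' Generate a synthetic developmental cohort
#'
#' Draws demographics, region-by-metabolite neurochemical measurements with
#' QC fields and voxel tissue fractions, a cognitive battery (two untimed
#' achievement subtests, a timed arithmetic-fluency test, matrix reasoning),
#' group-level multi-TE decay series, and per-spectrum fit cross-correlations
#' for the neurotransmitter pairs. Fixing the seed reproduces every table
#' bit-for-bit; each table has its own pseudo-random stream.
#'
#' The "absolute" concentration stored in the metabolite table is the
#' tissue-level concentration divided by the voxel composition factor, so the
#' tissue correction recovers the generating quantity exactly.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `mrsma_cohort`: a list with data.frames
#'   `demographics`, `metabolites`, `cognitive`, `te_series`,
#'   `fit_correlations`, plus `truth` (generating parameters and derived
#'   scalars) and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_per_group = 10, seed = 7))
#' head(coh$demographics)
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "mrsma_config"))
    stop_named("mrsma_validation_error", "'config' must come from cohort_config()")
  cfg <- config
  bands <- cfg$age_bands
  n_band <- cfg$n_per_group
  n <- n_band * nrow(bands)
  ids <- sprintf("P%04d", seq_len(n))

  ## --- demographics stream ---------------------------------------------
  demo <- with_stream(cfg$seed, 1L, {
    age_t1 <- unlist(lapply(seq_len(nrow(bands)), function(i) {
      rtruncnorm_icdf(n_band, bands$mean_months[i], bands$sd_months[i],
                      bands$lower[i], bands$upper[i])
    }))
    gender <- ifelse(stats::runif(n) < 0.5, "F", "M")
    present <- stats::runif(n) >= cfg$attrition_rate
    gap <- rtruncnorm_icdf(n, cfg$followup_mean_months, cfg$followup_sd_months,
                           lower = 6)
    data.frame(
      id = ids,
      gender = gender,
      age_group = rep(bands$label, each = n_band),
      age_months_t1 = age_t1,
      age_months_t2 = ifelse(present, age_t1 + gap, NA_real_),
      present_at_t2 = present,
      stringsAsFactors = FALSE
    )
  })

  z_age_t1 <- zscore(demo$age_months_t1, "age_months_t1")
  retained <- which(demo$present_at_t2)
  z_age_t2 <- rep(NA_real_, n)
  if (length(retained) >= 2)
    z_age_t2[retained] <- zscore(demo$age_months_t2[retained], "age_months_t2")

  scales <- metabolite_scales()
  regions <- c("IPS", "MFG")
  combos <- expand.grid(metabolite = scales$metabolite, region = regions,
                        stringsAsFactors = FALSE)

  ## --- concentration stream --------------------------------------------
  conc <- with_stream(cfg$seed, 2L, {
    r <- cfg$met_age_r
    rho <- cfg$test_retest_r
    z1 <- z2 <- matrix(NA_real_, n, nrow(combos),
                       dimnames = list(NULL, paste(combos$metabolite, combos$region, sep = "_")))
    for (k in seq_len(nrow(combos))) {
      s <- scales$age_sign[match(combos$metabolite[k], scales$metabolite)]
      u1 <- stats::rnorm(n)
      u2 <- stats::rnorm(n)
      z1[, k] <- s * r * z_age_t1 + sqrt(1 - r^2) * u1
      stable <- rho * u1 + sqrt(1 - rho^2) * u2
      z2[retained, k] <- (s * r * z_age_t2 + sqrt(1 - r^2) * stable)[retained]
    }
    list(z1 = z1, z2 = z2)
  })

  ## --- achievement latent stream ---------------------------------------
  keys <- measure_keys()
  systematic <- function(zc, za, beta_age) {
    sys <- cfg$beta0 + beta_age * za
    for (k in keys)
      sys <- sys + cfg$beta_met[k] * zc[, k] + cfg$beta_int[k] * zc[, k] * za
    sys
  }
  solve_base <- function(sys, za) {
    # sample variance of the systematic part fluctuates around its population
    # value; cap the explained share so sampling noise cannot zero the residual
    v <- min(stats::var(sys), 0.97)
    sqrt((1 - v) / mean((1 + cfg$hetero_slope * abs(za))^2))
  }
  lat <- with_stream(cfg$seed, 3L, {
    sys1 <- systematic(conc$z1, z_age_t1, cfg$beta_age)
    base1 <- solve_base(sys1, z_age_t1)
    A1 <- sys1 + base1 * (1 + cfg$hetero_slope * abs(z_age_t1)) * stats::rnorm(n)
    A2 <- rep(NA_real_, n)
    base2 <- NA_real_
    if (length(retained) >= 8) {
      sys2 <- systematic(conc$z2[retained, , drop = FALSE], z_age_t2[retained],
                         cfg$beta_age_t2)
      base2 <- solve_base(sys2, z_age_t2[retained])
      A2[retained] <- sys2 + base2 *
        (1 + cfg$hetero_slope * abs(z_age_t2[retained])) *
        stats::rnorm(length(retained))
    }
    list(A1 = A1, A2 = A2, base1 = base1, base2 = base2)
  })

  ## --- metabolite table stream (units, fractions, QC fields, missing) ---
  metab <- with_stream(cfg$seed, 4L, {
    rows <- vector("list", 0L)
    for (tp in 1:2) {
      idx <- if (tp == 1) seq_len(n) else retained
      if (length(idx) == 0) next
      zmat <- if (tp == 1) conc$z1 else conc$z2
      for (k in seq_len(nrow(combos))) {
        met <- combos$metabolite[k]; reg <- combos$region[k]
        mu <- scales$mu[match(met, scales$metabolite)]
        tissue_conc <- pmax(mu * (1 + cfg$conc_cv * zmat[idx, k]), 0.05 * mu)
        # Dirichlet voxel composition (region-specific tissue mix)
        alpha <- if (reg == "IPS") c(55, 35, 10) else c(60, 30, 10)
        g <- cbind(stats::rgamma(length(idx), alpha[1]),
                   stats::rgamma(length(idx), alpha[2]),
                   stats::rgamma(length(idx), alpha[3]))
        frac <- g / rowSums(g)
        fac <- composition_factor(frac[, 1], frac[, 2], frac[, 3])
        rows[[length(rows) + 1L]] <- data.frame(
          id = ids[idx],
          timepoint = tp,
          region = reg,
          metabolite = met,
          absolute_concentration = tissue_conc / fac,
          crlb_percent = stats::rgamma(length(idx), shape = cfg$crlb_shape,
                                       scale = cfg$crlb_scale),
          snr = stats::rnorm(length(idx), cfg$snr_mean, cfg$snr_sd),
          gm_fraction = frac[, 1],
          wm_fraction = frac[, 2],
          csf_fraction = frac[, 3],
          te_ms = 32,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    # voxel-level missingness: one acquisition per id x region x timepoint
    voxels <- unique(out[c("id", "region", "timepoint")])
    voxels$keep <- stats::runif(nrow(voxels)) >= cfg$missing_rate
    key <- function(d) paste(d$id, d$region, d$timepoint)
    out[voxels$keep[match(key(out), key(voxels))], , drop = FALSE]
  })
  rownames(metab) <- NULL

  ## --- cognitive battery stream ----------------------------------------
  # Raw scores are affine in the latent over the realistic range with
  # additive score noise; clipping bounds sit beyond ~2.5 latent SDs. Affine
  # maps keep the observed composite's residual spread level-independent, so
  # hetero_slope = 0 really produces a homoscedastic cohort.
  cog <- with_stream(cfg$seed, 5L, {
    lam <- cfg$matrix_loading
    clip_int <- function(x, lo, hi) as.integer(round(pmin(hi, pmax(lo, x))))
    one_tp <- function(tp) {
      idx <- if (tp == 1) seq_len(n) else retained
      if (length(idx) == 0) return(NULL)
      k <- length(idx)
      A <- if (tp == 1) lat$A1[idx] else lat$A2[idx]
      m_lat <- lam * A + sqrt(1 - lam^2) * stats::rnorm(k)
      data.frame(
        id = ids[idx],
        timepoint = tp,
        numops_correct = clip_int(20 + 6 * A + stats::rnorm(k, 0, 1.5), 0, 40),
        numops_attempted = 40L,
        reasoning_correct = clip_int(25 + 7 * A + stats::rnorm(k, 0, 2), 0, 50),
        reasoning_attempted = 50L,
        # both timed columns are attempted in full and ability shows mainly
        # in the correct count: constant attempted keeps the proportion's
        # noise level-independent, and a nearly flat solving time keeps the
        # efficiency score affine in the latent (no curvature artefacts)
        tempo_correct = clip_int(40 + 12 * A + stats::rnorm(k, 0, 2), 0, 80),
        tempo_attempted = 80L,
        tempo_time_s = round(pmin(300, pmax(60, 180 - 4 * A + stats::rnorm(k, 0, 2))), 1),
        matrix_raw = clip_int(17 + 6 * m_lat + stats::rnorm(k, 0, 1), 0, 35),
        stringsAsFactors = FALSE
      )
    }
    rbind(one_tp(1), one_tp(2))
  })
  rownames(cog) <- NULL

  ## --- group-level multi-TE decay series stream -------------------------
  te <- with_stream(cfg$seed, 6L, {
    rows <- lapply(seq_len(nrow(combos)), function(k) {
      met <- combos$metabolite[k]
      ser <- generate_multi_te_series(
        t2_ms = cfg$t2_true_ms[[met]],
        s0 = 100,
        noise_sd = cfg$te_noise_sd,
        seed = NULL
      )
      cbind(region = combos$region[k], metabolite = met, ser,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(te) <- NULL

  ## --- per-spectrum fit cross-correlations stream -----------------------
  fitcor <- with_stream(cfg$seed, 7L, {
    pairs <- c("Glutamate-Glutamine", "Glutamate-GABA")
    grid <- expand.grid(id = ids, region = regions, pair = pairs,
                        stringsAsFactors = FALSE)
    grid$correlation <- pmin(0.95, pmax(-0.95, stats::rnorm(nrow(grid), 0.28, 0.08)))
    grid
  })

  truth <- list(
    beta0 = cfg$beta0, beta_age = cfg$beta_age, beta_age_t2 = cfg$beta_age_t2,
    beta_met = as.list(cfg$beta_met), beta_int = as.list(cfg$beta_int),
    hetero_slope = cfg$hetero_slope,
    base_sd_t1 = lat$base1, base_sd_t2 = lat$base2,
    latent_sd_t1 = stats::sd(lat$A1),
    latent_sd_t2 = if (length(retained) >= 8) stats::sd(lat$A2[retained]) else NA_real_,
    latent_t1 = lat$A1, latent_t2 = lat$A2,
    t2_true_ms = as.list(cfg$t2_true_ms),
    n_t1 = n, n_t2 = length(retained)
  )

  structure(list(demographics = demo, metabolites = metab, cognitive = cog,
                 te_series = te, fit_correlations = fitcor,
                 truth = truth, config = cfg),
            class = "mrsma_cohort")
}

#' @export
print.mrsma_cohort <- function(x, ...) {
  cat("Synthetic developmental cohort\n")
  cat(sprintf("  participants: %d at Time 1, %d retained at Time 2\n",
              x$truth$n_t1, x$truth$n_t2))
  cat(sprintf("  metabolite records: %d; cognitive rows: %d\n",
              nrow(x$metabolites), nrow(x$cognitive)))
  cat(sprintf("  seed: %d\n", x$config$seed))
  invisible(x)
}

#' Simulate a multi-echo-time signal decay series
#'
#' Mono-exponential transverse relaxation: `signal(TE) = s0 * exp(-TE/T2)`
#' plus Gaussian noise, at the 13 default echo times (32 to 4,040 ms).
#'
#' @param t2_ms True T2 relaxation time in ms (must be positive).
#' @param s0 Signal at TE = 0, in arbitrary signal units.
#' @param te_list Echo times in ms; defaults to [default_te_schedule()].
#' @param noise_sd Gaussian noise SD in signal units.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return data.frame with columns `te_ms`, `signal`.
#' @examples
#' generate_multi_te_series(150, s0 = 100, noise_sd = 0)
#' @export
generate_multi_te_series <- function(t2_ms, s0 = 100,
                                     te_list = default_te_schedule(),
                                     noise_sd = 0, seed = NULL) {
  check_scalar(t2_ms, "t2_ms", lower = 0, allow_equal_lower = FALSE)
  check_scalar(s0, "s0")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (length(te_list) == 0 || any(!is.finite(te_list)) || any(te_list < 0))
    stop_named("mrsma_validation_error", "'te_list' must be non-empty, finite, non-negative")
  draw <- function() {
    data.frame(te_ms = as.numeric(te_list),
               signal = s0 * exp(-te_list / t2_ms) +
                 stats::rnorm(length(te_list), 0, noise_sd))
  }
  if (is.null(seed)) draw() else with_stream(seed, 0L, draw())
}

#' Write cohort tables to a directory as delimited text
#'
#' Writes `demographics.csv`, `metabolites.csv`, `cognitive.csv`,
#' `te_series.csv`, `fit_correlations.csv` and a `truth.json` sidecar holding
#' the generating parameters (scalar entries only).
#'
#' @param cohort An `mrsma_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mrsma_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("demographics", "metabolites", "cognitive", "te_series",
            "fit_correlations")
  paths <- character(0)
  for (tb in tabs) {
    p <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(cohort[[tb]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  truth <- cohort$truth
  truth$latent_t1 <- NULL
  truth$latent_t2 <- NULL
  p <- file.path(dir, "truth.json")
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA, pretty = TRUE), p)
  invisible(c(paths, p))
}

#' Read cohort tables previously written by [write_cohort()]
#'
#' @param dir Directory containing the cohort CSV files.
#' @return An `mrsma_cohort` (without generating `truth`/`config` unless the
#'   `truth.json` sidecar is present).
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  need <- c("demographics.csv", "metabolites.csv", "cognitive.csv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop_named("mrsma_io_error", "missing cohort tables in '%s': %s",
               dir, paste(miss, collapse = ", "))
  out <- list(
    demographics = rd("demographics.csv"),
    metabolites = rd("metabolites.csv"),
    cognitive = rd("cognitive.csv"),
    te_series = if (file.exists(file.path(dir, "te_series.csv"))) rd("te_series.csv"),
    fit_correlations = if (file.exists(file.path(dir, "fit_correlations.csv")))
      rd("fit_correlations.csv"),
    truth = if (file.exists(file.path(dir, "truth.json")))
      jsonlite::fromJSON(file.path(dir, "truth.json")),
    config = NULL
  )
  out$demographics$present_at_t2 <- as.logical(out$demographics$present_at_t2)
  structure(out, class = "mrsma_cohort")
}
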