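#' Build the participant-level analysis frame
#'
#' Applies quality control and concentration correction to the metabolite
#' table, computes the composite achievement and matrix-reasoning scores,
#' and merges everything into one wide row per participant: ages, gender,
#' MA composites, matrix scores, and one column per
#' metabolite-region-timepoint corrected concentration
#' (e.g. `Glutamate_IPS_t1`).
#'
#' @param cohort An `mrsma_cohort` (generated or read from disk).
#' @param correction `"tissue"` (voxel-fraction correction only, the primary
#'   quantification) or `"tissue_t2"` (additionally apply the T2 relaxation
#'   adjustment using group-level T2 values estimated from the cohort's
#'   multi-TE series, one per region x metabolite).
#' @param t2_convention Passed to [t2_correct()].
#' @param qc Apply [apply_qc()] exclusions (default `TRUE`).
#' @param crlb_max,sd_k QC thresholds.
#' @return A data.frame of class `ma_frame` with attributes `qc_report`
#'   (excluded records and reasons), `t2_estimates` (when used), and
#'   `gate` (the cross-correlation gate report, when fit correlations are
#'   available).
#' @export
analysis_frame <- function(cohort, correction = c("tissue", "tissue_t2"),
                           t2_convention = "as_published", qc = TRUE,
                           crlb_max = 50, sd_k = 3) {
  stopifnot(inherits(cohort, "mrsma_cohort"))
  correction <- match.arg(correction)
  if (is.null(cohort$cognitive) || nrow(cohort$cognitive) == 0)
    stop_named("mrsma_stage_error",
               "scoring stage failed: cognitive table is missing or empty")
  metab <- cohort$metabolites
  metab$age_group <- cohort$demographics$age_group[
    match(metab$id, cohort$demographics$id)]

  qc_report <- NULL
  if (qc) {
    metab <- apply_qc(metab, crlb_max = crlb_max, sd_k = sd_k)
    qc_report <- metab[!metab$retained,
                       c("id", "timepoint", "region", "metabolite",
                         "crlb_percent", "snr", "absolute_concentration",
                         "qc_reasons")]
    rownames(qc_report) <- NULL
    metab <- metab[metab$retained, , drop = FALSE]
  }

  metab$concentration <- tissue_correct(
    metab$absolute_concentration, metab$gm_fraction, metab$wm_fraction,
    metab$csf_fraction)

  t2_est <- NULL
  if (correction == "tissue_t2") {
    if (is.null(cohort$te_series))
      stop_named("mrsma_stage_error",
                 "T2 correction requested but the cohort has no multi-TE series")
    ser <- cohort$te_series
    keys <- unique(ser[c("region", "metabolite")])
    keys$t2_ms <- vapply(seq_len(nrow(keys)), function(i) {
      s <- ser[ser$region == keys$region[i] & ser$metabolite == keys$metabolite[i], ]
      fit_t2(s$te_ms, s$signal)$t2_ms
    }, numeric(1))
    t2_est <- keys
    idx <- match(paste(metab$region, metab$metabolite),
                 paste(keys$region, keys$metabolite))
    if (anyNA(idx))
      stop_named("mrsma_stage_error",
                 "no T2 series for some region x metabolite combinations")
    metab$concentration <- t2_correct(metab$concentration, metab$te_ms,
                                      keys$t2_ms[idx],
                                      convention = t2_convention)
  }

  scores <- composite_ma(cohort$cognitive)
  demo <- cohort$demographics
  out <- demo[c("id", "gender", "age_group", "age_months_t1",
                "age_months_t2", "present_at_t2")]
  for (tp in 1:2) {
    sc <- scores[scores$timepoint == tp, ]
    out[[paste0("ma_t", tp)]] <- sc$ma_composite[match(out$id, sc$id)]
    if ("matrix_raw" %in% names(sc))
      out[[paste0("matrix_t", tp)]] <- sc$matrix_raw[match(out$id, sc$id)]
  }
  for (tp in 1:2) {
    sub <- metab[metab$timepoint == tp, ]
    for (key in unique(paste(sub$metabolite, sub$region, sep = "_"))) {
      parts <- strsplit(key, "_")[[1]]
      s2 <- sub[sub$metabolite == parts[1] & sub$region == parts[2], ]
      out[[paste0(key, "_t", tp)]] <- s2$concentration[match(out$id, s2$id)]
    }
  }
  attr(out, "qc_report") <- qc_report
  attr(out, "t2_estimates") <- t2_est
  if (!is.null(cohort$fit_correlations))
    attr(out, "gate") <- cross_correlation_gate(cohort$fit_correlations)
  class(out) <- c("ma_frame", "data.frame")
  out
}

# Build the model-spec list of the standard analysis battery.
battery_specs <- function(include = c("main", "matrix", "gender",
                                      "specificity", "prediction")) {
  specs <- list()
  add <- function(s) specs[[length(specs) + 1L]] <<- s
  mets <- c("Glutamate", "GABA")
  regs <- c("IPS", "MFG")
  if ("main" %in% include) {
    for (tp in 1:2) for (reg in regs) for (met in mets)
      add(model_spec(paste0("ma_t", tp), paste0(met, "_", reg, "_t", tp),
                     paste0("age_months_t", tp),
                     label = sprintf("T%d %s %s", tp, reg, met)))
  }
  if ("matrix" %in% include) {
    for (tp in 1:2) for (reg in regs) for (met in mets)
      add(covariate_variant(
        model_spec(paste0("ma_t", tp), paste0(met, "_", reg, "_t", tp),
                   paste0("age_months_t", tp),
                   label = sprintf("T%d %s %s", tp, reg, met)),
        "matrix_reasoning"))
  }
  if ("gender" %in% include) {
    for (tp in 1:2) for (reg in regs) for (met in mets)
      add(covariate_variant(
        model_spec(paste0("ma_t", tp), paste0(met, "_", reg, "_t", tp),
                   paste0("age_months_t", tp),
                   label = sprintf("T%d %s %s", tp, reg, met)),
        "gender"))
  }
  if ("specificity" %in% include) {
    for (tp in 1:2)
      add(model_spec(paste0("ma_t", tp), paste0(measure_keys(), "_t", tp),
                     paste0("age_months_t", tp),
                     label = sprintf("specificity T%d", tp)))
  }
  if ("prediction" %in% include) {
    for (reg in regs) for (met in mets)
      add(model_spec("ma_t2", paste0(met, "_", reg, "_t1"), "age_months_t1",
                     covariates = "age_months_t2",
                     label = sprintf("prediction %s %s", reg, met),
                     vif_exempt = "age_months_t2"))
    add(model_spec("ma_t2", paste0(measure_keys(), "_t1"), "age_months_t1",
                   covariates = "age_months_t2",
                   label = "prediction specificity",
                   vif_exempt = "age_months_t2"))
  }
  specs
}

#' Run the standard analysis battery
#'
#' Fits the full model sequence on an analysis frame: the eight main
#' age-moderation models (2 regions x 2 metabolites x 2 timepoints), their
#' matrix-reasoning- and gender-adjusted variants, the four-measure
#' specificity models at both timepoints, and the prediction models (Time-2
#' MA from Time-1 measures with the Time-2 age covariate) including the
#' prediction specificity model. Models that cannot be fitted (insufficient
#' cases, aliasing) are recorded as failed rows, never silently dropped.
#'
#' Johnson-Neyman regions are emitted for every focal term of every fitted
#' model under both the HC0 and the classical covariance.
#'
#' @param frame An `ma_frame` (or plain data.frame with the same columns).
#' @param alpha Significance level used in reports.
#' @param include Battery components to run.
#' @param jn Emit Johnson-Neyman and simple-slopes tables (default `TRUE`).
#' @return An object of class `ma_results_bundle`: list with `fits`
#'   (named list of `ma_fit` or error messages), `results` (tidy per-term
#'   table), `diagnostics`, `jn`, `plot_data`, `failed`, `alpha`.
#' @export
standard_battery <- function(frame, alpha = 0.05,
                             include = c("main", "matrix", "gender",
                                         "specificity", "prediction"),
                             jn = TRUE) {
  if (!all(c("ma_t1", "age_months_t1") %in% names(frame)))
    stop_named("mrsma_stage_error",
               "fitting stage failed: frame lacks achievement/age columns")
  specs <- battery_specs(include)
  has_t2 <- "ma_t2" %in% names(frame) && sum(!is.na(frame$ma_t2)) >= 8
  fits <- list(); results <- list(); diags <- list()
  jn_rows <- list(); plots <- list(); failed <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    mid <- sprintf("m%02d", i)
    if (!has_t2 && (grepl("_t2$", sp$outcome) || grepl("_t2$", sp$moderator))) {
      failed[[mid]] <- data.frame(model_id = mid, model = sp$label,
                                  error = "skipped: no Time-2 data",
                                  stringsAsFactors = FALSE)
      next
    }
    ft <- tryCatch(fit_moderation(frame, sp), error = function(e) e)
    if (inherits(ft, "error")) {
      failed[[mid]] <- data.frame(model_id = mid, model = sp$label,
                                  error = conditionMessage(ft),
                                  stringsAsFactors = FALSE)
      diags[[mid]] <- data.frame(model_id = mid, model = sp$label, n = NA,
                                 bp_stat = NA, bp_df = NA, bp_p = NA,
                                 bp_stat_classic = NA, bp_p_classic = NA,
                                 sw_W = NA, sw_p = NA, max_vif = NA,
                                 max_vif_term = NA, vif_exempt = NA,
                                 stringsAsFactors = FALSE)
      next
    }
    fits[[mid]] <- ft
    tab <- coef_table(ft)
    tab$model_id <- mid
    results[[mid]] <- tab
    dg <- diagnostics_report(ft)
    dg <- cbind(model_id = mid, as.data.frame(dg), stringsAsFactors = FALSE)
    diags[[mid]] <- dg
    if (jn) {
      for (fc in ft$terms$focal) for (vc in c("HC0", "classical")) {
        jr <- jn_boundaries(ft, alpha = alpha, focal = fc, vcov = vc)
        jn_rows[[length(jn_rows) + 1L]] <- data.frame(
          model_id = mid, model = sp$label, focal = fc, vcov = vc,
          jnt_lower_months = jr$lower_months,
          jnt_lower_years = round(jr$lower_months / 12, 1),
          jnt_upper_months = jr$upper_months,
          jnt_upper_years = round(jr$upper_months / 12, 1),
          sig_below = jr$significant_below,
          sig_between = jr$significant_between,
          sig_above = jr$significant_above,
          stringsAsFactors = FALSE)
      }
      if (length(ft$terms$focal) == 1) {
        ss <- simple_slopes(ft)
        pl <- ss$lines
        pl$model_id <- mid; pl$model <- sp$label
        plots[[length(plots) + 1L]] <- pl
      }
    }
  }
  bundle <- list(
    fits = fits,
    results = if (length(results)) do.call(rbind, c(results, make.row.names = FALSE)) else NULL,
    diagnostics = if (length(diags)) do.call(rbind, c(diags, make.row.names = FALSE)) else NULL,
    jn = if (length(jn_rows)) do.call(rbind, c(jn_rows, make.row.names = FALSE)) else NULL,
    plot_data = if (length(plots)) do.call(rbind, c(plots, make.row.names = FALSE)) else NULL,
    failed = if (length(failed)) do.call(rbind, c(failed, make.row.names = FALSE)) else NULL,
    alpha = alpha
  )
  class(bundle) <- "ma_results_bundle"
  bundle
}

#' @export
print.ma_results_bundle <- function(x, ...) {
  cat(sprintf("Analysis battery: %d fitted models, %d failed/skipped\n",
              length(x$fits), if (is.null(x$failed)) 0L else nrow(x$failed)))
  if (!is.null(x$results)) {
    keep <- grepl("_x_", x$results$term)
    cat("Interaction terms:\n")
    print(x$results[keep, c("model", "term", "beta", "se_hc0", "t", "df", "p_hc0")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Construct a run manifest
#'
#' A manifest fully determines a pipeline run: the seed (funnelling every
#' source of randomness), generator configuration overrides, correction
#' mode, significance level, battery components, and output directory.
#' Re-running an identical manifest reproduces byte-identical result tables.
#'
#' @param seed Integer master seed.
#' @param correction `"tissue"` or `"tissue_t2"`.
#' @param alpha Significance level.
#' @param battery Battery components (see [standard_battery()]).
#' @param outdir Output directory, or `NULL` to skip writing.
#' @param input_dir Read cohort tables from this directory instead of
#'   generating (the generator is then disabled).
#' @param config Named list of [cohort_config()] overrides.
#' @return An object of class `mrsma_manifest`.
#' @export
run_manifest <- function(seed = 1L, correction = c("tissue", "tissue_t2"),
                         alpha = 0.05,
                         battery = c("main", "matrix", "gender",
                                     "specificity", "prediction"),
                         outdir = NULL, input_dir = NULL, config = list()) {
  correction <- match.arg(correction)
  core <- list(seed = as.integer(seed), correction = correction,
               alpha = alpha, battery = battery,
               generator = is.null(input_dir), config = config)
  js <- jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  writeLines(js, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  structure(c(core, list(outdir = outdir, input_dir = input_dir,
                         config_hash = hash,
                         version = as.character(utils::packageVersion("mrsma")))),
            class = "mrsma_manifest")
}

#' Run the full pipeline from a manifest
#'
#' Generate (or load) the cohort, apply QC and concentration correction,
#' score the cognitive battery, fit the standard model battery, probe
#' interactions, run diagnostics, and optionally write the results bundle.
#' The pipeline is a pure function of the manifest and input files.
#'
#' @param manifest An [run_manifest()] object.
#' @return The `ma_results_bundle`, with `cohort` and `frame` attached.
#' @export
run_pipeline <- function(manifest) {
  stopifnot(inherits(manifest, "mrsma_manifest"))
  cohort <- if (manifest$generator) {
    cfg <- do.call(cohort_config, c(list(seed = manifest$seed), manifest$config))
    generate_cohort(cfg)
  } else {
    read_cohort(manifest$input_dir)
  }
  frame <- analysis_frame(cohort, correction = manifest$correction)
  bundle <- standard_battery(frame, alpha = manifest$alpha,
                             include = manifest$battery)
  bundle$cohort <- cohort
  bundle$frame <- frame
  bundle$manifest <- manifest
  if (!is.null(manifest$outdir)) write_bundle(bundle, manifest$outdir)
  bundle
}

#' Write a results bundle to a directory
#'
#' Writes the cohort tables, the QC exclusion report, the analysis frame,
#' the tidy model results, the Johnson-Neyman table, diagnostics, plotting
#' data, the manifest, and a deterministic run log (no timestamps, so
#' repeated identical runs are byte-identical).
#'
#' @param bundle An `ma_results_bundle` from [run_pipeline()] or
#'   [standard_battery()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$cohort))
    paths <- c(paths, write_cohort(bundle$cohort, file.path(dir, "cohort")))
  if (!is.null(bundle$frame)) {
    wr(as.data.frame(bundle$frame), "analysis_frame.csv")
    wr(attr(bundle$frame, "qc_report"), "qc_report.csv")
    wr(attr(bundle$frame, "t2_estimates"), "t2_estimates.csv")
    wr(attr(bundle$frame, "gate"), "cross_correlation_gate.csv")
  }
  wr(bundle$results, "model_results.csv")
  wr(bundle$diagnostics, "diagnostics.csv")
  wr(bundle$jn, "jn_regions.csv")
  wr(bundle$plot_data, "plot_data.csv")
  wr(bundle$failed, "failed_models.csv")
  if (!is.null(bundle$manifest)) {
    # location fields are not part of the reproducible record
    m <- unclass(bundle$manifest)
    m$outdir <- NULL
    m$input_dir <- NULL
    p <- file.path(dir, "manifest.json")
    writeLines(jsonlite::toJSON(m, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"), p)
    paths <- c(paths, p)
  }
  log <- c(
    "mrsma pipeline run log",
    sprintf("models fitted: %d", length(bundle$fits)),
    sprintf("models failed or skipped: %d",
            if (is.null(bundle$failed)) 0L else nrow(bundle$failed)),
    if (!is.null(bundle$frame)) sprintf(
      "QC exclusions: %d",
      if (is.null(attr(bundle$frame, "qc_report"))) 0L
      else nrow(attr(bundle$frame, "qc_report"))),
    if (!is.null(bundle$results))
      sprintf("per-model n: %s",
              paste(vapply(bundle$fits, function(f) f$n, numeric(1)),
                    collapse = ","))
  )
  p <- file.path(dir, "run_log.txt")
  writeLines(log, p)
  invisible(c(paths, p))
}
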