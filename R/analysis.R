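#' Spearman correlation matrix between QC metrics
#'
#' Pairwise-complete Spearman correlations between the declared QC
#' metric columns. Direction metadata is attached so signs can be
#' interpreted; for display, correlations involving a higher-is-better
#' metric are conventionally shown as absolute values.
#'
#' @param cohort A [cohort_table].
#' @param metrics List of [qc_metric]s (or column names).
#' @return List: `rho` (symmetric matrix, `NA` for constant columns),
#'   `directions` (named vector), `display_abs` (logical matrix of
#'   cells involving a higher-is-better metric).
#' @export
metric_correlation_matrix <- function(cohort, metrics) {
  metrics <- lapply(metrics, as_qc_metric)
  nm <- vapply(metrics, function(m) m$name, character(1))
  if (length(nm) < 2L) stop("need at least 2 metrics", call. = FALSE)
  k <- length(nm)
  rho <- diag(1, k); dimnames(rho) <- list(nm, nm)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    x <- cohort[[nm[i]]]; y <- cohort[[nm[j]]]
    ok <- is.finite(x) & is.finite(y)
    rho[i, j] <- rho[j, i] <-
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        NA_real_
      else spearman_rho(x[ok], y[ok])$rho
  }
  dirs <- vapply(metrics, function(m) m$direction, character(1))
  names(dirs) <- nm
  better <- dirs == "higher_better"
  list(rho = rho, directions = dirs,
       display_abs = outer(better, better, "|"))
}

#' Demographic model of a quality metric
#'
#' Mixed model of the metric on age, age squared (centered), sex and
#' diagnosis, with a site random intercept. Cohen's d is derived from
#' the model t for the binary sex and diagnosis terms.
#'
#' @param cohort A [cohort_table].
#' @param metric A [qc_metric] or column name.
#' @param etiv Optional column name of estimated total intracranial
#'   volume to add as a covariate.
#' @return Data frame: term, estimate, se, t, p, cohens_d (binary terms
#'   only), plus attributes `n_used` and `singular`.
#' @export
demographic_quality_model <- function(cohort, metric, etiv = NULL) {
  metric <- as_qc_metric(metric)
  d <- prepare_model_data(cohort)
  fixed <- c("age_c", "age_c2", "sex", "diagnosis")
  if (!is.null(etiv)) fixed <- c(fixed, etiv)
  fit <- fit_lmm(d, metric$name, fixed)
  out <- fit$coefficients
  out$cohens_d <- NA_real_
  for (term in c("sex", "diagnosis")) {
    i <- match(term, out$term)
    if (is.na(i)) next
    g <- fit$data[[term]]
    out$cohens_d[i] <- cohens_d_from_t(out$t[i], sum(g == 0),
                                       sum(g != 0), fit$df_resid)
  }
  attr(out, "n_used") <- fit$n_used
  attr(out, "singular") <- fit$singular
  out
}

#' Quality correlations with global brain measures
#'
#' Spearman correlation of the metric with each global measure,
#' flagged at a Bonferroni-corrected level of `0.05 / n_measures`.
#'
#' @param cohort A [cohort_table].
#' @param metric A [qc_metric] or column name.
#' @param globals Column names of the global measures (default the six
#'   standard ones: cGMV, sGMV, TBV, WMV, ventricles, meanCT).
#' @return List: `results` (measure, rho, p, n, significant),
#'   `skipped` (absent columns), `bonferroni_level`.
#' @export
global_quality_correlations <- function(cohort, metric,
                                        globals = c("cGMV", "sGMV", "TBV",
                                                    "WMV", "ventricles",
                                                    "meanCT")) {
  metric <- as_qc_metric(metric)
  present <- intersect(globals, names(cohort))
  skipped <- setdiff(globals, present)
  level <- 0.05 / length(globals)
  rows <- lapply(present, function(g) {
    sr <- spearman_rho(cohort[[metric$name]], cohort[[g]])
    data.frame(measure = g, rho = sr$rho, p = sr$p, n = sr$n,
               significant = sr$p < level, stringsAsFactors = FALSE)
  })
  list(results = do.call(rbind, rows), skipped = skipped,
       bonferroni_level = level)
}

#' Regional quality-morphometry association map
#'
#' For every region of the phenotype, fits a mixed model of the region
#' value on the quality metric, age, age squared and sex (site random
#' intercept), converts the metric's t into a partial correlation, and
#' corrects across regions with the false discovery rate. For
#' higher-is-better metrics the partial correlation (and its t) are
#' negated so that positive always reads "worse quality, larger value".
#'
#' @param cohort A [cohort_table].
#' @param metric A [qc_metric] or column name.
#' @param phenotype Phenotype key registered in the cohort (e.g. "CT").
#' @param fdr_level FDR level across regions, default 0.05.
#' @param min_n Minimum complete rows per region.
#' @return Data frame of class `regional_effects`: region, phenotype,
#'   partial_r, t, df, p, q, significant, n_used; skipped regions are
#'   recorded in attribute `skipped`.
#' @export
regional_quality_associations <- function(cohort, metric, phenotype = "CT",
                                          fdr_level = 0.05, min_n = 10L) {
  metric <- as_qc_metric(metric)
  regions <- region_columns(cohort, phenotype)
  d <- prepare_model_data(cohort)
  flip <- if (metric$direction == "higher_better") -1 else 1
  rows <- list(); skipped <- character()
  for (rg in regions) {
    fit <- tryCatch(
      fit_lmm(d, rg, c(metric$name, "age_c", "age_c2", "sex"),
              min_n = min_n),
      error = function(e) e)
    if (inherits(fit, "error")) { skipped <- c(skipped, rg); next }
    cr <- coef_row(fit, metric$name)
    tt <- flip * cr$t
    rows[[rg]] <- data.frame(
      region = rg, phenotype = phenotype,
      partial_r = partial_r_from_t(tt, fit$df_resid), t = tt,
      df = fit$df_resid, p = cr$p, n_used = fit$n_used,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no region could be fitted for phenotype ", phenotype,
         call. = FALSE)
  out <- do.call(rbind, rows)
  fdr <- fdr_bh(out$p, fdr_level)
  out$q <- fdr$q
  out$significant <- fdr$significant
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "metric") <- metric$name
  class(out) <- c("regional_effects", "data.frame")
  out
}

#' Export thresholded and unthresholded regional maps
#'
#' Writes the full per-region table and a copy restricted to regions
#' surviving FDR, as CSV.
#'
#' @param effects A `regional_effects` data frame.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @export
export_regional_maps <- function(effects, dir, prefix = "map") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  full <- file.path(dir, paste0(prefix, "_unthresholded.csv"))
  thr <- file.path(dir, paste0(prefix, "_significant.csv"))
  utils::write.csv(as.data.frame(effects), full, row.names = FALSE)
  utils::write.csv(as.data.frame(effects)[effects$significant, ,
                                          drop = FALSE],
                   thr, row.names = FALSE)
  invisible(c(full, thr))
}

#' Threshold sweep: regional associations at increasing stringency
#'
#' Re-runs [regional_quality_associations()] after excluding
#' participants at each quality cutoff, and summarizes the attenuation
#' of the number of FDR-significant regions and of the mean absolute
#' partial correlation as the sample is restricted to better quality.
#'
#' @param cohort A [cohort_table].
#' @param metric A [qc_metric] or column name.
#' @param cutoffs Cutoffs ordered from lenient to stringent.
#' @param phenotype Phenotype key.
#' @param mode Filter mode passed to [apply_quality_filter()]
#'   (`"absolute"` for score cutoffs, `"mad_k"` for MAD multiples).
#' @param max_exclusion Sweep points excluding more than this fraction
#'   are flagged and not fitted (default 0.95).
#' @param ... Passed to [apply_quality_filter()].
#' @return List: `summary` (cutoff, n_retained, n_significant,
#'   mean_abs_partial_r, fitted flag) and `per_cutoff` (the regional
#'   tables, NULL where not fitted).
#' @export
threshold_sweep <- function(cohort, metric, cutoffs, phenotype = "CT",
                            mode = "absolute", max_exclusion = 0.95,
                            ...) {
  metric <- as_qc_metric(metric)
  n0 <- nrow(cohort)
  per <- vector("list", length(cutoffs))
  summ <- vector("list", length(cutoffs))
  for (i in seq_along(cutoffs)) {
    flt <- apply_quality_filter(cohort, metric, cutoffs[i], mode = mode,
                                ...)
    n_ret <- nrow(flt$cohort)
    if ((n0 - n_ret) / n0 > max_exclusion) {
      summ[[i]] <- data.frame(cutoff = cutoffs[i], n_retained = n_ret,
                              n_significant = NA_integer_,
                              mean_abs_partial_r = NA_real_,
                              fitted = FALSE)
      next
    }
    eff <- tryCatch(
      regional_quality_associations(flt$cohort, metric, phenotype),
      error = function(e) NULL)
    if (is.null(eff)) {
      summ[[i]] <- data.frame(cutoff = cutoffs[i], n_retained = n_ret,
                              n_significant = NA_integer_,
                              mean_abs_partial_r = NA_real_,
                              fitted = FALSE)
      next
    }
    per[[i]] <- eff
    summ[[i]] <- data.frame(cutoff = cutoffs[i], n_retained = n_ret,
                            n_significant = sum(eff$significant),
                            mean_abs_partial_r = mean(abs(eff$partial_r)),
                            fitted = TRUE)
  }
  list(summary = do.call(rbind, summ), per_cutoff = per)
}

#' Case-control comparison under a quality-handling strategy
#'
#' Per region, fits diagnosis + age + age squared + sex (site random
#' intercept) and converts the diagnosis t into Cohen's d. Strategies:
#' `none` ignores quality; `covariate` adds the metric to the model;
#' `threshold` first excludes participants beyond `cutoff`;
#' `hybrid` both thresholds (on `threshold_metric`, by default the
#' main metric) and covaries for `metric`. Subthreshold d values are
#' retained in the output alongside the FDR flags.
#'
#' @param cohort A [cohort_table].
#' @param phenotype Phenotype key.
#' @param strategy One of `"none"`, `"covariate"`, `"threshold"`,
#'   `"hybrid"`.
#' @param metric A [qc_metric] (required unless strategy is "none").
#' @param cutoff Threshold value (threshold/hybrid strategies).
#' @param threshold_metric Metric used for the exclusion step of
#'   `hybrid` (defaults to `metric`).
#' @param threshold_mode Filter mode for the exclusion step.
#' @param fdr_level FDR level, default 0.05.
#' @param min_n Minimum complete rows per region.
#' @return Data frame: region, phenotype, cohens_d, t, df, p, q,
#'   significant, n_cases, n_controls; attribute `strategy`.
#' @export
case_control_comparison <- function(cohort, phenotype = "CT",
                                    strategy = c("none", "covariate",
                                                 "threshold", "hybrid"),
                                    metric = NULL, cutoff = NULL,
                                    threshold_metric = NULL,
                                    threshold_mode = "absolute",
                                    fdr_level = 0.05, min_n = 10L) {
  strategy <- match.arg(strategy)
  if (strategy != "none" && is.null(metric))
    stop("strategy ", strategy, " requires a metric", call. = FALSE)
  if (!is.null(metric)) metric <- as_qc_metric(metric)
  dat <- cohort
  if (strategy %in% c("threshold", "hybrid")) {
    if (is.null(cutoff))
      stop("strategy ", strategy, " requires a cutoff", call. = FALSE)
    tm <- if (!is.null(threshold_metric)) as_qc_metric(threshold_metric)
          else metric
    dat <- apply_quality_filter(dat, tm, cutoff,
                                mode = threshold_mode)$cohort
    if (length(unique(dat$diagnosis[!is.na(dat$diagnosis)])) < 2L)
      stop("quality filtering emptied a diagnostic group", call. = FALSE)
  }
  fixed <- c("diagnosis", "age_c", "age_c2", "sex")
  if (strategy %in% c("covariate", "hybrid")) {
    mcol <- dat[[metric$name]]
    if (stats::var(mcol, na.rm = TRUE) < .Machine$double.eps) {
      warning("metric column is constant; dropping the quality ",
              "covariate (strategy reduces to 'none')")
    } else {
      fixed <- c(fixed, metric$name)
    }
  }
  d <- prepare_model_data(dat)
  regions <- region_columns(cohort, phenotype)
  rows <- list(); skipped <- character()
  for (rg in regions) {
    fit <- tryCatch(fit_lmm(d, rg, fixed, min_n = min_n),
                    error = function(e) e)
    if (inherits(fit, "error")) { skipped <- c(skipped, rg); next }
    cr <- coef_row(fit, "diagnosis")
    g <- fit$data$diagnosis
    n1 <- sum(g != 0); n0 <- sum(g == 0)
    rows[[rg]] <- data.frame(
      region = rg, phenotype = phenotype,
      cohens_d = cohens_d_from_t(cr$t, n0, n1, fit$df_resid),
      t = cr$t, df = fit$df_resid, p = cr$p, n_cases = n1,
      n_controls = n0, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no region could be fitted", call. = FALSE)
  out <- do.call(rbind, rows)
  fdr <- fdr_bh(out$p, fdr_level)
  out$q <- fdr$q
  out$significant <- fdr$significant
  rownames(out) <- NULL
  attr(out, "strategy") <- strategy
  attr(out, "skipped") <- skipped
  out
}

#' Diagnosis-by-quality interaction map
#'
#' Adds a diagnosis x metric interaction to the case-control model and
#' reports the interaction term per region with FDR correction — a
#' group difference in the quality-morphometry slope (e.g. a stronger
#' quality effect on cortical thickness in cases).
#'
#' @inheritParams case_control_comparison
#' @param metric A [qc_metric] or column name.
#' @return Data frame: region, estimate, se, t, df, p, q, significant,
#'   n_used.
#' @export
quality_diagnosis_interaction <- function(cohort, metric,
                                          phenotype = "CT",
                                          fdr_level = 0.05, min_n = 10L) {
  metric <- as_qc_metric(metric)
  if (stats::var(cohort[[metric$name]], na.rm = TRUE) <
      .Machine$double.eps)
    stop("design error: metric column is constant", call. = FALSE)
  d <- prepare_model_data(cohort)
  fixed <- c("diagnosis", metric$name, "age_c", "age_c2", "sex",
             paste0("diagnosis:", metric$name))
  iterm <- paste0("diagnosis:", metric$name)
  regions <- region_columns(cohort, phenotype)
  rows <- list()
  for (rg in regions) {
    fit <- tryCatch(fit_lmm(d, rg, fixed, min_n = min_n),
                    error = function(e) e)
    if (inherits(fit, "error")) next
    cr <- coef_row(fit, iterm)
    rows[[rg]] <- data.frame(region = rg, estimate = cr$estimate,
                             se = cr$se, t = cr$t, df = fit$df_resid,
                             p = cr$p, n_used = fit$n_used,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no region could be fitted", call. = FALSE)
  out <- do.call(rbind, rows)
  fdr <- fdr_bh(out$p, fdr_level)
  out$q <- fdr$q
  out$significant <- fdr$significant
  rownames(out) <- NULL
  out
}
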