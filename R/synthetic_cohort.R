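#' Parameters for the cohort simulator
#'
#' Defines the generative model of a simulated multi-site case-control
#' cohort with a latent image-quality variable: quality is worse in
#' younger and in diagnosed participants and varies by site; the
#' observed FSQC score is a clipped linear readout of latent quality
#' and the Euler index a rounded log-linear one (mimicking the heavy
#' right skew of real Euler distributions); each region's phenotype
#' value carries age, sex, diagnosis and quality effects plus a site
#' intercept and Gaussian residual. Per-region quality slopes `lambda`
#' are specified in partial-correlation units and converted internally
#' to model-unit slopes, so the implied per-region partial r is known
#' exactly.
#'
#' @param n Number of participants.
#' @param n_sites Number of acquisition sites.
#' @param site_sd SD of the site intercept on the phenotype scale (mm).
#' @param site_quality_share Multiplier taking the site intercept onto
#'   the quality scale.
#' @param age_range Uniform age range, years.
#' @param case_fraction Probability of diagnosis = 1.
#' @param beta_age Quality change per year of age (negative: younger is
#'   worse).
#' @param beta_dx Quality shift in cases (positive: cases worse).
#' @param quality_sd SD of the latent quality noise.
#' @param fsqc_intercept Mean FSQC at average age, control, site 0.
#' @param euler_a,euler_b,euler_sd Log-linear Euler link parameters:
#'   `euler = round(exp(a + b q + eps))`.
#' @param n_regions Number of phenotype regions (360 emulates a
#'   multimodal-parcellation-resolution table; 68 a Desikan-Killiany
#'   one).
#' @param lambda Per-region quality slopes in partial-r units: either a
#'   length-`n_regions` vector or a list
#'   `list(p_neg, p_zero, p_pos, neg_range, pos_range)` describing the
#'   random mixture (default: largely negative associations with a
#'   minority of positive ones, as regional quality effects show both
#'   signs).
#' @param delta Per-region diagnosis effect (mm); scalar recycled.
#' @param residual_sd Per-region residual SD (mm).
#' @param gamma_age_range,gamma_sex_range Uniform ranges from which the
#'   per-region age slopes (mm/year) and sex effects (mm) are drawn.
#' @param quality_channel `"fsqc"` routes the phenotype effect through
#'   observed FSQC (the analysis model is then correctly specified
#'   under the covariate strategy); `"latent"` through latent quality,
#'   for misspecification studies.
#' @param tail_pivot If non-NULL, quality effects act only through
#'   `pmax(fsqc - tail_pivot, 0)`: effects concentrate in the
#'   worst-quality tail.
#' @param globals Add the six global brain measures with a mild quality
#'   dependence.
#' @param n_reference Internal reference-sample size used to calibrate
#'   partial-r slope conversion.
#' @export
cohort_sim_params <- function(n = 2000L, n_sites = 10L, site_sd = 0.1,
                              site_quality_share = 2,
                              age_range = c(6, 30),
                              case_fraction = 0.45,
                              beta_age = -0.015, beta_dx = 0.15,
                              quality_sd = 0.5, fsqc_intercept = 1.6,
                              euler_a = 4.6, euler_b = 0.8,
                              euler_sd = 0.5, n_regions = 360L,
                              lambda = list(p_neg = 0.45, p_zero = 0.35,
                                            p_pos = 0.20,
                                            neg_range = c(-0.45, -0.05),
                                            pos_range = c(0.05, 0.35)),
                              delta = 0, residual_sd = 0.25,
                              gamma_age_range = c(-0.01, 0),
                              gamma_sex_range = c(-0.05, 0.05),
                              quality_channel = c("fsqc", "latent"),
                              tail_pivot = NULL, globals = TRUE,
                              n_reference = 50000L) {
  stopifnot(n >= 2L, n_sites >= 1L, site_sd >= 0, quality_sd >= 0,
            euler_sd >= 0, residual_sd >= 0,
            case_fraction > 0, case_fraction < 1,
            diff(age_range) > 0)
  quality_channel <- match.arg(quality_channel)
  list(n = as.integer(n), n_sites = as.integer(n_sites),
       site_sd = site_sd, site_quality_share = site_quality_share,
       age_range = age_range, case_fraction = case_fraction,
       beta_age = beta_age, beta_dx = beta_dx, quality_sd = quality_sd,
       fsqc_intercept = fsqc_intercept, euler_a = euler_a,
       euler_b = euler_b, euler_sd = euler_sd,
       n_regions = as.integer(n_regions), lambda = lambda,
       delta = delta, residual_sd = residual_sd,
       gamma_age_range = gamma_age_range,
       gamma_sex_range = gamma_sex_range,
       quality_channel = quality_channel, tail_pivot = tail_pivot,
       globals = globals, n_reference = as.integer(n_reference))
}

draw_demographics <- function(p, n) {
  site <- sprintf("site%02d", sample.int(p$n_sites, n, replace = TRUE))
  age <- stats::runif(n, p$age_range[1], p$age_range[2])
  sex <- stats::rbinom(n, 1L, 0.5)
  dx <- stats::rbinom(n, 1L, p$case_fraction)
  list(site = site, age = age, sex = sex, dx = dx)
}

draw_quality <- function(p, demo, site_int) {
  n <- length(demo$age)
  q <- p$beta_age * (demo$age - mean(p$age_range)) +
    p$beta_dx * demo$dx +
    p$site_quality_share * site_int[demo$site] +
    stats::rnorm(n, 0, p$quality_sd)
  fsqc <- pmin(pmax(p$fsqc_intercept + q, 1), 4)
  euler <- pmax(round(exp(p$euler_a + p$euler_b * q +
                            stats::rnorm(n, 0, p$euler_sd))), 0)
  list(q = q, fsqc = fsqc, euler = euler)
}

quality_effect_variable <- function(p, qual) {
  x <- if (p$quality_channel == "fsqc") qual$fsqc else qual$q
  if (!is.null(p$tail_pivot)) pmax(x - p$tail_pivot, 0) else x
}

#' Simulate a cohort with known ground truth
#'
#' All randomness comes from `seed`; repeated calls are identical. See
#' [cohort_sim_params()] for the generative model.
#'
#' @param params A [cohort_sim_params()].
#' @param seed Integer seed.
#' @return List: `cohort` (a [cohort_table] with QC columns `fsqc` and
#'   `euler`, global measures when requested, and region columns
#'   `CT_rXXX`), `truth` (per-region coefficients and the implied
#'   partial r), and `info` (reference-sample calibration values,
#'   including the implied Cohen's d of diagnosis on FSQC).
#' @export
simulate_cohort <- function(params = cohort_sim_params(), seed = 1L) {
  p <- params
  with_preserved_seed(seed, {
    # per-region ground-truth coefficients
    nr <- p$n_regions
    m_r <- stats::runif(nr, 2, 3.5)
    gamma_age <- stats::runif(nr, p$gamma_age_range[1],
                              p$gamma_age_range[2])
    gamma_sex <- stats::runif(nr, p$gamma_sex_range[1],
                              p$gamma_sex_range[2])
    delta_r <- rep_len(p$delta, nr)
    lam_r <- if (is.numeric(p$lambda)) rep_len(p$lambda, nr) else {
      grp <- sample(c("neg", "zero", "pos"), nr, replace = TRUE,
                    prob = c(p$lambda$p_neg, p$lambda$p_zero,
                             p$lambda$p_pos))
      ifelse(grp == "neg",
             stats::runif(nr, p$lambda$neg_range[1],
                          p$lambda$neg_range[2]),
             ifelse(grp == "pos",
                    stats::runif(nr, p$lambda$pos_range[1],
                                 p$lambda$pos_range[2]), 0))
    }
    if (abs(max(abs(lam_r))) >= 1)
      stop("lambda values are partial correlations; |lambda| < 1",
           call. = FALSE)
    site_int <- stats::setNames(
      stats::rnorm(p$n_sites, 0, p$site_sd),
      sprintf("site%02d", seq_len(p$n_sites)))

    # reference sample: calibrates the partial-r -> slope conversion
    ref_demo <- draw_demographics(p, p$n_reference)
    ref_qual <- draw_quality(p, ref_demo, site_int)
    ref_x <- quality_effect_variable(p, ref_qual)
    ref_df <- data.frame(x = ref_x,
                         age_c = ref_demo$age - mean(p$age_range),
                         sex = ref_demo$sex, dx = ref_demo$dx,
                         site = ref_demo$site)
    ref_df$age_c2 <- ref_df$age_c^2
    rhs <- if (p$n_sites > 1L) "age_c + age_c2 + sex + factor(site)"
           else "age_c + age_c2 + sex"
    sd_qres <- stats::sd(stats::residuals(stats::lm(
      stats::as.formula(paste("x ~", rhs)), data = ref_df)))
    x_center <- mean(ref_x)
    # implied d of diagnosis on FSQC, from the reference sample
    fit_dx <- stats::lm(stats::as.formula(paste("fsqc ~ dx +", rhs)),
                        data = cbind(ref_df, fsqc = ref_qual$fsqc))
    dx_fsqc_d <- unname(stats::coef(fit_dx)["dx"]) /
      stats::sd(stats::residuals(fit_dx))
    slope_r <- if (sd_qres < .Machine$double.eps) {
      if (any(lam_r != 0))
        stop("nonzero lambda requires quality variation", call. = FALSE)
      rep(0, nr)
    } else lam_r / sqrt(1 - lam_r^2) * p$residual_sd / sd_qres

    # the cohort itself
    demo <- draw_demographics(p, p$n)
    qual <- draw_quality(p, demo, site_int)
    x_eff <- quality_effect_variable(p, qual) - x_center
    site_term <- site_int[demo$site]
    regions <- matrix(stats::rnorm(p$n * nr, 0, p$residual_sd),
                      nrow = p$n)
    regions <- regions +
      outer(rep(1, p$n), m_r) +
      outer(demo$age, gamma_age) +
      outer(demo$sex, gamma_sex) +
      outer(demo$dx, delta_r) +
      outer(x_eff, slope_r) +
      matrix(site_term, p$n, nr)
    colnames(regions) <- sprintf("CT_r%03d", seq_len(nr))
    df <- data.frame(subject_id = sprintf("sub%05d", seq_len(p$n)),
                     age = demo$age, sex = demo$sex,
                     diagnosis = demo$dx, site = demo$site,
                     fsqc = qual$fsqc, euler = qual$euler,
                     stringsAsFactors = FALSE)
    qc_cols <- c("fsqc", "euler")
    if (isTRUE(p$globals)) {
      fc <- qual$fsqc - mean(qual$fsqc)
      df$cGMV <- 600 - 15 * fc + stats::rnorm(p$n, 0, 50)
      df$sGMV <- 60 - 1.5 * fc + stats::rnorm(p$n, 0, 6)
      df$TBV <- 1250 - 25 * fc + stats::rnorm(p$n, 0, 100)
      df$WMV <- 450 - 8 * fc + stats::rnorm(p$n, 0, 40)
      df$ventricles <- 15 + 1.2 * fc + stats::rnorm(p$n, 0, 4)
      df$meanCT <- 2.6 - 0.08 * fc + stats::rnorm(p$n, 0, 0.12)
    }
    df <- cbind(df, as.data.frame(regions))
    cohort <- cohort_table(df, qc_cols = qc_cols,
                           region_cols = list(CT = colnames(regions)))
    truth <- data.frame(region = colnames(regions), m = m_r,
                        gamma_age = gamma_age, gamma_sex = gamma_sex,
                        delta = delta_r, lambda_partial_r = lam_r,
                        lambda_slope = slope_r,
                        stringsAsFactors = FALSE)
    list(cohort = cohort, truth = truth,
         info = list(sd_quality_residual = sd_qres,
                     x_center = x_center, dx_fsqc_d = dx_fsqc_d,
                     site_intercepts = site_int, seed = seed))
  })
}
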