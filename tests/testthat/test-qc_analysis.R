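sim_small <- function(n = 400, n_regions = 12, seed = 61, ...) {
  simulate_cohort(cohort_sim_params(n = n, n_regions = n_regions,
                                    n_reference = 20000L, ...),
                  seed = seed)
}

test_that("the mixed model recovers a known slope with site intercepts", {
  set.seed(62)
  n <- 500
  site <- sample(sprintf("s%d", 1:8), n, replace = TRUE)
  site_eff <- setNames(rnorm(8, 0, 1), sprintf("s%d", 1:8))
  x <- rnorm(n)
  d <- data.frame(y = 2 * x + site_eff[site] + rnorm(n, 0, 0.5),
                  x = x, site = site)
  fit <- fit_lmm(d, "y", "x")
  cr <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_lt(abs(cr$estimate - 2), 3 * cr$se)
  expect_identical(fit$model, "lmm")
  expect_gt(fit$ranef_var, 0.1)
})

test_that("single-site data degrade to OLS, matching lm exactly", {
  set.seed(63)
  d <- data.frame(y = rnorm(50), x = rnorm(50), z = rnorm(50),
                  site = "only")
  expect_warning(fit_lmm(d, "y", c("x", "z")), "single level")
  fit <- suppressWarnings(fit_lmm(d, "y", c("x", "z")))
  ref <- lm(y ~ x + z, data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-6)
})

test_that("a zero-variance response is flagged singular with a null slope", {
  set.seed(64)
  d <- data.frame(y = 2, x = rnorm(60), site = rep(c("a", "b"), 30))
  fit <- suppressWarnings(fit_lmm(d, "y", "x"))
  expect_true(fit$singular)
  expect_equal(fit$coefficients$estimate[2], 0, tolerance = 1e-10)
})

test_that("partial r from t follows the closed form and the residual oracle", {
  expect_equal(partial_r_from_t(0, 10), 0)
  expect_equal(partial_r_from_t(1, 1), 1 / sqrt(2))
  set.seed(65)
  for (rep in 1:20) {
    n <- 80
    d <- data.frame(y = rnorm(n), x = rnorm(n), c1 = rnorm(n),
                    c2 = rnorm(n), site = "one")
    fit <- suppressWarnings(fit_lmm(d, "y", c("x", "c1", "c2")))
    cr <- fit$coefficients[fit$coefficients$term == "x", ]
    got <- partial_r_from_t(cr$t, fit$df_resid)
    ry <- resid(lm(y ~ c1 + c2, data = d))
    rx <- resid(lm(x ~ c1 + c2, data = d))
    # residual-residual correlation oracle (df conventions differ by
    # one covariate, hence the loose-but-tiny tolerance)
    expect_equal(got, cor(ry, rx), tolerance = 0.02)
  }
})

test_that("BH q-values and flags match the brute-force step-up scan", {
  expect_equal(fdr_bh(0.03)$q, 0.03)
  expect_equal(fdr_bh(rep(0.02, 7))$q, rep(0.02, 7))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
  set.seed(66)
  for (rep in 1:25) {
    p <- runif(360)^sample(c(1, 2, 3), 1)
    got <- fdr_bh(p)
    expect_identical(got$significant, brute_bh_flags(p))
    expect_true(all(got$q >= p - 1e-12))
  }
})

test_that("metric correlation matrix is symmetric with direction metadata", {
  set.seed(67)
  n <- 300
  latent <- rnorm(n)
  co <- toy_cohort(pmin(pmax(1.6 + 0.5 * latent, 1), 4))
  co$euler <- round(exp(4.5 + 0.8 * latent + rnorm(n, 0, 0.4)))
  co$qoala <- 50 - 20 * latent + rnorm(n, 0, 10) # higher = better
  attr(co, "qc_cols") <- c("fsqc", "euler", "qoala")
  mets <- list(qc_metric("fsqc"), qc_metric("euler"),
               qc_metric("qoala", "higher_better"))
  got <- metric_correlation_matrix(co, mets)
  expect_equal(got$rho, t(got$rho))
  expect_equal(unname(diag(got$rho)), rep(1, 3))
  expect_gt(got$rho["fsqc", "euler"], 0)
  expect_lt(got$rho["fsqc", "qoala"], 0) # sign tracks the direction flag
  expect_true(got$display_abs["fsqc", "qoala"])
  expect_false(got$display_abs["fsqc", "euler"])
})

test_that("the demographic model recovers the injected diagnosis effect on quality", {
  sim <- sim_small(n = 2000, n_regions = 2, seed = 68)
  got <- demographic_quality_model(sim$cohort, qc_metric("fsqc"))
  d_hat <- got$cohens_d[got$term == "diagnosis"]
  expect_lt(abs(d_hat - sim$info$dx_fsqc_d), 0.1)
  # worse quality in younger participants: negative age slope
  expect_lt(got$estimate[got$term == "age_c"], 0)
  expect_lt(got$p[got$term == "age_c"], 0.001)
  expect_true(is.na(got$cohens_d[got$term == "age_c"]))
})

test_that("null sex effects give uniform p-values across simulations", {
  set.seed(69)
  pvals <- replicate(200, {
    n <- 250
    co <- cohort_table(data.frame(
      subject_id = sprintf("s%d", 1:n), age = runif(n, 6, 30),
      sex = rbinom(n, 1, 0.5), diagnosis = rbinom(n, 1, 0.45),
      site = "one", fsqc = runif(n, 1, 4)), qc_cols = "fsqc")
    got <- suppressWarnings(demographic_quality_model(co,
                                                      qc_metric("fsqc")))
    got$p[got$term == "sex"]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("global quality correlations use the Bonferroni family of six", {
  sim <- sim_small(n = 600, n_regions = 2, seed = 70)
  got <- global_quality_correlations(sim$cohort, qc_metric("fsqc"))
  expect_equal(got$bonferroni_level, 0.05 / 6, tolerance = 1e-12)
  expect_identical(nrow(got$results), 6L)
  expect_lt(got$results$rho[got$results$measure == "meanCT"], 0)
  # perfect monotone dependence is flagged
  co <- sim$cohort
  co$TBV <- co$fsqc^3
  got2 <- global_quality_correlations(co, qc_metric("fsqc"))
  row <- got2$results[got2$results$measure == "TBV", ]
  expect_equal(row$rho, 1)
  expect_true(row$significant)
  # absent columns are reported, not fitted
  co$WMV <- NULL
  got3 <- global_quality_correlations(co, qc_metric("fsqc"))
  expect_identical(got3$skipped, "WMV")
})

test_that("regional associations recover injected partial correlations", {
  lam <- rep(c(-0.3, 0, 0.2), each = 5)
  sim <- simulate_cohort(cohort_sim_params(
    n = 1500, n_regions = 15, lambda = lam, n_reference = 30000L),
    seed = 71)
  eff <- regional_quality_associations(sim$cohort, qc_metric("fsqc"),
                                       "CT")
  expect_identical(nrow(eff), 15L)
  err <- eff$partial_r - sim$truth$lambda_partial_r
  expect_lt(max(abs(err)), 0.08)
  expect_true(all(sign(eff$partial_r) == sign(eff$t)))
  expect_true(all(eff$q >= eff$p - 1e-12))
  expect_true(all(eff$significant == (eff$q < 0.05)))
})

test_that("flipping the direction flag negates every partial r exactly", {
  sim <- sim_small(seed = 72)
  a <- regional_quality_associations(sim$cohort, qc_metric("fsqc"), "CT")
  b <- regional_quality_associations(
    sim$cohort, qc_metric("fsqc", "higher_better"), "CT")
  expect_equal(b$partial_r, -a$partial_r, tolerance = 1e-12)
  expect_equal(b$t, -a$t, tolerance = 1e-12)
})

test_that("duplicating every row leaves partial r unchanged but shrinks p", {
  set.seed(73)
  n <- 60
  co <- cohort_table(data.frame(
    subject_id = sprintf("s%d", 1:n), age = runif(n, 6, 30),
    sex = rbinom(n, 1, 0.5), diagnosis = 0L, site = "one",
    fsqc = runif(n, 1, 4), CT_r001 = rnorm(n, 2.5, 0.3)),
    qc_cols = "fsqc", region_cols = list(CT = "CT_r001"))
  co2 <- as.data.frame(co)
  co2 <- rbind(co2, transform(co2, subject_id = paste0(subject_id, "b")))
  co2 <- cohort_table(co2, qc_cols = "fsqc",
                      region_cols = list(CT = "CT_r001"))
  e1 <- suppressWarnings(
    regional_quality_associations(co, qc_metric("fsqc"), "CT"))
  e2 <- suppressWarnings(
    regional_quality_associations(co2, qc_metric("fsqc"), "CT"))
  expect_equal(e2$partial_r, e1$partial_r, tolerance = 1e-9)
  expect_lt(e2$p, e1$p)
})

test_that("threshold sweeps are identity at lenient cutoffs and monotone in n", {
  sim <- sim_small(n = 500, n_regions = 8, seed = 74)
  sweep <- threshold_sweep(sim$cohort, qc_metric("fsqc"),
                           cutoffs = c(5, 3, 2.5, 2, 1.5),
                           phenotype = "CT")
  expect_true(all(diff(sweep$summary$n_retained) <= 0))
  # cutoff retaining everyone reproduces the unfiltered analysis
  direct <- regional_quality_associations(sim$cohort,
                                          qc_metric("fsqc"), "CT")
  expect_equal(sweep$per_cutoff[[1]]$partial_r, direct$partial_r,
               tolerance = 1e-9)
  # a cutoff excluding nearly everyone is flagged, not fitted
  sweep2 <- threshold_sweep(sim$cohort, qc_metric("fsqc"),
                            cutoffs = c(1.0001), phenotype = "CT")
  expect_false(sweep2$summary$fitted[1])
})

test_that("case-control strategies recover a clean group effect", {
  sim <- simulate_cohort(cohort_sim_params(
    n = 1500, n_regions = 6, beta_dx = 0,
    delta = c(0.075, 0, 0, 0, 0, 0), lambda = 0,
    n_reference = 20000L), seed = 75)
  # delta = 0.075 mm on residual sd 0.25 => d = 0.3 in region 1
  for (strat in c("none", "covariate")) {
    got <- case_control_comparison(sim$cohort, "CT", strat,
                                   metric = qc_metric("fsqc"))
    expect_lt(abs(got$cohens_d[1] - 0.3), 0.1)
    expect_true(all(abs(got$cohens_d[-1]) < 0.15))
  }
  thr <- case_control_comparison(sim$cohort, "CT", "threshold",
                                 metric = qc_metric("fsqc"),
                                 cutoff = 3.5)
  expect_lt(abs(thr$cohens_d[1] - 0.3), 0.12)
  hyb <- case_control_comparison(sim$cohort, "CT", "hybrid",
                                 metric = qc_metric("fsqc"),
                                 cutoff = 3.5)
  expect_lt(abs(hyb$cohens_d[1] - 0.3), 0.12)
})

test_that("a threshold retaining every row equals strategy none", {
  sim <- sim_small(n = 400, n_regions = 5, seed = 76)
  none <- case_control_comparison(sim$cohort, "CT", "none")
  thr <- case_control_comparison(sim$cohort, "CT", "threshold",
                                 metric = qc_metric("fsqc"),
                                 cutoff = 4)
  expect_equal(thr$cohens_d, none$cohens_d, tolerance = 1e-12)
  # a constant metric column degrades covariate to none, with warning
  co <- sim$cohort
  co$flatmetric <- 1
  attr(co, "qc_cols") <- c(attr(co, "qc_cols"), "flatmetric")
  expect_warning(
    case_control_comparison(co, "CT", "covariate",
                            metric = qc_metric("flatmetric")),
    "constant")
  cov0 <- suppressWarnings(
    case_control_comparison(co, "CT", "covariate",
                            metric = qc_metric("flatmetric")))
  expect_equal(cov0$cohens_d, none$cohens_d, tolerance = 1e-12)
})

test_that("quality confounding biases naive group comparisons; covarying removes it", {
  sim <- simulate_cohort(cohort_sim_params(
    n = 2000, n_regions = 8, beta_dx = 0.3, delta = 0,
    lambda = c(rep(-0.3, 4), rep(0, 4)), n_reference = 30000L),
    seed = 77)
  naive <- case_control_comparison(sim$cohort, "CT", "none")
  adj <- case_control_comparison(sim$cohort, "CT", "covariate",
                                 metric = qc_metric("fsqc"))
  expect_lt(mean(naive$cohens_d[1:4]), -0.1) # spurious deficit
  expect_lt(abs(mean(adj$cohens_d[1:4])), 0.05)
})

test_that("diagnosis-by-quality interactions are detected and calibrated", {
  set.seed(78)
  gen_int <- function(slope_ctrl, slope_case, n = 2000) {
    fsqc <- pmin(pmax(1.6 + rnorm(n, 0, 0.5), 1), 4)
    dx <- rbinom(n, 1, 0.5)
    slope <- ifelse(dx == 1, slope_case, slope_ctrl)
    ct <- 2.5 + slope * (fsqc - mean(fsqc)) + rnorm(n, 0, 0.25)
    cohort_table(data.frame(
      subject_id = sprintf("s%d", 1:n), age = runif(n, 6, 30),
      sex = rbinom(n, 1, 0.5), diagnosis = dx, site = "one",
      fsqc = fsqc, CT_r001 = ct), qc_cols = "fsqc",
      region_cols = list(CT = "CT_r001"))
  }
  hits <- replicate(100, {
    co <- gen_int(-0.2, -0.4)
    got <- suppressWarnings(
      quality_diagnosis_interaction(co, qc_metric("fsqc"), "CT"))
    got$estimate[1] < 0
  })
  expect_gte(mean(hits), 0.9)

  # null interaction: FDR flags at most ~5%
  sim <- sim_small(n = 600, n_regions = 40, seed = 79)
  got0 <- quality_diagnosis_interaction(sim$cohort, qc_metric("fsqc"),
                                        "CT")
  expect_lte(mean(got0$significant), 0.055)

  co_flat <- gen_int(0, 0)
  co_flat$fsqc <- 2
  expect_error(
    quality_diagnosis_interaction(co_flat, qc_metric("fsqc"), "CT"),
    "constant")
})

test_that("all-null regional analyses keep the FDR flag rate at its nominal level", {
  set.seed(80)
  flags <- replicate(200, {
    n <- 200
    co <- cohort_table(data.frame(
      subject_id = sprintf("s%d", 1:n), age = runif(n, 6, 30),
      sex = rbinom(n, 1, 0.5), diagnosis = rbinom(n, 1, 0.45),
      site = "one", fsqc = runif(n, 1, 4),
      matrix(rnorm(n * 12, 2.5, 0.3), n,
             dimnames = list(NULL, sprintf("CT_r%03d", 1:12)))),
      qc_cols = "fsqc",
      region_cols = list(CT = sprintf("CT_r%03d", 1:12)))
    got <- suppressWarnings(
      regional_quality_associations(co, qc_metric("fsqc"), "CT"))
    mean(got$significant)
  })
  expect_lte(mean(flags), 0.055)
})
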