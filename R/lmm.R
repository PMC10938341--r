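#' Fit a random-intercept linear mixed model
#'
#' REML fit of `response ~ fixed terms + (1 | group)` via \pkg{lme4}.
#' When the grouping factor has a single level the model degrades to
#' ordinary least squares with a warning (the random intercept is not
#' identifiable). Singular fits are flagged but fixed-effect estimates
#' are still returned. Wald t statistics use the residual-df convention
#' `df = n_used - p_fixed`.
#'
#' @param data Data frame holding all columns.
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect terms (column names or
#'   formula terms such as interactions `"a:b"`).
#' @param random Grouping column for the random intercept (default
#'   `"site"`); `NULL` forces OLS.
#' @param min_n Minimum complete rows, default 10.
#' @return List of class `qc_lmm_fit`: `coefficients` (data.frame term,
#'   estimate, se, t, p), `n_used`, `df_resid`, `singular`,
#'   `ranef_var`, `model` ("lmm" or "ols").
#' @export
fit_lmm <- function(data, response, fixed, random = "site", min_n = 10L) {
  base_cols <- unique(unlist(strsplit(fixed, ":", fixed = TRUE)))
  cols <- c(response, base_cols, random)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("model columns absent from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  n <- nrow(d)
  if (n < min_n)
    stop("too few complete rows (", n, " < ", min_n, ") for response ",
         response, call. = FALSE)
  # guard against rank-deficient designs from constant columns
  num_fixed <- base_cols[vapply(d[base_cols], is.numeric, logical(1))]
  const <- num_fixed[vapply(d[num_fixed], function(x)
    stats::var(x) < .Machine$double.eps, logical(1))]
  if (length(const))
    stop("design error: constant fixed-effect column(s): ",
         paste(const, collapse = ", "), call. = FALSE)
  rhs <- paste(fixed, collapse = " + ")
  resp_const <- stats::var(d[[response]]) < .Machine$double.eps
  use_lmm <- !resp_const && !is.null(random) &&
    length(unique(d[[random]])) > 1L
  if (use_lmm) {
    fml <- stats::as.formula(paste0("`", response, "` ~ ", rhs,
                                    " + (1 | ", random, ")"))
    fit <- suppressMessages(lme4::lmer(
      fml, data = d, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
    singular <- lme4::isSingular(fit, tol = 1e-5)
    cf <- summary(fit)$coefficients
    vc <- lme4::VarCorr(fit)
    ranef_var <- as.numeric(vc[[random]][1, 1])
  } else {
    if (!resp_const && !is.null(random))
      warning("grouping factor ", random,
              " has a single level; falling back to OLS")
    fml <- stats::as.formula(paste0("`", response, "` ~ ", rhs))
    fit <- stats::lm(fml, data = d)
    if (any(is.na(stats::coef(fit))))
      stop("design error: rank-deficient fixed-effect design",
           call. = FALSE)
    cf <- summary(fit)$coefficients[, 1:3, drop = FALSE]
    singular <- FALSE
    ranef_var <- 0
  }
  df_resid <- n - nrow(cf)
  est <- cf[, 1]; se <- cf[, 2]
  tt <- ifelse(is.finite(est / se) & se > 0, est / se, 0)
  coefs <- data.frame(term = rownames(cf), estimate = unname(est),
                      se = unname(se), t = unname(tt),
                      p = 2 * stats::pt(-abs(unname(tt)), df = df_resid),
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  if (resp_const) singular <- TRUE
  structure(list(coefficients = coefs, n_used = n, df_resid = df_resid,
                 singular = singular, ranef_var = ranef_var,
                 model = if (use_lmm) "lmm" else "ols", data = d),
            class = "qc_lmm_fit")
}

coef_row <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("term not in model: ", term, call. = FALSE)
  fit$coefficients[i, ]
}

#' Partial correlation from a t statistic
#'
#' `r = t / sqrt(t^2 + df)`; the sign of t is preserved. This converts
#' the Wald t of a covariate into the partial correlation between that
#' covariate and the response, adjusting for the other model terms.
#'
#' @param t t statistic.
#' @param df Residual degrees of freedom, `>= 1`.
#' @export
partial_r_from_t <- function(t, df) {
  stopifnot(all(df >= 1))
  t / sqrt(t^2 + df)
}

#' Cohen's d from a two-group t statistic
#'
#' The two-sample conversion `d = t * (n1 + n2) / (sqrt(n1 n2) sqrt(df))`
#' applied to the model t of a binary term.
#'
#' @param t t statistic of the binary term.
#' @param n1,n2 Group sizes.
#' @param df Residual degrees of freedom.
#' @export
cohens_d_from_t <- function(t, n1, n2, df) {
  t * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values (with the usual monotonicity enforcement, as in
#' `p.adjust(method = "BH")`) and significance flags at `level`.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param level FDR level, default 0.05.
#' @return List with `q` and `significant` (q < level).
#' @export
fdr_bh <- function(p, level = 0.05) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = !is.na(q) & q < level)
}

#' Add centered-age model columns to a cohort
#'
#' Age is mean-centered before squaring (`age_c`, `age_c2`), which
#' decorrelates the linear and quadratic terms without changing the
#' model space.
#'
#' @param cohort A [cohort_table] or data.frame with an `age` column.
#' @export
prepare_model_data <- function(cohort) {
  mu <- mean(cohort$age, na.rm = TRUE)
  cohort$age_c <- cohort$age - mu
  cohort$age_c2 <- cohort$age_c^2
  cohort
}
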