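#' Age and sex reference model for PWV
#'
#' Ordinary least squares of PWV (m/s) on age (years) and a male indicator
#' (male = 1, female = 0), the standardization model used for reference
#' values: `PWV = beta0 + beta_age * age + beta_male * male`. The residual
#' standard deviation and 95% confidence intervals per coefficient are
#' reported, together with the p-value of an age-by-sex interaction from an
#' augmented fit (evidence for a sex-specific age slope).
#'
#' @param cohort data.frame with columns `age`, `pwv` and `male` (0/1) or
#'   `sex` (female/male).
#' @param pwv_col name of the PWV column to model (default `"pwv"`), e.g.
#'   when the table carries one column per wave-arrival method.
#' @return An object of class `reference_model`: `beta0`, `beta_age`,
#'   `beta_male`, `sigma`, `ci` (3 x 2 matrix), `interaction_p`, `n`, `fit`.
#' @export
fit_reference_model <- function(cohort, pwv_col = "pwv") {
  df <- as.data.frame(cohort)
  if (!"male" %in% names(df)) {
    if (!"sex" %in% names(df)) stop("need a 'male' or 'sex' column")
    df$male <- as.integer(df$sex == "male")
  }
  df$.pwv <- df[[pwv_col]]
  df <- df[stats::complete.cases(df[, c("age", "male", ".pwv")]), ]
  if (nrow(df) < 4) stop("reference model needs at least 4 subjects")
  if (length(unique(df$male)) < 2)
    stop("male coefficient is inestimable in a single-sex cohort")
  fit <- stats::lm(.pwv ~ age + male, data = df)
  fit_int <- stats::lm(.pwv ~ age * male, data = df)
  ci <- stats::confint(fit)
  co <- stats::coef(fit)
  structure(list(
    beta0 = unname(co[1]), beta_age = unname(co[2]), beta_male = unname(co[3]),
    sigma = summary(fit)$sigma,
    ci = ci,
    interaction_p = stats::coef(summary(fit_int))["age:male", "Pr(>|t|)"],
    n = nrow(df),
    fit = fit
  ), class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<reference_model> PWV = %.2f + %.3f*age + %.2f*male (m/s), sigma = %.2f, n = %d\n",
              x$beta0, x$beta_age, x$beta_male, x$sigma, x$n))
  cat(sprintf("  age x sex interaction p = %.2f\n", x$interaction_p))
  invisible(x)
}

#' Predict PWV from a reference model
#' @param object A `reference_model`.
#' @param age age in years. @param male male indicator (0/1).
#' @param ... unused.
#' @return Predicted PWV in m/s.
#' @export
predict.reference_model <- function(object, age, male, ...) {
  object$beta0 + object$beta_age * age + object$beta_male * male
}

#' Correlation adjusted for age and sex
#'
#' Each variable is regressed on the covariates (default age + male) and the
#' Pearson correlation between the two residual vectors is reported — the
#' association beyond the shared aging and sex effects. With an empty
#' covariate set this reduces exactly to the plain Pearson correlation. The
#' p-value uses the usual t distribution on n - 2 degrees of freedom of the
#' residual vectors (no correction for the prior regressions).
#'
#' @param cohort data.frame.
#' @param x,y column names of the two variables.
#' @param covariates character vector of adjustment columns (default
#'   `c("age", "male")`); use `character(0)` for an unadjusted correlation.
#' @return An object of class `adjusted_correlation`: `x`, `y`, `r`, `p`,
#'   `n`, `covariates`.
#' @export
adjusted_correlation <- function(cohort, x, y, covariates = c("age", "male")) {
  df <- as.data.frame(cohort)
  if ("sex" %in% names(df) && !"male" %in% names(df))
    df$male <- as.integer(df$sex == "male")
  cols <- c(x, y, covariates)
  if (!all(cols %in% names(df))) stop("missing columns: ",
    paste(setdiff(cols, names(df)), collapse = ", "))
  df <- df[stats::complete.cases(df[, cols, drop = FALSE]), ]
  if (nrow(df) < 4) stop("adjusted correlation needs at least 4 complete subjects")
  resid_on <- function(v) {
    if (length(covariates) == 0) return(df[[v]])
    X <- cbind(1, as.matrix(df[, covariates, drop = FALSE]))
    stats::lm.fit(X, df[[v]])$residuals
  }
  rx <- resid_on(x); ry <- resid_on(y)
  tol <- 1e-10
  if (stats::sd(rx) <= tol * max(stats::sd(df[[x]]), 1) ||
      stats::sd(ry) <= tol * max(stats::sd(df[[y]]), 1))
    stop("zero-variance residuals: correlation undefined")
  ct <- stats::cor.test(rx, ry)
  structure(list(x = x, y = y, r = unname(ct$estimate), p = ct$p.value,
                 n = nrow(df), covariates = covariates),
            class = "adjusted_correlation")
}

#' @export
print.adjusted_correlation <- function(x, ...) {
  adj <- if (length(x$covariates)) paste("adjusted for", paste(x$covariates, collapse = ", "))
         else "unadjusted"
  cat(sprintf("<adjusted_correlation> %s ~ %s (%s): r = %.3f, p = %.4g, n = %d\n",
              x$x, x$y, adj, x$r, x$p, x$n))
  invisible(x)
}

#' Bland-Altman agreement between two observers
#'
#' Differences are `obs2 - obs1`; limits of agreement are the mean
#' difference plus/minus 1.96 standard deviations (n - 1 denominator).
#'
#' @param obs1,obs2 paired measurements.
#' @return An object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and a `plot_data` data.frame of pairwise
#'   means vs differences for plotting.
#' @export
bland_altman <- function(obs1, obs2) {
  ok <- is.finite(obs1) & is.finite(obs2)
  obs1 <- obs1[ok]; obs2 <- obs2[ok]
  if (length(obs1) < 2) stop("Bland-Altman agreement needs at least 2 pairs")
  d <- obs2 - obs1
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 n = length(d),
                 plot_data = data.frame(mean = (obs1 + obs2) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> mean difference %.2f (sd %.2f), limits of agreement [%.2f, %.2f], n = %d\n",
              x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Paired Wilcoxon signed-rank comparison of two PWV methods
#'
#' Two-sided signed-rank test on the paired per-subject differences between
#' two wave-arrival methods: exact distribution for 25 or fewer non-zero
#' differences (when there are no ties), normal approximation with
#' continuity correction otherwise.
#'
#' @param a,b paired measurements (e.g. columns `pwv_ttf`, `pwv_xcor`), or a
#'   data.frame as first argument together with two column names.
#' @return htest object from [stats::wilcox.test()].
#' @export
compare_methods_wilcoxon <- function(a, b) {
  if (is.data.frame(a)) stop("pass two numeric vectors (e.g. cohort$pwv_ttf, cohort$pwv_xcor)")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  d <- a - b
  nz <- sum(d != 0)
  if (nz == 0) stop("all paired differences are zero: signed-rank statistic undefined")
  exact <- nz <= 25 && !any(duplicated(abs(d[d != 0]))) && !any(d == 0)
  stats::wilcox.test(a, b, paired = TRUE, exact = exact, correct = TRUE)
}
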