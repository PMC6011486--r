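#' Decade-by-sex cell sizes of the reference population
#'
#' The sampling frame used throughout: a population-based cohort of 126
#' adults stratified into six age decades (20--29 through 70--79) per sex.
#'
#' @return A data.frame with columns `decade_start`, `sex`, `n`.
#' @export
reference_cell_sizes <- function() {
  data.frame(
    decade_start = rep(seq(20, 70, by = 10), 2),
    sex = rep(c("female", "male"), each = 6),
    n = c(10, 9, 11, 13, 12, 9,      # females per decade
          10, 14, 10, 10, 9, 9)      # males per decade
  )
}

#' Specification of a simulated PWV cohort
#'
#' Subjects are drawn per (decade, sex) cell with ages uniform within the
#' decade, and PWV generated from the linear reference model
#' `PWV = beta0 + beta_age * age + beta_male * male + eps`,
#' `eps ~ N(0, sigma)`. Defaults reproduce the published reference values:
#' `PWV = 1.51 + 0.080 * age + 0.53 * male`, residual sd 0.77 m/s, with the
#' reference population's cell sizes.
#'
#' @param cells data.frame with `decade_start`, `sex`, `n` (see
#'   [reference_cell_sizes()]).
#' @param beta0 intercept (m/s).
#' @param beta_age age slope (m/s per year).
#' @param beta_male male offset (m/s); sex coding male = 1, female = 0.
#' @param sigma residual sd (m/s).
#' @param covariates optional named list describing extra columns; each
#'   element is `list(intercept =, age =, pwv =, sd =)` giving a linear link
#'   on age and/or PWV plus Gaussian noise. See [default_cohort_covariates()].
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cells = reference_cell_sizes(), beta0 = 1.51,
                        beta_age = 0.080, beta_male = 0.53, sigma = 0.77,
                        covariates = NULL, seed = NULL) {
  stopifnot(all(c("decade_start", "sex", "n") %in% names(cells)))
  if (any(cells$n < 0)) stop("cell sizes must be non-negative")
  if (sum(cells$n) == 0) stop("cohort must contain at least one subject")
  if (sigma < 0) stop("residual sd must be non-negative")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Default covariate links for simulated cohorts
#'
#' Plausible links for the covariates the reference study tabulated:
#' blood pressures and aortic diameters rise with age/PWV, and the
#' distensibility coefficient falls with age (so that DC and PWV correlate
#' negatively, as stiffening physiology dictates).
#'
#' @return Named list of covariate link descriptions for [cohort_spec()].
#' @export
default_cohort_covariates <- function() {
  list(
    systolic_bp  = list(intercept = 104, age = 0.45, pwv = 0, sd = 12),
    diastolic_bp = list(intercept = 70, age = 0.20, pwv = 0, sd = 8),
    dc_aao       = list(intercept = 75, age = -0.9, pwv = 0, sd = 6),
    dc_dao       = list(intercept = 80, age = -0.95, pwv = 0, sd = 6),
    diameter_aao = list(intercept = 24, age = 0.14, pwv = 0, sd = 2.5),
    diameter_dao = list(intercept = 18, age = 0.10, pwv = 0, sd = 2)
  )
}

#' Simulate a cohort from the reference model
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame (`cohort_table`): `id`, `age`, `sex`
#'   (factor female/male), `male` (0/1), `pwv` (m/s), plus any covariate
#'   columns. Reproducible under the spec's seed.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    rows <- lapply(seq_len(nrow(spec$cells)), function(i) {
      n <- spec$cells$n[i]
      if (n == 0) return(NULL)
      d0 <- spec$cells$decade_start[i]
      data.frame(age = stats::runif(n, d0, d0 + 10),
                 sex = spec$cells$sex[i])
    })
    tab <- do.call(rbind, rows)
    tab$id <- sprintf("S%03d", seq_len(nrow(tab)))
    tab$male <- as.integer(tab$sex == "male")
    tab$sex <- factor(tab$sex, levels = c("female", "male"))
    tab$pwv <- spec$beta0 + spec$beta_age * tab$age + spec$beta_male * tab$male +
      stats::rnorm(nrow(tab), 0, spec$sigma)
    for (nm in names(spec$covariates)) {
      lk <- spec$covariates[[nm]]
      tab[[nm]] <- (lk$intercept %||% 0) + (lk$age %||% 0) * tab$age +
        (lk$pwv %||% 0) * tab$pwv + stats::rnorm(nrow(tab), 0, lk$sd %||% 0)
    }
    tab <- tab[, c("id", "age", "sex", "male", "pwv",
                   setdiff(names(tab), c("id", "age", "sex", "male", "pwv")))]
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}
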