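test_that("reference model inference behaves on constructed cohorts", {
  tab <- simulate_cohort(cohort_spec(sigma = 0.77, seed = 42))
  rm <- fit_reference_model(tab)
  expect_equal(rm$n, 126)
  expect_true(rm$ci["age", 1] < rm$ci["age", 2])
  expect_true(rm$sigma > 0)
  expect_equal(predict(rm, 50, 1), rm$beta0 + 50 * rm$beta_age + rm$beta_male)
  # single-sex cohorts cannot identify the male offset
  expect_error(fit_reference_model(tab[tab$male == 0, ]), "single-sex")
})

test_that("age coefficient is unbiased over replicate simulated cohorts", {
  n_rep <- 60
  est <- vapply(seq_len(n_rep), function(i) {
    tab <- simulate_cohort(cohort_spec(sigma = 0.77, seed = 1000 + i))
    fit_reference_model(tab)$beta_age
  }, numeric(1))
  expect_equal(mean(est), 0.080, tolerance = 0.02)
})

test_that("interaction p-values are roughly uniform under the null", {
  p <- vapply(1:40, function(i) {
    tab <- simulate_cohort(cohort_spec(sigma = 0.77, seed = 5000 + i))
    fit_reference_model(tab)$interaction_p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("adjusted correlation agrees with the closed-form partial correlation", {
  # 6-row hand-made table; oracle: recursive partial-correlation formula
  tab <- data.frame(
    age = c(25, 37, 44, 52, 63, 71),
    male = c(0, 1, 0, 1, 0, 1),
    x = c(5.1, 6.0, 5.4, 7.2, 7.9, 8.8),
    y = c(61, 52, 47, 44, 30, 25)
  )
  pc_oracle <- function(df) {
    r <- function(a, b) cor(df[[a]], df[[b]])
    p1 <- function(a, b, z)                       # first-order partial
      (r(a, b) - r(a, z) * r(b, z)) / sqrt((1 - r(a, z)^2) * (1 - r(b, z)^2))
    # second-order: condition on age then male
    (p1("x", "y", "age") - p1("x", "male", "age") * p1("y", "male", "age")) /
      sqrt((1 - p1("x", "male", "age")^2) * (1 - p1("y", "male", "age")^2))
  }
  ac <- adjusted_correlation(tab, "x", "y")
  expect_equal(ac$r, pc_oracle(tab), tolerance = 1e-10)
})

test_that("adjusted correlation reduces to plain Pearson without covariates", {
  set.seed(8)
  tab <- data.frame(x = rnorm(30), y = rnorm(30), age = rnorm(30))
  ac <- adjusted_correlation(tab, "x", "y", covariates = character(0))
  ct <- cor.test(tab$x, tab$y)
  expect_identical(ac$r, unname(ct$estimate))
  expect_identical(ac$p, ct$p.value)
  # y = x exactly: r = 1
  expect_equal(adjusted_correlation(data.frame(x = 1:6, y = 1:6, age = rnorm(6),
                                               male = rep(0:1, 3)),
                                    "x", "y", character(0))$r, 1)
  expect_error(adjusted_correlation(data.frame(x = 1:6, y = rep(1, 6),
                                               age = 1:6),
                                    "x", "y", "age"), "zero-variance")
})

test_that("age-driven variables decorrelate after age adjustment", {
  set.seed(31)
  n <- 500
  age <- runif(n, 20, 80)
  male <- rbinom(n, 1, 0.5)
  tab <- data.frame(age = age, male = male,
                    x = 2 + 0.1 * age + rnorm(n),
                    y = 50 - 0.5 * age + rnorm(n, 0, 3))
  expect_lt(abs(adjusted_correlation(tab, "x", "y")$r), 0.1)
  expect_lt(cor(tab$x, tab$y), -0.5)             # raw correlation is strong
})

test_that("Bland-Altman limits reproduce the arithmetic definition", {
  # hand-computed 4-pair example
  o1 <- c(5.0, 6.0, 7.0, 8.0)
  o2 <- c(5.2, 5.9, 7.4, 7.9)
  ba <- bland_altman(o1, o2)
  d <- o2 - o1
  expect_equal(ba$mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd_diff, sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sd(d), tolerance = 1e-12)
  # identical observers: degenerate agreement
  ba0 <- bland_altman(o1, o1)
  expect_equal(c(ba0$mean_diff, ba0$sd_diff, ba0$loa_low, ba0$loa_high),
               rep(0, 4))
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("Wilcoxon exact p matches full sign-assignment enumeration at n = 8", {
  a <- c(5.1, 5.8, 6.2, 6.9, 7.3, 7.8, 8.4, 9.1)
  b <- a + c(0.31, -0.12, 0.27, 0.48, -0.05, 0.23, 0.4, 0.09)
  res <- compare_methods_wilcoxon(a, b)
  # brute-force oracle: enumerate all 2^8 sign assignments of the ranked
  # absolute differences to get the exact null distribution of V
  d <- a - b
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  v_null <- signs %*% rk
  p_oracle <- mean(v_null >= max(v_obs, sum(rk) - v_obs)) +
    mean(v_null <= min(v_obs, sum(rk) - v_obs))
  expect_equal(res$p.value, p_oracle, tolerance = 1e-12)
  # sign symmetry
  expect_equal(compare_methods_wilcoxon(b, a)$p.value, res$p.value)
  expect_error(compare_methods_wilcoxon(a, a), "zero")
})

test_that("Wilcoxon detects a constant location shift at n = 30", {
  set.seed(12)
  a <- rnorm(30, 6, 1)
  b <- a + 0.5 + rnorm(30, 0, 0.1)
  expect_lt(compare_methods_wilcoxon(a, b)$p.value, 0.01)
})
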