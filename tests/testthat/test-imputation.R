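test_that("coefficient-to-OR uses the unbiased lognormal mean", {
  expect_equal(or_from_coefficient(0, 0), 1)
  expect_equal(or_from_coefficient(log(2), 0), 2)
  expect_equal(or_from_coefficient(0.5, 0.3), exp(0.545))
  expect_error(or_from_coefficient(Inf, 0.1), "finite")
  expect_error(or_from_coefficient(0.5, -0.1), ">= 0")
})

test_that("CI inversion reproduces known (mu, sigma) and the printed bounds", {
  expect_equal(sigma_from_ci(1, 1, 1), list(mu = 0, sigma = 0))
  # round-trip oracle: construct the interval from known parameters
  mu <- 0.4; sigma <- 0.2
  lo <- exp(mu + sigma^2 / 2 - 1.96 * sigma)
  hi <- exp(mu + sigma^2 / 2 + 1.96 * sigma)
  got <- sigma_from_ci(exp(mu + sigma^2 / 2), lo, hi)
  expect_equal(got$mu, mu, tolerance = 1e-10)
  expect_equal(got$sigma, sigma, tolerance = 1e-10)
  # closed-form hand evaluation
  got2 <- sigma_from_ci(2, 1, 4)
  expect_equal(got2$sigma, log(4) / (2 * 1.96), tolerance = 1e-12)
  expect_equal(got2$mu, log(2) - (log(4) / (2 * 1.96))^2 / 2, tolerance = 1e-12)
  expect_error(sigma_from_ci(2, -1, 4), "positive")
})

test_that("CI round-trip is the identity over random parameters", {
  set.seed(4)
  for (i in 1:50) {
    mu <- runif(1, -2, 2); sigma <- runif(1, 0, 1)
    lo <- exp(mu + sigma^2 / 2 - 1.96 * sigma)
    hi <- exp(mu + sigma^2 / 2 + 1.96 * sigma)
    got <- sigma_from_ci(exp(mu + sigma^2 / 2), lo, hi)
    expect_equal(got$mu, mu, tolerance = 1e-10)
    expect_equal(got$sigma, sigma, tolerance = 1e-10)
  }
})

test_that("Altman-Bland conversion matches its spot values and monotonicity", {
  got <- sigma_from_pvalue(0.05, log(2))
  expect_equal(got$z, 1.9566, tolerance = 1e-4)
  expect_equal(got$sigma, log(2) / got$z)
  expect_lt(abs(got$z - qnorm(0.975)), 0.01)
  got2 <- sigma_from_pvalue(0.01, 1)
  expect_equal(got2$z, 2.5751, tolerance = 1e-4)
  expect_lt(abs(got2$z - qnorm(0.995)), 0.01)
  expect_lt(sigma_from_pvalue(0.01, log(2))$sigma,
            sigma_from_pvalue(0.05, log(2))$sigma)
  expect_error(sigma_from_pvalue(0, log(2)), "\\(0, 1\\)")
  expect_error(sigma_from_pvalue(1, log(2)), "\\(0, 1\\)")
  expect_error(sigma_from_pvalue(0.05, 0), "nonzero")
})

test_that("Altman-Bland z tracks the exact normal quantile to 0.02 on [1e-3, 0.5]", {
  p <- exp(seq(log(1e-3), log(0.5), length.out = 200))
  z_ab <- -0.862 + sqrt(0.743 - 2.404 * log(p))
  expect_true(all(abs(z_ab - qnorm(1 - p / 2)) < 0.02))
})

test_that("contingency reconstruction recovers the worked example", {
  tab <- solve_contingency(30, 170, 2.0, pearson_chi2(20, 80, 10, 90), ">1")
  expect_equal(tab$a, 20, tolerance = 1e-6)
  expect_equal(tab$b, 80, tolerance = 1e-6)
  expect_equal(tab$c, 10, tolerance = 1e-6)
  expect_equal(tab$d, 90, tolerance = 1e-6)
  expect_lt(max(tab$residuals), 1e-8)
  expect_error(solve_contingency(30, 170, 1.0, 0), "degenerate")
  expect_error(solve_contingency(30, 170, 2.0, 1e6), "inconsistent")
})

test_that("reconstructed tables satisfy all four equations on random inputs", {
  set.seed(12)
  n_done <- 0
  while (n_done < 60) {
    cells <- as.numeric(sample(1:500, 4, replace = TRUE))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    if (a * d == b * c) next
    r <- (a / (a + b)) / (c / (c + d))
    tab <- solve_contingency(a + c, b + d, r, pearson_chi2(a, b, c, d),
                             if (a * d / (b * c) > 1) ">1" else "<1")
    expect_lt(max(tab$residuals), 1e-8)
    expect_equal(tab$a + tab$c, a + c)          # marginals hold exactly
    expect_equal(tab$b + tab$d, b + d)
    expect_true((tab$or > 1) == (a * d / (b * c) > 1))
    n_done <- n_done + 1
  }
})

test_that("log odds-ratio variance is the sum of reciprocal cells", {
  expect_equal(var_logor_from_table(c(20, 80, 10, 90)),
               1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  expect_equal(var_logor_from_table(c(10, 10, 10, 10)), 0.4)
  cells <- c(7, 13, 29, 31)
  expect_equal(var_logor_from_table(2 * cells), var_logor_from_table(cells) / 2)
  expect_error(var_logor_from_table(c(0, 1, 2, 3)), "positive")
})

test_that("exactly one imputation method fires per estimate, by precedence", {
  tab <- validate_studies(rbind(
    est_row("S1", "f1", "hi", value = 2.0, se = 0.3,
            ci_low = 1.1, ci_high = 3.6),            # se wins over CI
    est_row("S1", "f2", "hi", value = 1.8, ci_low = 1.2, ci_high = 2.7,
            p_value = 0.01),                         # CI wins over p
    est_row("S1", "f3", "hi", value = 1.5, p_value = 0.03,
            chi2 = 4.1, n_cases = 100, n_controls = 200),  # p wins over chi2
    est_row("S1", "f4", "hi", value = 2.0, chi2 = pearson_chi2(20, 80, 10, 90),
            n_cases = 30, n_controls = 170),
    est_row("S1", "f5", "hi", estimate_type = "coefficient", value = 0.5,
            se = 0.3)))
  imp <- impute_estimates(tab)
  expect_equal(imp$imp_method,
               c("reported", "from_ci", "from_pvalue", "from_chi2",
                 "from_coefficient"))
  # the trace carries z only for the p-value path, cells only for chi2
  expect_true(all(is.na(imp$imp_z) == (imp$imp_method != "from_pvalue")))
  expect_true(all(is.na(imp$imp_a) == (imp$imp_method != "from_chi2")))
  expect_equal(imp$sigma[1], 0.3)
  expect_equal(imp$mu[1], log(2) - 0.3^2 / 2)        # lognormal mean = reported OR
  expect_equal(imp$sigma[4], sqrt(var_logor_from_table(c(20, 80, 10, 90))),
               tolerance = 1e-6)
  expect_equal(imp$or_point[5], or_from_coefficient(0.5, 0.3))
  expect_error(impute_estimates(validate_studies(est_row(value = 2))),
               "no variability")
})

test_that("prevalence imputation follows the tier fallback chain", {
  studies <- validate_studies(rbind(
    est_row("S1", "f1", "hi", se = 0.2, control_prevalence = 0.2),
    est_row("S2", "f1", "hi", se = 0.2, control_prevalence = 0.4),
    est_row("S3", "f2", "hi", se = 0.2)))
  fallback <- validate_prevalence(prev_binary("f2", 0.3, tier = 1))
  got <- impute_prevalence("f1", "hi", studies)
  expect_equal(got$prevalence, 0.3)      # unweighted mean of 0.2 and 0.4
  expect_equal(got$tier, 4L)
  # own study excluded from the averaging
  got_excl <- impute_prevalence("f1", "hi", studies, exclude_study = "S2")
  expect_equal(got_excl$prevalence, 0.2)
  # no study source: external fallback with its own tier
  got2 <- impute_prevalence("f2", "hi", studies, fallback)
  expect_equal(got2$prevalence, 0.3)
  expect_equal(got2$tier, 1L)
  # absent everywhere: exclusion signal
  got3 <- impute_prevalence("f9", "hi", studies, fallback)
  expect_true(got3$excluded)
})
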