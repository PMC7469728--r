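cfg0 <- model_config(n_reps = 1000, prevalence_cv = 0, seed = 42)

single_factor_study <- function(or = 2, sigma = 0.3, p_hi = 0.5) {
  st <- impute_estimates(validate_studies(rbind(
    est_row("S1", "f1", "hi", value = or, se = sigma),
    est_row("S1", "f2", "hi", value = 1, se = 0))))  # second factor inert
  prev <- validate_prevalence(rbind(prev_binary("f1", p_hi),
                                    prev_binary("f2", 0.5)))
  list(st = st, prev = prev)
}

test_that("configuration invariants are enforced", {
  expect_error(model_config(r0 = 0), "\\(0, 1\\)")
  expect_error(model_config(n_reps = 10), "at least 100")
  expect_error(model_config(prevalence_cv = -0.1), ">= 0")
  expect_equal(model_config()$r0, 0.000094)
  expect_equal(model_config()$n_reps, 10000L)
  expect_equal(model_config()$prevalence_cv, 0.1)
})

test_that("baseline calibration divides out the prevalence-weighted OR product", {
  fx <- single_factor_study(or = 2, p_hi = 0.5)
  b <- baseline_risk(fx$st, fx$prev, cfg0)
  expect_equal(b, 0.000094 / 2^0.5, tolerance = 1e-12)
  # all ORs 1: baseline equals the population incidence
  inert <- single_factor_study(or = 1)
  expect_equal(baseline_risk(inert$st, inert$prev, cfg0), 0.000094)
  # two independent factors multiply in the denominator (brute-force product)
  st2 <- impute_estimates(validate_studies(rbind(
    est_row("S1", "f1", "hi", value = 2, se = 0.1),
    est_row("S1", "f2", "hi", value = 3, se = 0.1))))
  prev2 <- validate_prevalence(rbind(prev_binary("f1", 0.4), prev_binary("f2", 0.2)))
  expect_equal(baseline_risk(st2, prev2, cfg0),
               0.000094 / (2^0.4 * 3^0.2), tolerance = 1e-12)
  # missing prevalence errors naming the level
  expect_error(baseline_risk(st2, validate_prevalence(prev_binary("f1", 0.4)), cfg0),
               "f2 hi")
})

test_that("calibration identity holds exactly for random synthetic studies", {
  set.seed(5)
  for (i in 1:25) {
    n_lev <- sample(2:4, 1)
    ors <- runif(n_lev, 0.5, 5)
    p <- runif(n_lev + 1); p <- p / sum(p)
    st <- impute_estimates(validate_studies(do.call(rbind, c(
      lapply(seq_len(n_lev), function(j)
        est_row("S1", "f1", paste0("L", j), value = ors[j], se = 0.2)),
      list(est_row("S1", "f2", "hi", value = runif(1, 0.5, 5), se = 0.2))))))
    prev <- validate_prevalence(rbind(
      data.frame(factor_id = "f1", level = c("ref", paste0("L", seq_len(n_lev))),
                 prevalence = p, tier = 1, source_note = "",
                 reference = c(TRUE, rep(FALSE, n_lev))),
      prev_binary("f2", 0.37)))
    b <- baseline_risk(st, prev, cfg0)
    key <- paste(st$factor_id, st$level)
    pr <- prev$prevalence[match(key, paste(prev$factor_id, prev$level))]
    expect_equal(b * exp(sum(pr * log(st$or_point))), 0.000094,
                 tolerance = 1e-12)
  }
})

test_that("patient-study risk multiplies the baseline by the patient's ORs", {
  fx <- single_factor_study(or = 2, p_hi = 0.5)
  b <- baseline_risk(fx$st, fx$prev, cfg0)
  ref_prof <- data.frame(patient_id = "p", f1 = "lo", f2 = "lo")
  expect_equal(patient_study_risk(ref_prof, fx$st, b, fx$prev), b)
  hi_prof <- data.frame(patient_id = "p", f1 = "hi", f2 = "lo")
  expect_equal(patient_study_risk(hi_prof, fx$st, b, fx$prev), 2 * b)
  expect_equal(2 * b, 2 * 0.000094 / sqrt(2), tolerance = 1e-12)
  expect_equal(2 * b, 1.32936e-4, tolerance = 1e-5)
  # not-applicable behaves as reference
  na_prof <- data.frame(patient_id = "p", f1 = NA, f2 = NA)
  expect_equal(patient_study_risk(na_prof, fx$st, b, fx$prev), b)
  # unmapped level is an error
  bad <- data.frame(patient_id = "p", f1 = "enormous", f2 = "lo")
  expect_error(patient_study_risk(bad, fx$st, b, fx$prev), "unmapped level")
})

test_that("Monte Carlo SE matches the analytic single-factor propagation", {
  fx <- single_factor_study(or = 2, sigma = 0.3, p_hi = 0.5)
  prof <- data.frame(patient_id = "p", f1 = "hi", f2 = "lo")
  cfg <- model_config(n_reps = 10000, prevalence_cv = 0, seed = 42)
  s <- mc_log_se(prof, fx$st, fx$prev, cfg)
  # ln R = ln R0 + (1 - p) * X with X ~ N(mu, 0.3), so SD = 0.15
  expect_lt(abs(s - 0.15) / 0.15, 0.02)
  # degenerate sampling: zero variability everywhere gives exactly zero
  fx0 <- single_factor_study(or = 2, sigma = 0)
  expect_equal(mc_log_se(prof, fx0$st, fx0$prev, cfg), 0)
  # identical seed and inputs reproduce bit-exactly; RNG state is restored
  set.seed(777); before <- runif(1)
  s2 <- mc_log_se(prof, fx$st, fx$prev, cfg)
  expect_identical(s, s2)
  set.seed(777)
  expect_identical(runif(1), before)
})

test_that("Monte Carlo SE scales linearly in sigma and stabilizes in n_reps", {
  fx <- single_factor_study(or = 2, sigma = 0.3)
  prof <- data.frame(patient_id = "p", f1 = "hi", f2 = "lo")
  st2 <- fx$st; st2$sigma <- fx$st$sigma * 2
  expect_equal(mc_log_se(prof, st2, fx$prev, cfg0),
               2 * mc_log_se(prof, fx$st, fx$prev, cfg0), tolerance = 1e-12)
  # doubling replications moves the SD within 3 Monte Carlo SEs of the SD
  cfg_a <- model_config(n_reps = 5000, prevalence_cv = 0, seed = 9)
  cfg_b <- model_config(n_reps = 10000, prevalence_cv = 0, seed = 10)
  sa <- mc_log_se(prof, fx$st, fx$prev, cfg_a)
  sb <- mc_log_se(prof, fx$st, fx$prev, cfg_b)
  mc_se <- 0.15 * sqrt(1 / (2 * 5000) + 1 / (2 * 10000))
  expect_lt(abs(sa - sb), 3 * mc_se)
})

test_that("an infeasible Beta parameterization is rejected with advice", {
  fx <- single_factor_study(or = 2, p_hi = 0.9)
  prof <- data.frame(patient_id = "p", f1 = "hi", f2 = "lo")
  cfg <- model_config(n_reps = 500, prevalence_cv = 0.5, seed = 1)
  expect_error(mc_log_se(prof, fx$st, fx$prev, cfg), "smaller prevalence_cv")
})

test_that("random-effects pooling matches the worked single- and two-study forms", {
  one <- pool_random_effects(
    data.frame(study_id = "S1", point = 1e-4, log_se = 0.2), cfg0)
  expect_equal(one$point, 1e-4)
  expect_equal(one$ci_low, exp(log(1e-4) - qnorm(0.975) * 0.2))
  expect_equal(one$ci_high, exp(log(1e-4) + qnorm(0.975) * 0.2))
  expect_equal(one$tau2, 0)
  expect_match(one$note, "single study")
  # two studies with Q <= df: tau2 truncates to zero, equal weights
  y <- c(log(1e-4), log(1.2e-4)); s <- c(0.4, 0.4)
  two <- pool_random_effects(
    data.frame(study_id = c("A", "B"), point = exp(y), log_se = s), cfg0)
  w <- 1 / s^2; Q <- sum(w * (y - sum(w * y) / sum(w))^2)
  expect_lte(Q, 1)
  expect_equal(two$tau2, 0)
  expect_equal(two$point, exp(mean(y)))
})

test_that("pooling agrees with an independent DL oracle and with metafor", {
  set.seed(31)
  for (k in c(2, 5, 11)) {
    y <- rnorm(k, log(1e-4), 0.5); s <- runif(k, 0.05, 0.4)
    got <- pool_random_effects(
      data.frame(study_id = paste0("S", 1:k), point = exp(y), log_se = s), cfg0)
    ora <- dl_oracle(y, s)
    expect_equal(got$log_point, ora$mu, tolerance = 1e-12)
    expect_equal(got$tau2, ora$tau2, tolerance = 1e-12)
    expect_equal(got$log_se, ora$se, tolerance = 1e-12)
    mf <- metafor::rma(yi = y, sei = s, method = "DL")
    expect_equal(got$log_point, as.numeric(mf$beta), tolerance = 1e-8)
    expect_equal(got$tau2, mf$tau2, tolerance = 1e-8)
  }
})

test_that("REML heterogeneity estimation matches metafor", {
  set.seed(13)
  y <- rnorm(6, log(1e-4), 0.4); s <- runif(6, 0.1, 0.3)
  cfg <- model_config(n_reps = 1000, seed = 1, re_method = "reml")
  got <- pool_random_effects(
    data.frame(study_id = paste0("S", 1:6), point = exp(y), log_se = s), cfg)
  mf <- metafor::rma(yi = y, sei = s, method = "REML")
  expect_equal(got$tau2, mf$tau2, tolerance = 1e-4)
  expect_equal(got$log_point, as.numeric(mf$beta), tolerance = 1e-6)
})

test_that("predict_risk composes the pipeline and respects monotonicity", {
  st <- impute_estimates(validate_studies(rbind(
    est_row("S1", "f1", "hi", value = 2.0, se = 0.2),
    est_row("S1", "f2", "hi", value = 1.5, se = 0.2),
    est_row("S2", "f1", "hi", value = 2.4, se = 0.3),
    est_row("S2", "f2", "hi", value = 1.2, se = 0.2))))
  prev <- validate_prevalence(rbind(prev_binary("f1", 0.3), prev_binary("f2", 0.4)))
  prof <- data.frame(patient_id = c("ref", "exposed"),
                     f1 = c("lo", "hi"), f2 = c("lo", "hi"))
  cfg <- model_config(n_reps = 800, seed = 3)
  # the all-reference patient legitimately warns: no study covers a
  # non-reference assignment
  pred <- suppressWarnings(predict_risk(prof, st, prev, cfg))
  ps <- attr(pred, "per_study")
  for (pid in pred$patient_id) {
    sub <- ps[ps$patient_id == pid, ]
    i <- which(pred$patient_id == pid)
    expect_gte(pred$point[i], min(sub$point) - 1e-15)
    expect_lte(pred$point[i], max(sub$point) + 1e-15)
    expect_lte(pred$ci_low[i], pred$point[i])
    expect_gte(pred$ci_high[i], pred$point[i])
  }
  expect_gt(pred$point[2], pred$point[1])
  # raising one OR strictly raises the exposed patient's risk, not the reference's
  st_up <- st; st_up$or_point[1] <- st$or_point[1] * 1.5
  pred_up <- suppressWarnings(predict_risk(prof, st_up, prev, cfg))
  expect_gt(pred_up$point[2], pred$point[2])
  expect_equal(pred_up$point[1] < pred$point[1], TRUE)  # baseline recalibrates down
})

test_that("all-reference profiles over inert studies recover the population risk", {
  st <- impute_estimates(validate_studies(rbind(
    est_row("S1", "f1", "hi", value = 1, se = 0),
    est_row("S1", "f2", "hi", value = 1, se = 0),
    est_row("S2", "f1", "hi", value = 1, se = 0),
    est_row("S2", "f2", "hi", value = 1, se = 0))))
  prev <- validate_prevalence(rbind(prev_binary("f1", 0.3), prev_binary("f2", 0.4)))
  prof <- data.frame(patient_id = "ref", f1 = "lo", f2 = "lo")
  cfg <- model_config(n_reps = 500, prevalence_cv = 0, seed = 2)
  w <- capture_warnings(pred <- predict_risk(prof, st, prev, cfg))
  expect_match(w, "no eligible study covers", all = FALSE)
  expect_equal(pred$point, 0.000094, tolerance = 1e-12)
  expect_equal(pred$ratio_to_r0, 1, tolerance = 1e-12)
})
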