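# Generators for synthetic study tables, prevalence tables and
# dependency-aware patient profiles. They stand in for the model's real
# inputs (per-study published estimates and population prevalence searches),
# at the same dimensionality: 11 case-control studies, 17 risk factors,
# ~140 reported risk-factor levels.

# Canonical factor layout: 17 cervical-cancer risk factors, each with one
# reference level, plus the generative pieces the profile sampler needs.
default_factor_layout <- function() {
  L <- function(factor_id, levels, ref, log_or, probs, tier) {
    data.frame(factor_id = factor_id, level = levels,
               reference = levels == ref,
               log_or = log_or, prob = probs, tier = tier,
               stringsAsFactors = FALSE)
  }
  rbind(
    L("sexual_debut", c("ge20", "17_19", "lt17"), "ge20",
      c(0, log(1.5), log(2.2)), NA, 1),
    L("sexual_partners", c("1", "2_3", "ge4"), "1",
      c(0, log(1.6), log(2.5)), c(0.62, 0.30, 0.08), 2),
    L("hpv", c("no", "yes"), "no", c(0, log(15)), c(0.85, 0.15), 2),
    L("screening_history", c("never", "1_2", "ge3"), "never",
      c(0, log(0.6), log(0.4)), c(0.55, 0.30, 0.15), 4),
    L("screening_interval", c("within_3y", "gt_3y"), "within_3y",
      c(0, log(1.5)), c(0.6, 0.4), 2),
    L("age_first_pregnancy", c("ge25", "20_24", "lt20"), "ge25",
      c(0, log(1.3), log(1.8)), NA, 1),
    L("age_first_delivery", c("ge25", "20_24", "lt20"), "ge25",
      c(0, log(1.35), log(1.9)), NA, 1),
    L("n_pregnancies", c("le1", "2", "ge3"), "le1",
      c(0, log(1.4), log(1.9)), c(0.40, 0.35, 0.25), 1),
    L("n_deliveries", c("le1", "2", "ge3"), "le1",
      c(0, log(1.45), log(2.0)), c(0.55, 0.30, 0.15), 1),
    L("contraception", c("none", "iud", "condom"), "none",
      c(0, log(1.3), log(0.7)), c(0.50, 0.40, 0.10), 1),
    L("years_iud", c("none", "lt10", "ge10"), "none",
      c(0, log(1.2), log(1.5)), NA, 2),
    L("menopause", c("no", "yes"), "no", c(0, log(1.6)), c(0.70, 0.30), 1),
    L("poor_hygiene", c("no", "yes"), "no", c(0, log(1.8)), c(0.65, 0.35), 2),
    L("smoking", c("never", "ci_le100", "ci_gt100"), "never",
      c(0, log(1.5), log(2.1)), NA, 1),
    L("secondhand_smoke", c("no", "yes"), "no", c(0, log(1.4)), c(0.55, 0.45), 2),
    L("education", c("college", "high", "middle", "low"), "college",
      c(0, log(1.3), log(1.6), log(2.0)), c(0.12, 0.18, 0.40, 0.30), 1),
    L("intellectual_job", c("yes", "no"), "yes", c(0, log(1.4)), c(0.25, 0.75), 1))
}

#' Synthetic-data generator specification
#'
#' Defines the study conditions the generators emulate: 11 case-control
#' studies over 17 cervical-cancer risk factors with partially overlapping
#' factor coverage, lognormally distributed odds ratios whose variability
#' information is censored into the four reporting patterns the imputation
#' module handles (full 95% CI, p-value only, chi-square + totals only,
#' regression coefficient only), a population-prevalence simplex per factor,
#' and high-level dependencies between age-like attributes (first pregnancy
#' at least 9 months after sexual debut, delivery 9 months after pregnancy,
#' IUD duration only for IUD users, gestational factors not applicable to
#' never-pregnant women). HPV infection is generated with a dominant true
#' odds ratio (15) so that its outsized influence on prediction accuracy and
#' precision is a reproducible property of the default conditions.
#'
#' @param n_studies number of studies (default 11).
#' @param between_sd between-study SD of the log odds ratios (default 0.15).
#' @param report_probs named probabilities of the reporting patterns
#'   `ci`, `p`, `chi2`, `coef` (must sum to 1).
#' @param sigma_range range of the baseline per-estimate SEs of the log odds
#'   ratio (drawn uniformly).
#' @param sigma_logor_scale how strongly the SE of a log odds ratio grows
#'   with its magnitude: the drawn SE is multiplied by
#'   `1 + sigma_logor_scale * |true log OR|`. Extreme odds ratios in
#'   case-control data come from sparse exposed cells, whose Woolf variance
#'   grows with the effect size; this keeps the dominant-OR factor (HPV) also
#'   the dominant uncertainty source.
#' @param factors_per_study integer range of distinct factors per study
#'   (minimum 2 enforced).
#' @param n_cases_range,n_controls_range ranges of per-study totals.
#' @param hpv_inclusion_prob probability that a study reports the HPV factor.
#' @param dup_unadjusted_prob probability that an estimate is accompanied by
#'   a univariate (unadjusted) duplicate, exercising the multivariate-
#'   preference filter.
#' @param control_prev_prob probability that a row carries a control-group
#'   prevalence (feeds the tier-4 prevalence imputation path).
#' @param ever_pregnant probability that a profile has any pregnancy
#'   (1 - natural infertility rate of 17.14%).
#' @param min_gap minimum years between sexual debut and first pregnancy,
#'   and between first pregnancy and first delivery (9 months = 0.75).
#' @param seed generator seed.
#' @return a `cc_generator_spec` list, including the canonical factor layout
#'   (`$layout`) and the true log odds ratios (`$truth`).
#' @export
generator_spec <- function(n_studies = 11, between_sd = 0.15,
                           report_probs = c(ci = 0.55, p = 0.20,
                                            chi2 = 0.15, coef = 0.10),
                           sigma_range = c(0.12, 0.35),
                           sigma_logor_scale = 0.35,
                           factors_per_study = c(5, 10),
                           n_cases_range = c(120, 400),
                           n_controls_range = c(200, 800),
                           hpv_inclusion_prob = 0.8,
                           dup_unadjusted_prob = 0.05,
                           control_prev_prob = 0.3,
                           ever_pregnant = 1 - 0.1714,
                           min_gap = 0.75,
                           seed = 1L) {
  if (abs(sum(report_probs) - 1) > 1e-8) stop("report_probs must sum to 1")
  if (!all(c("ci", "p", "chi2", "coef") %in% names(report_probs)))
    stop("report_probs needs entries ci, p, chi2, coef")
  if (factors_per_study[1] < 2) stop("each study needs at least 2 factors")
  layout <- default_factor_layout()
  spec <- list(
    n_studies = n_studies, between_sd = between_sd,
    report_probs = report_probs, sigma_range = sigma_range,
    sigma_logor_scale = sigma_logor_scale,
    factors_per_study = factors_per_study,
    n_cases_range = n_cases_range, n_controls_range = n_controls_range,
    hpv_inclusion_prob = hpv_inclusion_prob,
    dup_unadjusted_prob = dup_unadjusted_prob,
    control_prev_prob = control_prev_prob,
    ever_pregnant = ever_pregnant, min_gap = min_gap,
    seed = as.integer(seed),
    layout = layout,
    truth = layout[!layout$reference, c("factor_id", "level", "log_or")],
    # continuous attribute models (years)
    debut = list(mean = 18.5, sd = 2.2, lower = 14, upper = 35),
    preg = list(mean = 23, sd = 3),
    smoker_prob = 0.024,
    cigindex = list(meanlog = log(120), sdlog = 0.8, cut = 100),
    iud_years = list(meanlog = log(8), sdlog = 0.6, cut = 10))
  class(spec) <- "cc_generator_spec"
  spec
}

# truncated-normal helpers (inverse-CDF sampling keeps bin probabilities exact)
tnorm_cdf <- function(q, m, s, lo, hi) {
  plo <- pnorm(lo, m, s); phi <- pnorm(hi, m, s)
  pmin(pmax((pnorm(q, m, s) - plo) / (phi - plo), 0), 1)
}
tnorm_draw <- function(n, m, s, lo, hi) {
  u <- runif(n, pnorm(lo, m, s), pnorm(hi, m, s))
  qnorm(u, m, s)
}

# P(first pregnancy age in [l, u)) marginalized over debut, where pregnancy
# age | debut is Normal(preg) left-truncated at debut + min_gap
preg_bin_prob <- function(spec, l, u) {
  d <- spec$debut; pg <- spec$preg; gap <- spec$min_gap
  f <- function(x) {
    lo <- x + gap
    denom <- 1 - pnorm(lo, pg$mean, pg$sd)
    num <- pnorm(u, pg$mean, pg$sd) - pnorm(pmax(l, lo), pg$mean, pg$sd)
    num <- pmax(num, 0)
    dens <- dnorm(x, d$mean, d$sd) /
      (pnorm(d$upper, d$mean, d$sd) - pnorm(d$lower, d$mean, d$sd))
    ifelse(denom <= 0, 0, num / denom) * dens
  }
  stats::integrate(f, d$lower, d$upper, rel.tol = 1e-9)$value
}

#' Population-prevalence table implied by a generator spec
#'
#' Closed-form (or numerically integrated) marginal prevalences of every
#' factor level under the profile-generation process, so that empirical level
#' frequencies of [generate_profiles()] match this table up to sampling
#' error. Not-applicable states (never pregnant, no IUD) are folded into the
#' reference level, which is exactly how the risk equations treat them.
#'
#' @param spec a `cc_generator_spec`.
#' @return a `cc_prevalence` table.
#' @export
spec_prevalence <- function(spec) {
  lay <- spec$layout
  d <- spec$debut
  p_lt17 <- tnorm_cdf(17, d$mean, d$sd, d$lower, d$upper)
  p_1719 <- tnorm_cdf(20, d$mean, d$sd, d$lower, d$upper) - p_lt17
  pe <- spec$ever_pregnant
  pr_lt20 <- preg_bin_prob(spec, -Inf, 20)
  pr_2024 <- preg_bin_prob(spec, 20, 25)
  # delivery age = pregnancy age + min_gap: shift the bin edges
  dl_lt20 <- preg_bin_prob(spec, -Inf, 20 - spec$min_gap)
  dl_2024 <- preg_bin_prob(spec, 20 - spec$min_gap, 25 - spec$min_gap)
  smk <- spec$smoker_prob
  p_le100 <- plnorm(spec$cigindex$cut, spec$cigindex$meanlog, spec$cigindex$sdlog)
  iud <- lay$prob[lay$factor_id == "contraception" & lay$level == "iud"]
  p_iud_lt10 <- plnorm(spec$iud_years$cut, spec$iud_years$meanlog, spec$iud_years$sdlog)
  pp <- lay$prob[lay$factor_id == "n_pregnancies"]  # conditional on ever pregnant
  pd <- lay$prob[lay$factor_id == "n_deliveries"]

  probs <- list(
    sexual_debut = c(ge20 = 1 - p_lt17 - p_1719, `17_19` = p_1719, lt17 = p_lt17),
    age_first_pregnancy = c(ge25 = 1 - pe * (pr_lt20 + pr_2024),
                            `20_24` = pe * pr_2024, lt20 = pe * pr_lt20),
    age_first_delivery = c(ge25 = 1 - pe * (dl_lt20 + dl_2024),
                           `20_24` = pe * dl_2024, lt20 = pe * dl_lt20),
    n_pregnancies = c(le1 = (1 - pe) + pe * pp[1], `2` = pe * pp[2], ge3 = pe * pp[3]),
    n_deliveries = c(le1 = (1 - pe) + pe * pd[1], `2` = pe * pd[2], ge3 = pe * pd[3]),
    smoking = c(never = 1 - smk, ci_le100 = smk * p_le100,
                ci_gt100 = smk * (1 - p_le100)),
    years_iud = c(none = 1 - iud, lt10 = iud * p_iud_lt10,
                  ge10 = iud * (1 - p_iud_lt10)))
  out <- lay[, c("factor_id", "level", "reference", "tier")]
  out$prevalence <- NA_real_
  for (i in seq_len(nrow(out))) {
    f <- out$factor_id[i]
    out$prevalence[i] <- if (f %in% names(probs)) probs[[f]][[out$level[i]]]
      else lay$prob[i]
  }
  out$source_note <- "synthetic population (generator spec)"
  validate_prevalence(out[, c("factor_id", "level", "prevalence", "tier",
                              "source_note", "reference")])
}

# construct a fractional 2x2 table with given totals, control exposure b and
# cell-proportion ratio r; returns NULL when infeasible
make_table_from_ratio <- function(N1, N0, b, r) {
  A <- 1 - r
  B <- r * N1 - N1 - N0 + b * (1 - r)
  C <- r * N1 * b
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(NULL)
  roots <- if (abs(A) < 1e-12) -C / B else (-B + c(1, -1) * sqrt(disc)) / (2 * A)
  for (a in roots) {
    c <- N1 - a; d <- N0 - b
    if (is.finite(a) && a > 1e-6 && c > 1e-6 && d > 1e-6)
      return(list(a = a, b = b, c = c, d = d))
  }
  NULL
}

#' Generate a synthetic multi-study estimates table
#'
#' Each study reports a random subset (at least two) of the 17 factors; its
#' log odds ratio for every non-reference level is the generative truth plus
#' Normal(0, between-study SD) noise, and its variability information is then
#' censored into one of the four reporting patterns so that every imputation
#' path is exercised: full 95% CI, p-value only, chi-square statistic with
#' case/control totals only, or regression coefficient with SE. Reported
#' values are constructed to be exactly invertible where the pattern allows
#' it (CI and coefficient patterns reproduce the study's log odds ratio and
#' SE; the p-value pattern is limited by the accuracy of the Altman-Bland
#' approximation; the chi-square pattern by the two-root ambiguity of the
#' contingency system).
#'
#' @param spec a `cc_generator_spec`.
#' @return list with `studies` (a validated `cc_studies`), `prevalence`
#'   (a `cc_prevalence`), and `truth` (data frame of generative per-level log
#'   odds ratios plus per-study realized values).
#' @export
generate_studies <- function(spec = generator_spec()) {
  prevalence <- spec_prevalence(spec)
  lay <- spec$layout
  nonref <- lay[!lay$reference, ]
  with_local_seed(spec$seed, {
    rows <- list(); truth_rows <- list()
    for (k in seq_len(spec$n_studies)) {
      sid <- sprintf("S%02d", k)
      n_f <- sample(seq(spec$factors_per_study[1], spec$factors_per_study[2]), 1)
      facs <- unique(lay$factor_id)
      chosen <- character(0)
      if (runif(1) < spec$hpv_inclusion_prob) chosen <- "hpv"
      chosen <- c(chosen, sample(setdiff(facs, chosen), n_f - length(chosen)))
      N1 <- sample(seq(spec$n_cases_range[1], spec$n_cases_range[2]), 1)
      N0 <- sample(seq(spec$n_controls_range[1], spec$n_controls_range[2]), 1)
      sub <- nonref[nonref$factor_id %in% chosen, ]
      for (i in seq_len(nrow(sub))) {
        lor <- sub$log_or[i] + rnorm(1, 0, spec$between_sd)
        sig <- runif(1, spec$sigma_range[1], spec$sigma_range[2]) *
          (1 + spec$sigma_logor_scale * abs(sub$log_or[i]))
        pat <- sample(names(spec$report_probs), 1, prob = spec$report_probs)
        pkey <- prevalence$factor_id == sub$factor_id[i]
        p_lev <- prevalence$prevalence[pkey & prevalence$level == sub$level[i]]
        p_ref <- prevalence$prevalence[pkey & prevalence$reference]
        p0 <- p_lev / (p_lev + p_ref)
        row <- data.frame(
          study_id = sid, factor_id = sub$factor_id[i], level = sub$level[i],
          estimate_type = "or", value = exp(lor),
          ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
          chi2 = NA_real_, n_cases = NA_real_, n_controls = NA_real_,
          adjusted = TRUE, se = NA_real_,
          control_prevalence = NA_real_, stringsAsFactors = FALSE)
        if (pat == "p") {
          p <- 2 * pnorm(-abs(lor) / sig)
          if (p < 1e-12 || abs(lor) < 1e-6) pat <- "ci" else row$p_value <- p
        }
        if (pat == "chi2") {
          tab <- make_table_from_ratio(N1, N0, N0 * p0, exp(lor))
          ch <- if (is.null(tab)) 0 else ct_chi2(tab$a, tab$b, tab$c, tab$d)
          if (is.null(tab) || ch < 0.05 || abs(lor) < 0.05) pat <- "ci"
          else { row$chi2 <- ch; row$n_cases <- N1; row$n_controls <- N0 }
        }
        if (pat == "coef") {
          row$estimate_type <- "coefficient"
          row$value <- lor - sig^2 / 2
          row$se <- sig
        }
        if (pat == "ci") {
          row$ci_low <- exp(lor) * exp(-1.96 * sig)
          row$ci_high <- exp(lor) * exp(1.96 * sig)
        }
        if (runif(1) < spec$control_prev_prob)
          row$control_prevalence <- min(max(p0 * runif(1, 0.9, 1.1), 1e-4), 0.999)
        rows[[length(rows) + 1]] <- row
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          study_id = sid, factor_id = sub$factor_id[i], level = sub$level[i],
          true_log_or = sub$log_or[i], realized_log_or = lor,
          realized_sigma = sig, pattern = pat, stringsAsFactors = FALSE)
        if (runif(1) < spec$dup_unadjusted_prob) {
          dup <- row
          dup$adjusted <- FALSE
          dup$value <- if (row$estimate_type == "coefficient")
            row$value * 1.2 else exp(lor * 1.2)
          rows[[length(rows) + 1]] <- dup
        }
      }
    }
    studies <- validate_studies(do.call(rbind, rows))
    list(studies = studies, prevalence = prevalence,
         truth = list(levels = spec$truth,
                      estimates = do.call(rbind, truth_rows)))
  })
}

#' Generate dependency-aware synthetic patient profiles
#'
#' Samples `n` profiles from the generator's population model: categorical
#' levels are drawn from the population prevalence simplex of each factor;
#' age-like quantities (sexual debut, age at first pregnancy/delivery) are
#' drawn continuously and constrained by rejection so that the first
#' pregnancy falls at least 9 months (`spec$min_gap` years) after sexual
#' debut and the first delivery 9 months after the pregnancy; a fraction of
#' profiles is never pregnant and carries not-applicable gestational entries;
#' IUD duration exists only for IUD users; the cigarette index (cigarettes
#' per day times years smoked) is drawn lognormally for smokers and then
#' discretized. Continuous values are kept in the `"continuous"` attribute.
#'
#' @param spec a `cc_generator_spec`.
#' @param n number of profiles.
#' @param max_attempts bound on rejection redraws for the age constraints.
#' @return a `cc_profiles` data frame (`patient_id` plus one column per
#'   factor; `NA` = not applicable).
#' @export
generate_profiles <- function(spec = generator_spec(), n = 100,
                              max_attempts = 1000) {
  lay <- spec$layout
  if (n == 0) {
    out <- as.data.frame(setNames(
      c(list(character(0)), rep(list(character(0)), length(unique(lay$factor_id)))),
      c("patient_id", unique(lay$factor_id))))
    class(out) <- c("cc_profiles", "data.frame")
    return(out)
  }
  draw_cat <- function(factor_id, n) {
    sub <- lay[lay$factor_id == factor_id, ]
    sample(sub$level, n, replace = TRUE, prob = sub$prob)
  }
  with_local_seed(spec$seed + 1L, {
    d <- spec$debut; pg <- spec$preg
    debut <- tnorm_draw(n, d$mean, d$sd, d$lower, d$upper)
    # first pregnancy: Normal, rejected below debut + min_gap
    preg_age <- rnorm(n, pg$mean, pg$sd)
    attempts <- 0
    repeat {
      bad <- which(preg_age < debut + spec$min_gap)
      if (!length(bad)) break
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop("could not satisfy the pregnancy-after-debut constraint after ",
             max_attempts, " rejection rounds")
      preg_age[bad] <- rnorm(length(bad), pg$mean, pg$sd)
    }
    deliv_age <- preg_age + spec$min_gap
    ever <- runif(n) < spec$ever_pregnant
    bin_age <- function(x) ifelse(x < 20, "lt20", ifelse(x < 25, "20_24", "ge25"))
    contraception <- draw_cat("contraception", n)
    iud_years <- exp(rnorm(n, spec$iud_years$meanlog, spec$iud_years$sdlog))
    smoker <- runif(n) < spec$smoker_prob
    cig_index <- exp(rnorm(n, spec$cigindex$meanlog, spec$cigindex$sdlog))

    out <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      sexual_debut = ifelse(debut < 17, "lt17", ifelse(debut < 20, "17_19", "ge20")),
      sexual_partners = draw_cat("sexual_partners", n),
      hpv = draw_cat("hpv", n),
      screening_history = draw_cat("screening_history", n),
      screening_interval = draw_cat("screening_interval", n),
      age_first_pregnancy = ifelse(ever, bin_age(preg_age), NA_character_),
      age_first_delivery = ifelse(ever, bin_age(deliv_age), NA_character_),
      n_pregnancies = ifelse(ever, draw_cat("n_pregnancies", n), NA_character_),
      n_deliveries = ifelse(ever, draw_cat("n_deliveries", n), NA_character_),
      contraception = contraception,
      years_iud = ifelse(contraception == "iud",
                         ifelse(iud_years < spec$iud_years$cut, "lt10", "ge10"),
                         NA_character_),
      menopause = draw_cat("menopause", n),
      poor_hygiene = draw_cat("poor_hygiene", n),
      smoking = ifelse(smoker,
                       ifelse(cig_index <= spec$cigindex$cut, "ci_le100", "ci_gt100"),
                       "never"),
      secondhand_smoke = draw_cat("secondhand_smoke", n),
      education = draw_cat("education", n),
      intellectual_job = draw_cat("intellectual_job", n),
      stringsAsFactors = FALSE)
    attr(out, "continuous") <- data.frame(
      patient_id = out$patient_id, debut_age = debut,
      pregnancy_age = ifelse(ever, preg_age, NA_real_),
      delivery_age = ifelse(ever, deliv_age, NA_real_),
      iud_years = ifelse(contraception == "iud", iud_years, NA_real_),
      cigarette_index = ifelse(smoker, cig_index, NA_real_))
    class(out) <- c("cc_profiles", "data.frame")
    out
  })
}

#' Eight hypothetical patient profiles
#'
#' The packaged validation fixture: eight hand-crafted profiles of Chinese
#' women spanning low- to high-risk combinations of the 17 factors (three
#' HPV-positive, one with every factor at reference or not applicable),
#' encoded into the canonical level layout of [generator_spec()]. The raw
#' attribute values (exact ages, smear counts, cigarette indices) are kept in
#' the `"raw"` attribute; `NA` means the factor is not applicable to that
#' woman (e.g. gestational factors when never pregnant) and acts as the
#' reference level in the risk equations.
#'
#' @return a `cc_profiles` data frame with 8 rows.
#' @export
table1_fixture <- function() {
  out <- data.frame(
    patient_id = paste0("profile_", 1:8),
    sexual_debut      = c("17_19", "ge20", "lt17", "17_19", "17_19", "ge20", "ge20", "17_19"),
    sexual_partners   = c("2_3", "2_3", "1", "2_3", "1", "1", "2_3", "1"),
    hpv               = c("yes", "no", "yes", "no", "no", "no", "yes", "no"),
    screening_history = c("ge3", NA, NA, "1_2", NA, "1_2", NA, NA),
    screening_interval = c("within_3y", NA, NA, NA, NA, "within_3y", NA, NA),
    age_first_pregnancy = c("20_24", "20_24", NA, "ge25", "lt20", "ge25", "20_24", NA),
    age_first_delivery  = c("20_24", "20_24", NA, "ge25", "lt20", "ge25", "20_24", NA),
    n_pregnancies     = c("le1", "2", NA, "le1", "ge3", "le1", "2", NA),
    n_deliveries      = c("le1", "le1", NA, "le1", "2", "le1", "2", NA),
    contraception     = c("condom", "none", "condom", "none", "iud", "iud", "none", "none"),
    years_iud         = c(NA, NA, NA, NA, "ge10", "lt10", NA, NA),
    menopause         = c("no", "no", "no", "no", "yes", "no", "yes", "no"),
    poor_hygiene      = c("yes", "yes", "no", "no", "no", "yes", "no", "no"),
    smoking           = c("ci_le100", "ci_gt100", "never", "never", "never", "ci_le100", "never", "never"),
    secondhand_smoke  = c("yes", "no", "yes", "no", "yes", "yes", "yes", "no"),
    education         = c("low", "college", "middle", "high", "low", "high", "middle", "low"),
    intellectual_job  = c("no", "no", "yes", "no", "no", "yes", "no", "yes"),
    stringsAsFactors = FALSE)
  attr(out, "raw") <- data.frame(
    patient_id = out$patient_id,
    age_sexual_debut = c(19, 20, 16, 19, 18, 21, 20, 19),
    lifetime_partners = c(2, 2, 1, 3, 1, 1, 3, 1),
    non_marital_partners = c(1, 1, 0, 1, 0, 0, 1, 1),
    negative_smears = c(4, NA, NA, 1, NA, 2, NA, NA),
    years_since_last_smear = c(2, NA, NA, NA, NA, 1, NA, NA),
    age_first_pregnancy = c(21, 21.5, NA, 27, 18, 25, 20, NA),
    age_first_delivery = c(22, 22.5, NA, 28, 19, 26, 21, NA),
    n_pregnancies = c(1, 2, NA, 1, 3, 1, 2, NA),
    n_deliveries = c(1, 1, NA, 1, 2, 1, 2, NA),
    iud_years = c(NA, NA, NA, NA, 15, 9, NA, NA),
    cigarette_index = c(50, 250, NA, NA, NA, 50, NA, NA),
    education_code = c(1, 5, 3, 4, 1, 4, 3, 1))
  class(out) <- c("cc_profiles", "data.frame")
  out
}
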