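# The meta-model core: per-study baseline calibration, patient x study risk,
# Monte Carlo within-study SE, random-effects pooling of per-study log-risks.

#' Model configuration
#'
#' @param r0 population probability of cervical cancer for a Chinese woman
#'   aged 18-85 at the time of assessment (default 0.000094).
#' @param n_reps Monte Carlo replications per (patient, study) (default
#'   10000; at least 100).
#' @param prevalence_cv coefficient of variation assumed for every prevalence
#'   estimate when sampling (default 0.1; 0 disables prevalence sampling).
#' @param seed integer RNG seed; every (patient, study) Monte Carlo run uses
#'   a substream derived deterministically from (seed, study id), so removing
#'   a study never shifts another study's draws.
#' @param ci_level confidence level for pooled intervals (default 0.95).
#' @param re_method between-study variance estimator: `"dl"`
#'   (DerSimonian-Laird, default) or `"reml"` (restricted maximum
#'   likelihood).
#' @param pool_scale scale for the odds-ratio ranking pooling (`"or"` or
#'   `"log"`), see [pool_or()].
#' @return a validated `cc_config` list.
#' @export
model_config <- function(r0 = 0.000094, n_reps = 10000, prevalence_cv = 0.1,
                         seed = 1L, ci_level = 0.95,
                         re_method = c("dl", "reml"),
                         pool_scale = c("or", "log")) {
  re_method <- match.arg(re_method)
  pool_scale <- match.arg(pool_scale)
  if (!is.finite(r0) || r0 <= 0 || r0 >= 1) stop("r0 must lie in (0, 1)")
  if (n_reps < 100) stop("n_reps must be at least 100")
  if (prevalence_cv < 0) stop("prevalence_cv must be >= 0")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  structure(list(r0 = r0, n_reps = as.integer(n_reps),
                 prevalence_cv = prevalence_cv, seed = as.integer(seed),
                 ci_level = ci_level, re_method = re_method,
                 pool_scale = pool_scale),
            class = "cc_config")
}

# prevalence lookup for the non-reference levels estimated by one study,
# errors naming any missing level
study_prevalences <- function(study_est, prevalence) {
  prev <- as.data.frame(prevalence)
  key <- paste(study_est$factor_id, study_est$level)
  idx <- match(key, paste(prev$factor_id, prev$level))
  if (anyNA(idx))
    stop("no prevalence for level(s): ",
         paste(key[is.na(idx)], collapse = ", "))
  prev$prevalence[idx]
}

#' Per-study baseline risk of the reference patient
#'
#' Each study's odds ratios describe risk relative to that study's reference
#' patient (all factors at reference levels), while the population incidence
#' `r0` describes the average woman. The baseline divides `r0` by the relative
#' risk of the average woman versus the reference patient, computed as the
#' product of the study's odds ratios geometrically weighted by the population
#' prevalence of each level:
#' \deqn{R_{0k} = R_0 / \exp\left(\sum_{\mathrm{levels}\ l} p_l \log OR_l\right)}
#' Reference levels contribute nothing (log OR = 0).
#'
#' @param study_est imputed estimate rows of one study.
#' @param prevalence a `cc_prevalence` table covering every estimated level.
#' @param config a `cc_config`.
#' @return the baseline risk R0k.
#' @export
baseline_risk <- function(study_est, prevalence, config) {
  study_est <- as.data.frame(study_est)
  if (!"or_point" %in% names(study_est) || anyNA(study_est$or_point))
    stop("study estimates must be imputed first (impute_estimates)")
  p <- study_prevalences(study_est, prevalence)
  config$r0 / exp(sum(p * log(study_est$or_point)))
}

profile_assignment <- function(profile_row, factor_id) {
  if (!factor_id %in% names(profile_row)) return(NA_character_)
  as.character(profile_row[[factor_id]])
}

# log odds-ratio multiplier of one patient in one study (plug-in scale);
# returns the row indices of study_est matched by the patient's levels
profile_study_rows <- function(profile_row, study_est, prevalence) {
  prev <- as.data.frame(prevalence)
  hit <- integer(0)
  for (f in unique(study_est$factor_id)) {
    lev <- profile_assignment(profile_row, f)
    if (is.na(lev)) next                      # not applicable -> reference
    rows <- which(study_est$factor_id == f & study_est$level == lev)
    if (length(rows)) { hit <- c(hit, rows); next }
    is_ref <- any(prev$factor_id == f & prev$level == lev & prev$reference)
    if (!is_ref)
      stop("unmapped level: patient level '", lev, "' of factor '", f,
           "' is neither estimated by study '", study_est$study_id[1],
           "' nor the reference level")
  }
  hit
}

#' Patient- and study-specific risk
#'
#' Multiplies the study baseline by the odds ratio of the patient's level for
#' every factor the study estimates: \eqn{R_{ik} = R_{0k} \prod_j OR_{jk}}.
#' Reference levels and not-applicable entries contribute a multiplier of 1;
#' factors the study does not cover are skipped. A patient level that the
#' study does not estimate and that is not the reference level is an error
#' ("unmapped level") -- level harmonization belongs to the table author.
#'
#' @param profile_row one row of a `cc_profiles` data frame.
#' @param study_est imputed estimate rows of one study.
#' @param baseline the study baseline from [baseline_risk()].
#' @param prevalence a `cc_prevalence` table (identifies reference levels).
#' @return the point risk R_ik.
#' @export
patient_study_risk <- function(profile_row, study_est, baseline, prevalence) {
  study_est <- as.data.frame(study_est)
  rows <- profile_study_rows(profile_row, study_est, prevalence)
  baseline * prod(study_est$or_point[rows])
}

beta_pars <- function(m, cv) {
  s2 <- (cv * m)^2
  if (any(s2 >= m * (1 - m)))
    stop("beta parameters invalid for prevalence ",
         paste(signif(m[s2 >= m * (1 - m)], 4), collapse = ", "),
         " at cv ", cv, "; use a smaller prevalence_cv")
  k <- m * (1 - m) / s2 - 1
  list(shape1 = m * k, shape2 = (1 - m) * k)
}

#' Monte Carlo standard error of a patient's log study-risk
#'
#' Propagates the two uncertainty sources through the study risk equation:
#' each log odds ratio is drawn Normal(mu, sigma) and each non-reference
#' prevalence estimate is drawn from a Beta distribution with mean p and SD
#' `prevalence_cv * p` (method-of-moments shapes), independently per level --
#' the reference level holds the simplex remainder, so when a factor's
#' non-reference draws sum to 1 or more they are rescaled to keep the
#' remainder positive (rare at realistic CVs). For each of `n_reps`
#' replicates the baseline and the patient x study log-risk are recomputed;
#' the returned value is the sample standard deviation of the simulated
#' log-risks. Draws come from a substream seeded by (config seed, study id),
#' so results are reproducible and independent of which other studies are in
#' the model.
#'
#' @inheritParams patient_study_risk
#' @param prevalence a `cc_prevalence` table.
#' @param config a `cc_config` (uses `n_reps`, `prevalence_cv`, `seed`).
#' @return the Monte Carlo SE sigma_ik of the log study-risk.
#' @export
mc_log_se <- function(profile_row, study_est, prevalence, config) {
  study_est <- as.data.frame(study_est)
  prev <- as.data.frame(prevalence)
  n <- config$n_reps
  m <- nrow(study_est)
  study_prevalences(study_est, prevalence)  # validates level coverage
  hit <- profile_study_rows(profile_row, study_est, prevalence)
  with_local_seed(substream_seed(config$seed, study_est$study_id[1]), {
    # log-OR draws: n x m
    lor <- matrix(rnorm(n * m, mean = rep(study_est$mu, each = n),
                        sd = rep(study_est$sigma, each = n)), nrow = n)
    # Beta draws for the non-reference prevalence estimates of the study's
    # factors; the reference level is the simplex remainder, so a factor's
    # non-reference draws are rescaled in the rare replicates where they
    # sum to >= 1
    if (config$prevalence_cv > 0) {
      fac <- unique(study_est$factor_id)
      prows <- prev[prev$factor_id %in% fac & !prev$reference, , drop = FALSE]
      bp <- beta_pars(prows$prevalence, config$prevalence_cv)
      # inverse-CDF sampling from common uniforms: configurations differing
      # only in prevalence_cv share draws, so their comparison is paired
      draws <- matrix(stats::qbeta(runif(n * nrow(prows)),
                                   rep(bp$shape1, each = n),
                                   rep(bp$shape2, each = n)),
                      nrow = n)
      for (f in fac) {
        cols <- which(prows$factor_id == f)
        tot <- rowSums(draws[, cols, drop = FALSE])
        over <- tot >= 1
        if (any(over))
          draws[over, cols] <- draws[over, cols, drop = FALSE] *
            (0.999999 / tot[over])
      }
      idx <- match(paste(study_est$factor_id, study_est$level),
                   paste(prows$factor_id, prows$level))
      pmat <- draws[, idx, drop = FALSE]
    } else {
      p0 <- study_prevalences(study_est, prevalence)
      pmat <- matrix(p0, nrow = n, ncol = m, byrow = TRUE)
    }
    # log R_ik = log r0 - sum_l p_l * lor_l + sum_{patient levels} lor_l
    logr <- log(config$r0) - rowSums(pmat * lor)
    if (length(hit)) logr <- logr + rowSums(lor[, hit, drop = FALSE])
    stats::sd(logr)
  })
}

#' Random-effects pooling of per-study risks
#'
#' Pools the per-study log-risks with an inverse-variance random-effects
#' model. The between-study variance tau^2 comes from the DerSimonian-Laird
#' moment estimator (default): with fixed-effect weights `w = 1/se^2`,
#' `Q = sum w (y - ybar)^2` and
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; `"reml"`
#' maximizes the restricted likelihood instead. Random-effects weights are
#' `1/(se^2 + tau2)`, the pooled log-risk is their weighted mean, the Wald
#' interval `pooled +/- z * sqrt(1/sum w*)` is exponentiated along with the
#' point estimate.
#'
#' @param study_risks data frame with columns `study_id`, `point` (risk) and
#'   `log_se` (Monte Carlo SE of the log-risk); a `baseline` column is carried
#'   through if present.
#' @param config a `cc_config` (uses `ci_level`, `re_method`).
#' @return a `cc_pooled_risk` list: `point`, `ci_low`, `ci_high`, `tau2`,
#'   `log_point`, `log_se`, `per_study`, and `note` (e.g. single-study
#'   passthrough).
#' @export
pool_random_effects <- function(study_risks, config = model_config()) {
  sr <- as.data.frame(study_risks)
  if (nrow(sr) == 0) stop("no study risks to pool")
  if (any(!is.finite(sr$point) | sr$point <= 0)) stop("study risks must be positive")
  if (any(!is.finite(sr$log_se) | sr$log_se < 0)) stop("log_se must be finite and >= 0")
  y <- log(sr$point); s2 <- sr$log_se^2; k <- nrow(sr)
  z <- qnorm(1 - (1 - config$ci_level) / 2)
  note <- ""
  if (k == 1) {
    tau2 <- 0
    pooled <- y; pse <- sr$log_se
    note <- "single study: no heterogeneity estimable"
  } else if (all(s2 == 0)) {
    tau2 <- 0
    pooled <- mean(y); pse <- 0
    note <- "all within-study variances zero: equal-weight mean"
    warning("pool_random_effects: ", note)
  } else {
    s2 <- pmax(s2, .Machine$double.eps)
    tau2 <- switch(config$re_method,
      dl = {
        w <- 1 / s2
        ybar <- sum(w * y) / sum(w)
        Q <- sum(w * (y - ybar)^2)
        max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
      },
      reml = {
        nll <- function(t2) {
          wi <- 1 / (s2 + t2)
          mu <- sum(wi * y) / sum(wi)
          0.5 * (sum(log(s2 + t2)) + log(sum(wi)) + sum(wi * (y - mu)^2))
        }
        upper <- max(stats::var(y) * 10, max(s2) * 10, 1e-8)
        optimize(nll, c(0, upper), tol = 1e-12)$minimum
      })
    wst <- 1 / (s2 + tau2)
    pooled <- sum(wst * y) / sum(wst)
    pse <- sqrt(1 / sum(wst))
  }
  structure(list(point = exp(pooled), ci_low = exp(pooled - z * pse),
                 ci_high = exp(pooled + z * pse), tau2 = tau2,
                 log_point = pooled, log_se = pse, per_study = sr,
                 note = note),
            ci_level = config$ci_level,
            class = "cc_pooled_risk")
}

#' @export
print.cc_pooled_risk <- function(x, ...) {
  lvl <- attr(x, "ci_level", exact = TRUE) %||% 0.95
  cat(sprintf("Pooled risk: %.6g  (%d%% CI %.6g - %.6g)\n",
              x$point, round(100 * lvl), x$ci_low, x$ci_high))
  cat(sprintf("tau^2 = %.4g over %d studies\n", x$tau2, nrow(x$per_study)))
  if (nzchar(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict individualized risks
#'
#' The full meta-model pipeline for one or more patient profiles: for every
#' eligible study, calibrate the baseline ([baseline_risk()]), compute the
#' patient x study risk ([patient_study_risk()]), estimate its Monte Carlo
#' log-scale SE ([mc_log_se()]), then pool the per-study risks with a
#' random-effects model ([pool_random_effects()]).
#'
#' @param profiles a `cc_profiles` data frame (or a single-row profile).
#' @param studies imputed `cc_studies` (run [filter_eligible()] and
#'   [impute_estimates()] first).
#' @param prevalence a `cc_prevalence` table.
#' @param config a `cc_config`.
#' @return a `cc_risk_predictions` data frame, one row per patient:
#'   `patient_id`, `point`, `ci_low`, `ci_high`, `tau2`, `ratio_to_r0`
#'   (point/r0, reported to 2 decimals by the CLI), `n_studies`. The
#'   per-study decomposition (`patient_id`, `study_id`, `baseline`, `point`,
#'   `log_se`, `n_factors_used`) is attached as attribute `"per_study"`.
#' @export
predict_risk <- function(profiles, studies, prevalence, config = model_config()) {
  profiles <- as.data.frame(profiles)
  df <- as.data.frame(studies)
  if (!"mu" %in% names(df) || anyNA(df$mu))
    stop("studies must be imputed first (impute_estimates)")
  split_est <- split(df, df$study_id)
  baselines <- vapply(split_est, baseline_risk, numeric(1),
                      prevalence = prevalence, config = config)
  out <- vector("list", nrow(profiles))
  per_study <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    prow <- profiles[i, , drop = FALSE]
    sr <- do.call(rbind, lapply(names(split_est), function(sid) {
      se_tab <- split_est[[sid]]
      rows <- profile_study_rows(prow, se_tab, prevalence)
      data.frame(study_id = sid,
                 baseline = baselines[[sid]],
                 point = baselines[[sid]] * prod(se_tab$or_point[rows]),
                 log_se = mc_log_se(prow, se_tab, prevalence, config),
                 n_factors_used = length(unique(se_tab$factor_id)),
                 stringsAsFactors = FALSE)
    }))
    covered <- any(vapply(names(split_est), function(sid) {
      length(profile_study_rows(prow, split_est[[sid]], prevalence)) > 0
    }, logical(1)))
    if (!covered)
      warning("no eligible study covers any non-reference assignment of ",
              "patient ", prow$patient_id,
              "; the prediction pools the study baselines")
    pooled <- pool_random_effects(sr, config)
    out[[i]] <- data.frame(
      patient_id = prow$patient_id, point = pooled$point,
      ci_low = pooled$ci_low, ci_high = pooled$ci_high, tau2 = pooled$tau2,
      ratio_to_r0 = pooled$point / config$r0, n_studies = nrow(sr),
      stringsAsFactors = FALSE)
    sr$patient_id <- prow$patient_id
    per_study[[i]] <- sr
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "per_study") <- do.call(rbind, per_study)
  class(res) <- c("cc_risk_predictions", "data.frame")
  res
}
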