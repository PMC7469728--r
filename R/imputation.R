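# Missing-data procedures for the log odds-ratio location (mu) and its
# standard error (sigma), plus the prevalence imputation fallback chain.

#' Odds ratio from a reported regression coefficient
#'
#' When a study reports only the coefficient of a logistic-type regression,
#' the model's odds-ratio point estimate is the unbiased lognormal mean
#' `exp(mu + sigma^2 / 2)`, not the naive `exp(mu)`; the Monte Carlo engine
#' still samples the log odds ratio as Normal(mu, sigma).
#'
#' @param mu log-scale coefficient.
#' @param sigma standard error of the coefficient (>= 0).
#' @return the odds-ratio point estimate (vectorized).
#' @examples
#' or_from_coefficient(log(2), 0)    # 2
#' or_from_coefficient(0.5, 0.3)     # exp(0.545)
#' @export
or_from_coefficient <- function(mu, sigma) {
  if (any(!is.finite(mu)) || any(!is.finite(sigma)))
    stop("mu and sigma must be finite")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  exp(mu + sigma^2 / 2)
}

#' Log odds-ratio location and SE from a 95% confidence interval
#'
#' Inverts the lognormal interval parameterization
#' `[exp(mu + sigma^2/2 - 1.96 sigma), exp(mu + sigma^2/2 + 1.96 sigma)]`:
#' `sigma = (log hi - log lo) / (2 * 1.96)` and
#' `mu = (log hi + log lo)/2 - sigma^2/2`, so that rebuilding the bounds from
#' the result reproduces the inputs exactly.
#'
#' @param or_value the reported odds ratio (used for validation only).
#' @param ci_low,ci_high positive confidence bounds, `ci_low <= ci_high`.
#' @return list with `mu` and `sigma`.
#' @examples
#' sigma_from_ci(2, 1, 4)   # sigma = log(4)/3.92, mu = log(2) - sigma^2/2
#' @export
sigma_from_ci <- function(or_value, ci_low, ci_high) {
  if (any(!is.finite(c(or_value, ci_low, ci_high)))) stop("non-finite inputs")
  if (ci_low <= 0) stop("ci_low must be positive")
  if (ci_low > ci_high) stop("ci_low must not exceed ci_high")
  sigma <- (log(ci_high) - log(ci_low)) / (2 * 1.96)
  mu <- (log(ci_high) + log(ci_low)) / 2 - sigma^2 / 2
  list(mu = mu, sigma = sigma)
}

#' Log odds-ratio SE from a p-value (Altman-Bland conversion)
#'
#' Converts a two-sided p-value into an effective z-statistic with the
#' Altman-Bland approximation `z = -0.862 + sqrt(0.743 - 2.404 * log(p))`
#' (natural logarithm) and returns `sigma = |mu / z|`. The approximation
#' tracks the exact standard-normal quantile to about 0.02 for p between
#' roughly 0.001 and 0.5 and degrades slowly for smaller p.
#'
#' @param p two-sided p-value in (0, 1).
#' @param mu log odds ratio the p-value refers to; must be nonzero, since a
#'   null effect carries no scale information.
#' @return list with `sigma` and the intermediate `z`.
#' @examples
#' sigma_from_pvalue(0.05, log(2))  # z ~ 1.9566
#' @export
sigma_from_pvalue <- function(p, mu) {
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (!is.finite(mu) || mu == 0)
    stop("mu must be finite and nonzero (sigma = |mu/z| is undefined at mu = 0)")
  z <- -0.862 + sqrt(0.743 - 2.404 * log(p))
  list(sigma = abs(mu / z), z = z)
}

ct_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  (a * d - b * c)^2 * n / ((a + b) * (c + d) * (b + d) * (a + c))
}

#' Reconstruct a 2x2 contingency table from summary statistics
#'
#' Given the case and control totals, the reported effect ratio, and the
#' Pearson chi-square statistic, numerically solves the system
#' \deqn{a + c = N_1,\quad b + d = N_0,\quad
#'   \frac{a/(a+b)}{c/(c+d)} = \mathrm{ratio},\quad
#'   \chi^2 = \frac{(ad-bc)^2 (a+b+c+d)}{(a+b)(c+d)(b+d)(a+c)}}
#' for the cells a (cases exposed), b (controls exposed), c (cases
#' unexposed), d (controls unexposed). Cells may be fractional: summary
#' statistics rounded for publication generally admit no integer solution.
#'
#' The ratio constraint ties b to a in closed form, leaving a bracketed
#' one-dimensional root search in a. The chi-square level set along that
#' curve typically crosses twice; both crossings have their odds ratio on the
#' side of 1 given by `direction`, so among the feasible roots the table whose
#' implied odds ratio is closest (log scale) to `ratio` is returned -- under
#' the rare-disease reading in which the reported value is an odds ratio, that
#' is the table with the smallest internal OR/RR discrepancy.
#'
#' @param total_cases,total_controls positive marginal totals (a+c, b+d).
#' @param ratio reported effect ratio (> 0, != 1).
#' @param chi2 Pearson chi-square statistic (> 0).
#' @param direction `">1"` or `"<1"`: the side of 1 the implied odds ratio
#'   must fall on (the sign of the reported log odds ratio); `"auto"` takes
#'   the side of `ratio` itself.
#' @return list of class `cc_contingency` with cells `a`, `b`, `c`, `d`, the
#'   implied `or`, and `residuals` (relative residuals of the four equations).
#' @examples
#' solve_contingency(30, 170, 2, 3.9215686, ">1")  # ~ (20, 80, 10, 90)
#' @export
solve_contingency <- function(total_cases, total_controls, ratio, chi2,
                              direction = c("auto", ">1", "<1")) {
  direction <- match.arg(direction)
  N1 <- total_cases; N0 <- total_controls
  if (!is.finite(N1) || !is.finite(N0) || N1 <= 0 || N0 <= 0)
    stop("totals must be positive")
  if (!is.finite(ratio) || ratio <= 0) stop("ratio must be positive")
  if (ratio == 1 || chi2 <= 0)
    stop("degenerate system: ratio = 1 (or chi2 = 0) carries no association")
  if (direction == "auto") direction <- if (ratio > 1) ">1" else "<1"

  b_of <- function(a) a * ((N1 + N0 - a) - ratio * (N1 - a)) / (a + ratio * (N1 - a))
  g <- function(a) {
    b <- b_of(a); c <- N1 - a; d <- N0 - b
    out <- ct_chi2(a, b, c, d) - chi2
    out[b <= 0 | d <= 0 | c <= 0 | a <= 0] <- NA_real_
    out
  }
  grid <- seq(N1 * 1e-9, N1 * (1 - 1e-9), length.out = 4000)
  gv <- g(grid)
  ok <- which(!is.na(gv))
  if (!length(ok)) stop("inconsistent summary statistics")
  roots <- c()
  sgn <- sign(gv[ok]); ga <- grid[ok]
  for (i in which(diff(sgn) != 0)) {
    r <- uniroot(g, c(ga[i], ga[i + 1]), tol = .Machine$double.eps^0.9)$root
    # polish with a secant step for sharper residuals
    h <- max(abs(r) * 1e-7, 1e-10)
    gr <- g(r); gp <- g(r + h)
    if (is.finite(gr) && is.finite(gp) && gp != gr) {
      r2 <- r - gr * h / (gp - gr)
      if (is.finite(r2) && r2 > 0 && r2 < N1 && is.finite(g(r2)) &&
          abs(g(r2)) < abs(gr)) r <- r2
    }
    roots <- c(roots, r)
  }
  # tangency: the two chi-square roots coincide at an extremum of the curve,
  # so the grid shows no sign change there; polish curve extrema that graze
  # zero and accept them when the residual vanishes
  gvx <- gv[ok]
  ext <- which(diff(sign(diff(gvx))) != 0) + 1
  for (i in ext) {
    if (i < 2 || i > length(gvx) - 1) next
    if (abs(gvx[i]) > 1e-4 * max(chi2, 1)) next
    opt <- optimize(function(a) abs(g(a)), c(ga[i - 1], ga[i + 1]),
                    tol = .Machine$double.eps^0.75 * N1)
    if (abs(opt$objective) <= 1e-8 * max(chi2, 1))
      roots <- c(roots, opt$minimum)
  }
  if (!length(roots)) stop("inconsistent summary statistics")
  cand <- lapply(roots, function(a) {
    b <- b_of(a); c <- N1 - a; d <- N0 - b
    list(a = a, b = b, c = c, d = d, or = (a * d) / (b * c))
  })
  cand <- Filter(function(t) all(unlist(t[c("a", "b", "c", "d")]) > 0), cand)
  want_pos <- direction == ">1"
  cand <- Filter(function(t) (t$or > 1) == want_pos, cand)
  if (!length(cand))
    stop("inconsistent summary statistics: no table matches the requested ",
         "odds-ratio direction")
  dev <- vapply(cand, function(t) abs(log(t$or) - log(ratio)), numeric(1))
  tab <- cand[[which.min(dev)]]
  rr <- with(tab, (a / (a + b)) / (c / (c + d)))
  tab$residuals <- c(
    cases = abs(tab$a + tab$c - N1) / N1,
    controls = abs(tab$b + tab$d - N0) / N0,
    ratio = abs(rr - ratio) / ratio,
    chi2 = abs(ct_chi2(tab$a, tab$b, tab$c, tab$d) - chi2) / chi2)
  class(tab) <- "cc_contingency"
  tab
}

#' Variance of the log odds ratio from a 2x2 table
#'
#' The Woolf variance `1/a + 1/b + 1/c + 1/d`.
#'
#' @param table a `cc_contingency` object, a list with `a`..`d`, or a numeric
#'   vector of the four cells (all strictly positive).
#' @return the variance of the log odds ratio.
#' @export
var_logor_from_table <- function(table) {
  cells <- if (is.list(table)) unlist(table[c("a", "b", "c", "d")]) else as.numeric(table)
  if (length(cells) != 4 || any(!is.finite(cells))) stop("need four finite cells")
  if (any(cells <= 0)) stop("all cells must be strictly positive")
  sum(1 / cells)
}

#' Impute the log odds-ratio location and SE for every estimate
#'
#' For each retained study estimate exactly one imputation method fires,
#' chosen by decreasing information content:
#' \describe{
#'   \item{`reported`}{a directly reported SE of the log odds ratio (`se`
#'     column); `mu = log(OR) - se^2/2` for ratio rows (so the lognormal mean
#'     reproduces the reported OR), `mu = value` for coefficient rows.}
#'   \item{`from_coefficient`}{coefficient rows; the OR point estimate becomes
#'     [or_from_coefficient()] of (value, se).}
#'   \item{`from_ci`}{both 95% bounds present; [sigma_from_ci()].}
#'   \item{`from_pvalue`}{[sigma_from_pvalue()] with `mu = log(OR)`.}
#'   \item{`from_chi2`}{chi-square plus totals; [solve_contingency()] then
#'     [var_logor_from_table()], with `mu = log(OR)`.}
#' }
#' The method and its intermediates (z, reconstructed table cells) are stored
#' on the returned table as an imputation trace (`imp_method`, `imp_z`,
#' `imp_a`..`imp_d`), alongside `mu`, `sigma` and the plug-in `or_point`.
#'
#' @param studies a filtered `cc_studies` data frame (see [filter_eligible()]).
#' @return the same table with imputation columns filled in.
#' @export
impute_estimates <- function(studies) {
  df <- as.data.frame(studies)
  n <- nrow(df)
  df$mu <- NA_real_; df$sigma <- NA_real_; df$or_point <- NA_real_
  df$imp_method <- NA_character_; df$imp_z <- NA_real_
  df$imp_a <- NA_real_; df$imp_b <- NA_real_; df$imp_c <- NA_real_; df$imp_d <- NA_real_
  for (i in seq_len(n)) {
    r <- df[i, ]
    is_coef <- r$estimate_type == "coefficient"
    if (!is.na(r$se)) {
      df$sigma[i] <- r$se
      df$mu[i] <- if (is_coef) r$value else log(r$value) - r$se^2 / 2
      df$imp_method[i] <- if (is_coef) "from_coefficient" else "reported"
      df$or_point[i] <- if (is_coef) or_from_coefficient(r$value, r$se) else r$value
    } else if (is_coef) {
      if (is.na(r$p_value))
        stop("coefficient row ", i, " needs a reported se or a p-value")
      pv <- sigma_from_pvalue(r$p_value, r$value)
      df$sigma[i] <- pv$sigma; df$imp_z[i] <- pv$z
      df$mu[i] <- r$value
      df$imp_method[i] <- "from_coefficient"
      df$or_point[i] <- or_from_coefficient(r$value, pv$sigma)
    } else if (!is.na(r$ci_low) && !is.na(r$ci_high)) {
      ms <- sigma_from_ci(r$value, r$ci_low, r$ci_high)
      df$mu[i] <- ms$mu; df$sigma[i] <- ms$sigma
      df$imp_method[i] <- "from_ci"
      df$or_point[i] <- r$value
    } else if (!is.na(r$p_value)) {
      pv <- sigma_from_pvalue(r$p_value, log(r$value))
      df$mu[i] <- log(r$value); df$sigma[i] <- pv$sigma; df$imp_z[i] <- pv$z
      df$imp_method[i] <- "from_pvalue"
      df$or_point[i] <- r$value
    } else if (!is.na(r$chi2) && !is.na(r$n_cases) && !is.na(r$n_controls)) {
      tab <- solve_contingency(r$n_cases, r$n_controls, r$value, r$chi2,
                               if (r$value > 1) ">1" else "<1")
      df$mu[i] <- log(r$value)
      df$sigma[i] <- sqrt(var_logor_from_table(tab))
      df$imp_method[i] <- "from_chi2"
      df$imp_a[i] <- tab$a; df$imp_b[i] <- tab$b
      df$imp_c[i] <- tab$c; df$imp_d[i] <- tab$d
      df$or_point[i] <- r$value
    } else {
      stop("estimate in row ", i, " carries no variability information; ",
           "run filter_eligible() first")
    }
  }
  stopifnot(all(is.finite(df$mu)), all(df$sigma >= 0))
  class(df) <- c("cc_studies", "data.frame")
  df
}

#' Impute a missing population prevalence
#'
#' Fallback chain for the prevalence of one factor level: (1) if other
#' case-control studies report a control-group prevalence for the level, their
#' unweighted mean is used (provenance tier 4); (2) otherwise the external
#' fallback table entry with its own tier; (3) otherwise the factor must be
#' excluded from the model, signalled by an `excluded` result.
#'
#' @param factor_id,level the level to impute.
#' @param studies a `cc_studies` table (its optional `control_prevalence`
#'   column feeds branch 1).
#' @param fallback_table a `cc_prevalence` table, or `NULL`.
#' @param exclude_study optional study id whose own control prevalence must be
#'   ignored ("the other case-control studies").
#' @return list with `prevalence`, `tier`, `source` and logical `excluded`.
#' @export
impute_prevalence <- function(factor_id, level, studies, fallback_table = NULL,
                              exclude_study = NULL) {
  df <- as.data.frame(studies)
  if ("control_prevalence" %in% names(df)) {
    sel <- df$factor_id == factor_id & df$level == level &
      !is.na(df$control_prevalence)
    if (!is.null(exclude_study)) sel <- sel & df$study_id != exclude_study
    if (any(sel)) {
      return(list(prevalence = mean(df$control_prevalence[sel]), tier = 4L,
                  source = "control groups of other case-control studies",
                  excluded = FALSE))
    }
  }
  if (!is.null(fallback_table)) {
    ft <- as.data.frame(fallback_table)
    hit <- ft$factor_id == factor_id & ft$level == level
    if (any(hit)) {
      i <- which(hit)[1]
      return(list(prevalence = ft$prevalence[i], tier = as.integer(ft$tier[i]),
                  source = if (nzchar(ft$source_note[i])) ft$source_note[i]
                           else "fallback prevalence table",
                  excluded = FALSE))
    }
  }
  list(prevalence = NA_real_, tier = NA_integer_,
       source = "no prevalence source found; exclude the factor",
       excluded = TRUE)
}
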