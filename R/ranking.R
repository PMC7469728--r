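# Pooled odds ratio and pooled prevalence per risk factor, used to rank
# factors by effect magnitude (a reporting feature; expert selection, not the
# ranking, decides what enters the risk engine).

#' Pool odds-ratio estimates for one factor (or one level)
#'
#' To make effect magnitudes comparable across factors, any odds ratio below 1
#' is replaced by its reciprocal (the variance of the log is unchanged by
#' inversion). The pooled value is then the inverse-variance weighted mean of
#' the (possibly inverted) odds ratios, with weights `1/sigma^2`; by default
#' the mean is taken on the OR scale, `scale = "log"` pools the log odds
#' ratios and exponentiates. The lower confidence bound comes from the pooled
#' weight sum on the log scale: `pooled * exp(-z * sqrt(1/sum(w)))`.
#'
#' @param estimates imputed `cc_studies` rows (needs `or_point` and `sigma`).
#' @param scale `"or"` (weighted mean of odds ratios) or `"log"`.
#' @param ci_level confidence level for the lower bound (default 0.95).
#' @return one-row data frame: `pooled_or`, `pooled_or_ci_low`, `n_studies`,
#'   `n_estimates`.
#' @export
pool_or <- function(estimates, scale = c("or", "log"), ci_level = 0.95) {
  scale <- match.arg(scale)
  df <- as.data.frame(estimates)
  if (nrow(df) == 0) stop("no estimates to pool")
  if (!all(c("or_point", "sigma") %in% names(df)))
    stop("estimates must be imputed first (impute_estimates)")
  or <- df$or_point
  or[or < 1] <- 1 / or[or < 1]
  v <- df$sigma^2
  w <- if (all(v == 0)) rep(1, length(v)) else 1 / pmax(v, .Machine$double.eps)
  if (all(!is.finite(w))) stop("all variances infinite; nothing to pool")
  pooled <- if (scale == "or") sum(w * or) / sum(w)
            else exp(sum(w * log(or)) / sum(w))
  z <- qnorm(1 - (1 - ci_level) / 2)
  ci_low <- pooled * exp(-z * sqrt(1 / sum(w)))
  data.frame(pooled_or = pooled, pooled_or_ci_low = ci_low,
             n_studies = length(unique(df$study_id)), n_estimates = nrow(df))
}

#' Pool prevalence over the non-reference levels of one factor
#'
#' Weighted mean of the level prevalences; weights are the inverse variances
#' of the paired odds-ratio estimates when available, equal otherwise.
#'
#' @param prevalences numeric prevalence values (non-reference levels).
#' @param weights optional positive weights (e.g. `1/sigma^2` of the paired
#'   odds ratios); recycled equal weights when `NULL`.
#' @return the pooled prevalence.
#' @export
pool_prevalence <- function(prevalences, weights = NULL) {
  p <- as.numeric(prevalences)
  if (!length(p)) stop("no prevalence values")
  if (is.null(weights)) weights <- rep(1, length(p))
  if (length(weights) != length(p) || any(weights < 0))
    stop("weights must be nonnegative and match prevalences in length")
  if (all(weights == 0)) weights <- rep(1, length(p))
  sum(weights * p) / sum(weights)
}

#' Build per-factor rankings from imputed study estimates
#'
#' Pools all non-reference-level odds ratios of each factor with [pool_or()]
#' and the corresponding prevalences with [pool_prevalence()] (weights =
#' inverse variance of the paired estimate where the prevalence table covers
#' the level).
#'
#' @param studies imputed `cc_studies`.
#' @param prevalence a `cc_prevalence` table.
#' @param scale pooling scale passed to [pool_or()].
#' @return a `FactorRanking` data frame: `factor_id`, `pooled_or`,
#'   `pooled_or_ci_low`, `pooled_prevalence`, `n_studies`.
#' @export
factor_rankings <- function(studies, prevalence, scale = c("or", "log")) {
  scale <- match.arg(scale)
  df <- as.data.frame(studies)
  prev <- as.data.frame(prevalence)
  out <- lapply(split(df, df$factor_id), function(sub) {
    p <- pool_or(sub, scale = scale)
    key <- paste(sub$factor_id, sub$level)
    pk <- paste(prev$factor_id, prev$level)
    pr <- prev$prevalence[match(key, pk)]
    hasp <- !is.na(pr)
    pooled_prev <- if (any(hasp))
      pool_prevalence(pr[hasp], 1 / pmax(sub$sigma[hasp]^2, .Machine$double.eps))
    else NA_real_
    data.frame(factor_id = sub$factor_id[1], pooled_or = p$pooled_or,
               pooled_or_ci_low = p$pooled_or_ci_low,
               pooled_prevalence = pooled_prev, n_studies = p$n_studies)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank factors by pooled odds ratio
#'
#' Descending by `pooled_or`; ties broken by `n_studies` (more studies first)
#' and then alphabetically by `factor_id`.
#'
#' @param rankings a `FactorRanking` data frame (see [factor_rankings()]).
#' @param top_n how many factors to keep (default all).
#' @return the ordered, truncated data frame.
#' @export
rank_factors <- function(rankings, top_n = Inf) {
  df <- as.data.frame(rankings)
  if (nrow(df) == 0) return(df)
  ord <- order(-df$pooled_or, -df$n_studies, df$factor_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_n)
}
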