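# Leave-one-out sensitivity analyses and configuration scans.

rel_ci_width <- function(pred) (pred$ci_high - pred$ci_low) / pred$point

# rebuild the eligible study set after removing a factor or a study
remove_item <- function(studies, item, axis) {
  df <- as.data.frame(studies)
  df <- if (axis == "factor") df[df$factor_id != item, , drop = FALSE]
        else df[df$study_id != item, , drop = FALSE]
  class(df) <- c("cc_studies", "data.frame")
  filter_eligible(df)
}

#' Leave-one-out sensitivity analysis
#'
#' Removes one risk factor (its estimates from every study) or one study at a
#' time, re-runs the full prediction on every profile, and reports the
#' model's two sensitivity metrics against the base case:
#' \describe{
#'   \item{accuracy}{mean over profiles of the absolute deviation of the
#'     predicted risk from the base-case prediction (with
#'     `normalize = TRUE`, the deviation is divided by the base-case risk);}
#'   \item{precision}{mean over profiles of the change in the relative width
#'     of the 95% CI, `(hi - lo)/point`: base-case width minus scenario
#'     width, so a positive value means the interval got narrower (the model
#'     more precise) after removal.}
#' }
#' Removing a factor can push a study below the two-factor eligibility
#' threshold, in which case the whole study drops out (recorded in `note`).
#' Because every study's Monte Carlo draws come from a substream seeded only
#' by (seed, study id), retained studies reuse identical draws across
#' scenarios and the metrics isolate the removal effect from Monte Carlo
#' noise; removing an item that appears nowhere yields exactly zero.
#'
#' @param profiles a `cc_profiles` data frame.
#' @param studies imputed `cc_studies`.
#' @param prevalence a `cc_prevalence` table.
#' @param config a `cc_config`.
#' @param axis `"factor"` or `"study"`.
#' @param items items to remove (default: every factor/study present).
#' @param normalize divide risk deviations by the base-case risk.
#' @return a data frame: `removed_item`, `axis`, `accuracy`, `precision`,
#'   `n_profiles`, `n_studies_retained`, `note`.
#' @export
leave_one_out <- function(profiles, studies, prevalence,
                          config = model_config(),
                          axis = c("factor", "study"), items = NULL,
                          normalize = FALSE) {
  axis <- match.arg(axis)
  df <- as.data.frame(studies)
  if (is.null(items))
    items <- unique(if (axis == "factor") df$factor_id else df$study_id)
  base <- predict_risk(profiles, studies, prevalence, config)
  base_w <- rel_ci_width(base)
  out <- lapply(items, function(item) {
    sc <- remove_item(studies, item, axis)
    note <- ""
    dropped <- setdiff(unique(df$study_id), unique(sc$study_id))
    dropped <- setdiff(dropped, if (axis == "study") item else character(0))
    if (length(dropped))
      note <- paste0("study set reduced below 2 factors, dropped: ",
                     paste(dropped, collapse = ", "))
    if (nrow(sc) == 0) {
      return(data.frame(removed_item = item, axis = axis,
                        accuracy = NA_real_, precision = NA_real_,
                        n_profiles = nrow(base), n_studies_retained = 0L,
                        note = "no prediction possible",
                        stringsAsFactors = FALSE))
    }
    pred <- predict_risk(profiles, sc, prevalence, config)
    dev <- abs(pred$point - base$point)
    if (normalize) dev <- dev / base$point
    data.frame(removed_item = item, axis = axis,
               accuracy = mean(dev),
               precision = mean(base_w - rel_ci_width(pred)),
               n_profiles = nrow(base),
               n_studies_retained = length(unique(sc$study_id)),
               note = note, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan prevalence CV and Monte Carlo replication settings
#'
#' Re-runs the prediction over a grid of prevalence coefficients of variation
#' and Monte Carlo replication counts, reporting the mean predicted risk and
#' the mean relative CI width per configuration. The mean CI width responds
#' monotonically to the prevalence CV; the sign of the response depends on
#' the heterogeneity regime (when the moment estimate of tau^2 is positive,
#' extra within-study variance is reallocated out of tau^2 and the pooled
#' interval can tighten slightly; with tau^2 at its zero floor the interval
#' widens). Changing the replication count should move results only within
#' Monte Carlo error. A CV that makes the Beta method-of-moments
#' parameterization infeasible for some prevalence is flagged, not fatal.
#'
#' @param profiles,studies,prevalence,base_config as in [leave_one_out()].
#' @param cv_grid prevalence CV values (default `c(0, 0.1, 0.2)`).
#' @param reps_grid replication counts (default the base config's).
#' @return a data frame: `prevalence_cv`, `n_reps`, `mean_point`,
#'   `mean_rel_ci_width`, `flag`.
#' @export
scan_config <- function(profiles, studies, prevalence,
                        base_config = model_config(),
                        cv_grid = c(0, 0.1, 0.2),
                        reps_grid = base_config$n_reps) {
  if (!length(cv_grid) || !length(reps_grid)) stop("grids must be nonempty")
  grid <- expand.grid(prevalence_cv = cv_grid, n_reps = reps_grid)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base_config
    cfg$prevalence_cv <- grid$prevalence_cv[i]
    cfg$n_reps <- as.integer(grid$n_reps[i])
    res <- tryCatch(predict_risk(profiles, studies, prevalence, cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(prevalence_cv = cfg$prevalence_cv, n_reps = cfg$n_reps,
                 mean_point = NA_real_, mean_rel_ci_width = NA_real_,
                 flag = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(prevalence_cv = cfg$prevalence_cv, n_reps = cfg$n_reps,
                 mean_point = mean(res$point),
                 mean_rel_ci_width = mean(rel_ci_width(res)),
                 flag = "", stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  for (r in unique(res$n_reps)) {
    sub <- res[res$n_reps == r & res$flag == "", ]
    sub <- sub[order(sub$prevalence_cv), ]
    d <- diff(sub$mean_rel_ci_width)
    if (nrow(sub) > 1 && any(d < 0) && any(d > 0))
      warning("mean relative CI width is not monotone in prevalence_cv at ",
              "n_reps = ", r)
  }
  res
}
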