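# Study-estimates table: schema, readers/writers, validation, eligibility filters.

STUDY_COLS_REQUIRED <- c("study_id", "factor_id", "level", "estimate_type", "value")
STUDY_COLS_OPTIONAL <- c("ci_low", "ci_high", "p_value", "chi2", "n_cases",
                         "n_controls", "adjusted", "se", "control_prevalence")
PREV_COLS_REQUIRED <- c("factor_id", "level", "prevalence", "tier")
PREV_COLS_OPTIONAL <- c("source_note", "reference")

#' Read a study-estimates table
#'
#' Reads one row per (study, risk factor, level) odds-ratio record from CSV or
#' JSON. The fixed column schema is
#' `study_id, factor_id, level, estimate_type, value, ci_low, ci_high, p_value,
#' chi2, n_cases, n_controls, adjusted`, with optional extras `se` (directly
#' reported standard error of the log odds ratio) and `control_prevalence`
#' (prevalence of the level in the study's control group). Unknown columns are
#' ignored with a warning. `estimate_type` is one of `"or"`, `"rr"` or
#' `"coefficient"`; because the source designs are case-control studies, rows
#' labelled `"rr"` are relabelled `"or"` (with `rr_as_or = TRUE` recorded) --
#' a relative risk is not directly estimable from a case-control design and
#' for a rare outcome the two are close.
#'
#' @param path file path (`.csv` or `.json`).
#' @param factors optional factor-level table (`factor_id`, `level`,
#'   `reference` columns); when supplied, estimates referring to unknown
#'   factors or levels are an error.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return a validated `cc_studies` data frame.
#' @seealso [filter_eligible()], [impute_estimates()]
#' @export
read_study_table <- function(path, factors = NULL, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_studies(df, factors = factors)
}

#' Write a study-estimates table
#'
#' @param x a `cc_studies` data frame.
#' @param path output path (`.csv` or `.json` by extension).
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path) {
  keep <- intersect(c(STUDY_COLS_REQUIRED, STUDY_COLS_OPTIONAL, "rr_as_or"), names(x))
  out <- as.data.frame(x)[, keep]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Validate a study-estimates data frame
#'
#' Checks the column schema and per-row invariants (positive odds ratios,
#' ordered confidence bounds, p-values in (0,1), nonnegative chi-square,
#' positive totals), relabels relative risks as odds ratios, and returns a
#' `cc_studies` object. Violations are reported with the offending row
#' numbers.
#'
#' @param df a data frame in the study-table schema.
#' @param factors optional factor-level table used to reject unknown
#'   `factor_id`/`level` combinations.
#' @return a `cc_studies` data frame.
#' @export
validate_studies <- function(df, factors = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(STUDY_COLS_REQUIRED, names(df))
  if (length(missing_cols))
    stop("study table is missing required columns: ", paste(missing_cols, collapse = ", "))
  known <- c(STUDY_COLS_REQUIRED, STUDY_COLS_OPTIONAL, "rr_as_or",
             "mu", "sigma", "or_point", "imp_method", "imp_z",
             "imp_a", "imp_b", "imp_c", "imp_d")
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning("ignoring unknown study-table columns: ", paste(extra, collapse = ", "))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  for (col in setdiff(STUDY_COLS_OPTIONAL, names(df)))
    df[[col]] <- if (col == "adjusted") NA else NA_real_
  for (col in c("value", "ci_low", "ci_high", "p_value", "chi2", "se",
                "control_prevalence")) {
    df[[col]][df[[col]] %in% ""] <- NA
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("n_cases", "n_controls")) df[[col]] <- as.numeric(df[[col]])
  df$adjusted <- as.logical(df$adjusted)
  df$estimate_type <- tolower(as.character(df$estimate_type))

  bad_rows <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop("invalid study table: ", what, " in row(s) ",
           paste(idx, collapse = ", "))
  }
  bad_rows(!df$estimate_type %in% c("or", "rr", "coefficient"),
           "estimate_type not one of or/rr/coefficient")
  # RR-as-OR convention for case-control sources
  if (!"rr_as_or" %in% names(df)) df$rr_as_or <- rep(FALSE, nrow(df))
  df$rr_as_or[is.na(df$rr_as_or)] <- FALSE
  is_rr <- df$estimate_type == "rr"
  if (any(is_rr)) {
    warning(sum(is_rr), " relative-risk row(s) relabelled as odds ratios ",
            "(case-control sources cannot estimate RR directly)")
    df$estimate_type[is_rr] <- "or"
    df$rr_as_or[is_rr] <- TRUE
  }
  ratio_type <- df$estimate_type == "or"
  bad_rows(ratio_type & (!is.finite(df$value) | df$value <= 0),
           "odds ratio not a positive number")
  bad_rows(df$estimate_type == "coefficient" & !is.finite(df$value),
           "non-finite regression coefficient")
  both_ci <- !is.na(df$ci_low) & !is.na(df$ci_high)
  bad_rows(both_ci & df$ci_low >= df$ci_high, "ci_low >= ci_high")
  bad_rows(!is.na(df$ci_low) & df$ci_low <= 0 & ratio_type, "nonpositive ci_low")
  bad_rows(!is.na(df$p_value) & (df$p_value <= 0 | df$p_value >= 1),
           "p_value outside (0, 1)")
  bad_rows(!is.na(df$chi2) & df$chi2 < 0, "negative chi2")
  bad_rows(!is.na(df$n_cases) & df$n_cases <= 0, "nonpositive n_cases")
  bad_rows(!is.na(df$n_controls) & df$n_controls <= 0, "nonpositive n_controls")
  bad_rows(!is.na(df$se) & df$se < 0, "negative se")

  if (!is.null(factors)) {
    key <- paste(df$factor_id, df$level)
    fkey <- paste(factors$factor_id, factors$level)
    bad_rows(!df$factor_id %in% factors$factor_id, "unknown factor_id")
    bad_rows(!key %in% fkey, "level not defined for its factor")
    ref <- factors[factors$reference, ]
    bad_rows(key %in% paste(ref$factor_id, ref$level),
             "estimate reported for a reference level")
  }
  # duplicates with identical adjustment status are irreconcilable
  dup_key <- paste(df$study_id, df$factor_id, df$level, df$adjusted)
  bad_rows(duplicated(dup_key), "duplicate (study, factor, level) estimate")
  class(df) <- c("cc_studies", "data.frame")
  df
}

#' Apply the model's study-eligibility filters
#'
#' Three rules, applied in order: (1) estimates carrying no variability
#' information at all (no reported SE, no confidence interval, no p-value, and
#' no chi-square statistic with case/control totals) are dropped -- nothing can
#' be learned about their standard error; (2) where a (study, factor, level)
#' has both a univariate and a multivariate estimate, only the multivariate
#' (adjusted) one is retained; (3) whole studies contributing fewer than two
#' distinct risk factors after (1)-(2) are excluded, because single-factor
#' studies cannot be calibrated against the others without biasing the pooled
#' prediction. The filter is total (never errors) and idempotent.
#'
#' @param studies a `cc_studies` data frame.
#' @return the filtered `cc_studies`; the per-study exclusion report is
#'   attached as attribute `"exclusion_report"` (see [exclusion_report()]).
#' @export
filter_eligible <- function(studies) {
  df <- as.data.frame(studies)
  if (nrow(df) == 0) {
    out <- df
    class(out) <- c("cc_studies", "data.frame")
    attr(out, "exclusion_report") <- data.frame(
      study_id = character(), n_in = integer(), dropped_no_variability = integer(),
      dropped_unadjusted = integer(), study_excluded = logical())
    return(out)
  }
  all_ids <- unique(df$study_id)
  n_in <- table(factor(df$study_id, levels = all_ids))

  has_var <- !is.na(df$se) |
    (!is.na(df$ci_low) & !is.na(df$ci_high)) |
    !is.na(df$p_value) |
    (!is.na(df$chi2) & !is.na(df$n_cases) & !is.na(df$n_controls))
  dropped_novar <- table(factor(df$study_id[!has_var], levels = all_ids))
  df <- df[has_var, , drop = FALSE]

  key <- paste(df$study_id, df$factor_id, df$level)
  adj <- !is.na(df$adjusted) & df$adjusted
  has_adj <- tapply(adj, key, any)[key]
  keep <- !(has_adj & !adj)
  dropped_unadj <- table(factor(df$study_id[!keep], levels = all_ids))
  df <- df[keep, , drop = FALSE]

  nf <- tapply(df$factor_id, df$study_id, function(f) length(unique(f)))
  ok_studies <- names(nf)[nf >= 2]
  excluded <- !all_ids %in% ok_studies
  df <- df[df$study_id %in% ok_studies, , drop = FALSE]

  rownames(df) <- NULL
  class(df) <- c("cc_studies", "data.frame")
  attr(df, "exclusion_report") <- data.frame(
    study_id = all_ids,
    n_in = as.integer(n_in),
    dropped_no_variability = as.integer(dropped_novar),
    dropped_unadjusted = as.integer(dropped_unadj),
    study_excluded = excluded,
    stringsAsFactors = FALSE)
  df
}

#' Per-study exclusion report of the last eligibility filtering
#'
#' @param studies the result of [filter_eligible()].
#' @return a data frame with one row per input study: estimates received,
#'   estimates dropped for lacking variability information, unadjusted
#'   duplicates dropped, and whether the whole study was excluded.
#' @export
exclusion_report <- function(studies) attr(studies, "exclusion_report")

#' Read a population-prevalence table
#'
#' Schema: `factor_id, level, prevalence, tier, source_note, reference`.
#' `tier` records the provenance rank of the estimate (1 = national population
#' database, 2 = large cohort/survey, 3 = grey literature, 4 = control group of
#' a source case-control study, 5 = non-Chinese source). The logical
#' `reference` column marks each factor's reference level. Within each factor
#' the prevalences over all levels (reference included) are renormalized to
#' sum to one; a deviation larger than `tol` before normalization is an error.
#'
#' @param path CSV or JSON file path.
#' @param normalize renormalize each factor's simplex (default `TRUE`).
#' @param tol largest tolerated deviation of a factor's prevalence sum from 1.
#' @return a validated `cc_prevalence` data frame.
#' @export
read_prevalence_table <- function(path, normalize = TRUE, tol = 0.05) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_prevalence(df, normalize = normalize, tol = tol)
}

#' @rdname read_prevalence_table
#' @param df a data frame in the prevalence-table schema.
#' @export
validate_prevalence <- function(df, normalize = TRUE, tol = 0.05) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PREV_COLS_REQUIRED, names(df))
  if (length(missing_cols))
    stop("prevalence table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"reference" %in% names(df))
    stop("prevalence table needs a logical `reference` column marking each ",
         "factor's reference level")
  if (!"source_note" %in% names(df)) df$source_note <- ""
  df$prevalence <- as.numeric(df$prevalence)
  df$tier <- as.integer(df$tier)
  df$reference <- as.logical(df$reference)
  if (any(!is.finite(df$prevalence) | df$prevalence <= 0 | df$prevalence >= 1))
    stop("prevalences must lie strictly inside (0, 1)")
  if (any(is.na(df$tier) | df$tier < 1 | df$tier > 5))
    stop("tier must be an integer in 1..5")
  if (anyDuplicated(paste(df$factor_id, df$level)))
    stop("duplicate (factor_id, level) in prevalence table")
  nref <- tapply(df$reference, df$factor_id, sum)
  if (any(nref != 1))
    stop("each factor needs exactly one reference level; offending: ",
         paste(names(nref)[nref != 1], collapse = ", "))
  sums <- tapply(df$prevalence, df$factor_id, sum)
  if (any(abs(sums - 1) > tol))
    stop("prevalences of factor(s) ",
         paste(names(sums)[abs(sums - 1) > tol], collapse = ", "),
         " deviate from a unit sum by more than ", tol)
  if (normalize)
    df$prevalence <- df$prevalence / ave(df$prevalence, df$factor_id, FUN = sum)
  rownames(df) <- NULL
  class(df) <- c("cc_prevalence", "data.frame")
  df
}

#' Write a prevalence table
#' @param x a `cc_prevalence` data frame.
#' @param path output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_prevalence_table <- function(x, path) {
  out <- as.data.frame(x)[, c(PREV_COLS_REQUIRED, "source_note", "reference")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read patient profiles
#'
#' Wide format: one row per patient, a `patient_id` column, and one column per
#' risk factor holding the patient's level identifier or an empty/NA entry for
#' "not applicable" (e.g. gestational factors of a never-pregnant woman).
#' Not-applicable entries act as the reference level (odds-ratio multiplier 1)
#' in the risk equations.
#'
#' @param path CSV or JSON file path.
#' @param factors optional factor-level table; when given, assigned levels are
#'   checked against it.
#' @return a `cc_profiles` data frame.
#' @export
read_profiles <- function(path, factors = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_profiles(df, factors = factors)
}

#' @rdname read_profiles
#' @param df a data frame in the wide profile format.
#' @export
validate_profiles <- function(df, factors = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) stop("profiles need a patient_id column")
  fac_cols <- setdiff(names(df), "patient_id")
  for (col in fac_cols) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][df[[col]] %in% c("", "NA", "not_applicable")] <- NA_character_
  }
  if (!is.null(factors)) {
    for (col in intersect(fac_cols, unique(factors$factor_id))) {
      lv <- factors$level[factors$factor_id == col]
      bad <- !is.na(df[[col]]) & !df[[col]] %in% lv
      if (any(bad))
        stop("profile level(s) not defined for factor ", col, ": ",
             paste(unique(df[[col]][bad]), collapse = ", "))
    }
  }
  class(df) <- c("cc_profiles", "data.frame")
  df
}
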