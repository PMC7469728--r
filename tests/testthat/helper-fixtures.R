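# Shared fixtures and independent oracles.

# minimal valid estimate row; override fields as needed
est_row <- function(study_id = "S1", factor_id = "f1", level = "hi",
                    estimate_type = "or", value = 2, ci_low = NA, ci_high = NA,
                    p_value = NA, chi2 = NA, n_cases = NA, n_controls = NA,
                    adjusted = TRUE, se = NA, control_prevalence = NA) {
  data.frame(study_id = study_id, factor_id = factor_id, level = level,
             estimate_type = estimate_type, value = value,
             ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high),
             p_value = as.numeric(p_value), chi2 = as.numeric(chi2),
             n_cases = as.numeric(n_cases), n_controls = as.numeric(n_controls),
             adjusted = adjusted, se = as.numeric(se),
             control_prevalence = as.numeric(control_prevalence),
             stringsAsFactors = FALSE)
}

# binary-factor prevalence rows (reference level "lo")
prev_binary <- function(factor_id = "f1", p_hi = 0.5, tier = 1) {
  data.frame(factor_id = factor_id, level = c("lo", "hi"),
             prevalence = c(1 - p_hi, p_hi), tier = tier, source_note = "",
             reference = c(TRUE, FALSE), stringsAsFactors = FALSE)
}

# three-study table exercising CI / p-value / reported-SE variability
three_study_table <- function() {
  rbind(
    est_row("S1", "f1", "hi", value = 2.0, ci_low = 1.2, ci_high = 3.3),
    est_row("S1", "f2", "hi", value = 1.5, p_value = 0.04),
    est_row("S2", "f1", "hi", value = 2.4, se = 0.25),
    est_row("S2", "f2", "hi", value = 0.7, ci_low = 0.5, ci_high = 0.98),
    est_row("S3", "f1", "hi", value = 3.1, ci_low = 1.8, ci_high = 5.3),
    est_row("S3", "f2", "hi", value = 1.8, p_value = 0.01))
}

pearson_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  (a * d - b * c)^2 * n / ((a + b) * (c + d) * (b + d) * (a + c))
}

# independent DerSimonian-Laird oracle: literal textbook formulas, scalar loops
dl_oracle <- function(y, s) {
  k <- length(y)
  if (k == 1) return(list(mu = y, se = s, tau2 = 0))
  w <- numeric(k)
  for (i in seq_len(k)) w[i] <- 1 / s[i]^2
  ybar <- sum(w * y) / sum(w)
  Q <- 0
  for (i in seq_len(k)) Q <- Q + w[i] * (y[i] - ybar)^2
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- numeric(k)
  for (i in seq_len(k)) ws[i] <- 1 / (s[i]^2 + tau2)
  list(mu = sum(ws * y) / sum(ws), se = sqrt(1 / sum(ws)), tau2 = tau2)
}

# generative log-risk score of a profile (sum of true log odds ratios)
truth_score <- function(profiles, layout) {
  vapply(seq_len(nrow(profiles)), function(i) {
    s <- 0
    for (f in unique(layout$factor_id)) {
      lev <- profiles[[f]][i]
      if (is.na(lev)) next
      s <- s + layout$log_or[layout$factor_id == f & layout$level == lev]
    }
    s
  }, numeric(1))
}
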