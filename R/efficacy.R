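#' POMS2 total mood disturbance (TMD) score
#'
#' TMD is the sum of the five negative-mood subscales (anger-hostility,
#' confusion-bewilderment, depression-dejection, fatigue-inertia,
#' tension-anxiety) minus vigor-activity. Friendliness does not enter.
#'
#' @param scores Data frame (or named list) with numeric columns
#'   `anger_hostility`, `confusion_bewilderment`, `depression_dejection`,
#'   `fatigue_inertia`, `tension_anxiety`, `vigor_activity`.
#' @return Numeric vector of TMD scores.
#' @examples
#' tmd_score(data.frame(anger_hostility = 2, confusion_bewilderment = 2,
#'                      depression_dejection = 2, fatigue_inertia = 2,
#'                      tension_anxiety = 2, vigor_activity = 3))
#' @export
tmd_score <- function(scores) {
  need <- c("anger_hostility", "confusion_bewilderment", "depression_dejection",
            "fatigue_inertia", "tension_anxiety", "vigor_activity")
  missing_sub <- setdiff(need, names(scores))
  if (length(missing_sub) > 0) {
    stop("missing subscale(s): ", paste(missing_sub, collapse = ", "))
  }
  vals <- lapply(need, function(nm) scores[[nm]])
  if (any(vapply(vals, function(v) any(is.na(v)), logical(1)))) {
    stop("missing data in subscale values")
  }
  (vals[[1]] + vals[[2]] + vals[[3]] + vals[[4]] + vals[[5]]) - vals[[6]]
}

#' Fill change scores (post minus pre) on a trial table
#'
#' Adds `change = outcome_post - outcome_pre` to each record. Records with a
#' missing pre or post value are excluded listwise, with a message giving
#' the count (the excluded count is also attached as attribute
#' `n_excluded`).
#'
#' @param records Data frame with columns `outcome_pre` and `outcome_post`.
#' @return The records with a `change` column, incomplete rows dropped.
#' @export
compute_change_scores <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("outcome_pre", "outcome_post") %in% names(records)))
  ok <- !is.na(records$outcome_pre) & !is.na(records$outcome_post)
  if (any(!ok)) {
    message(sum(!ok), " record(s) excluded for missing pre or post values")
  }
  out <- records[ok, , drop = FALSE]
  out$change <- out$outcome_post - out$outcome_pre
  attr(out, "n_excluded") <- sum(!ok)
  out
}

# The treatment implied by the 2x2 design: sequence I is active-then-placebo,
# sequence II placebo-then-active.
implied_treatment <- function(sequence, period) {
  ifelse((sequence == "I") == (as.integer(period) == 1L), "active", "placebo")
}

validate_crossover <- function(records, outcome) {
  req <- c("subject_id", "sequence", "period", "treatment")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop("records must contain columns ", paste(req, collapse = ", "))
  }
  if (!all(records$sequence %in% c("I", "II"))) {
    stop("sequence must be 'I' (active-then-placebo) or 'II' (placebo-then-active)")
  }
  if (!all(as.integer(records$period) %in% 1:2)) stop("period must be 1 or 2")
  if (!all(records$treatment %in% c("active", "placebo"))) {
    stop("treatment must be 'active' or 'placebo'")
  }
  bad <- records$treatment != implied_treatment(records$sequence, records$period)
  if (any(bad)) {
    stop(sum(bad), " record(s) have a treatment inconsistent with their ",
         "(sequence, period) cell")
  }
  if (anyDuplicated(records[, c("subject_id", "period")])) {
    stop("each subject may contribute at most one record per period")
  }
  if (!outcome %in% names(records)) {
    stop("outcome column '", outcome, "' not found")
  }
  invisible(records)
}

#' Treatment effect in a 2x2 crossover by linear mixed model
#'
#' Fits `outcome ~ sequence + period + treatment + (1 | subject)` by REML
#' (compound-symmetric subject covariance) and reports the active-minus-
#' placebo contrast with a 95% CI and two-sided p-value. Degrees of freedom
#' use the between-within partition: for the within-subject treatment
#' contrast in a 2x2 design this is (number of subjects used) - 2.
#' Incomplete subjects (one period only) are excluded with a message.
#'
#' @param records Trial table with columns `subject_id`, `sequence` (I/II),
#'   `period` (1/2), `treatment` (active/placebo) and the outcome column.
#'   If `outcome` is `"change"` and the column is absent but
#'   `outcome_pre`/`outcome_post` are present, change scores are computed
#'   first.
#' @param outcome Name of the outcome column (default `"change"`).
#' @return A list of class `crossover_fit`: `effect` (active - placebo),
#'   `se`, `ci_low`, `ci_high`, `p_value`, `df`, `fixed_effects` (sequence
#'   and period estimates), `n_used` (subjects), and `means` (per-treatment
#'   mean and SD of the outcome).
#' @export
fit_crossover <- function(records, outcome = "change") {
  if (identical(outcome, "change") && !"change" %in% names(records) &&
      all(c("outcome_pre", "outcome_post") %in% names(records))) {
    records <- compute_change_scores(records)
  }
  validate_crossover(records, outcome)
  y <- records[[outcome]]
  keep <- !is.na(y)
  if (any(!keep)) {
    message(sum(!keep), " record(s) excluded for missing outcome")
    records <- records[keep, , drop = FALSE]
    y <- y[keep]
  }
  complete <- names(which(table(records$subject_id) == 2L))
  drop_n <- length(unique(records$subject_id)) - length(complete)
  if (drop_n > 0) {
    message(drop_n, " incomplete subject(s) excluded")
    records <- records[records$subject_id %in% complete, , drop = FALSE]
    y <- records[[outcome]]
  }
  seq_of <- tapply(records$sequence, records$subject_id, `[`, 1)
  n_per_seq <- table(factor(seq_of, levels = c("I", "II")))
  if (any(n_per_seq == 0)) {
    stop("inestimable sequence effect: all subjects are in one sequence")
  }
  if (any(n_per_seq < 2)) stop("need >= 2 subjects per sequence")
  n_used <- length(complete)
  df <- n_used - 2

  means <- do.call(rbind, lapply(c("active", "placebo"), function(tr) {
    v <- y[records$treatment == tr]
    data.frame(treatment = tr, mean = mean(v), sd = stats::sd(v), n = length(v))
  }))

  if (stats::sd(y) == 0) {
    # Degenerate: no variation at all; the contrast is 0 with no evidence.
    return(structure(list(effect = 0, se = 0, ci_low = 0, ci_high = 0,
                          p_value = 1, df = df,
                          fixed_effects = c(sequenceII = 0, period2 = 0),
                          n_used = n_used, means = means,
                          outcome = outcome),
                     class = "crossover_fit"))
  }

  dat <- data.frame(
    y = y,
    subject = factor(records$subject_id),
    sequence = factor(records$sequence, levels = c("I", "II")),
    period = factor(as.integer(records$period), levels = 1:2),
    treatment = factor(records$treatment, levels = c("placebo", "active"))
  )
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ sequence + period + treatment + (1 | subject), data = dat,
               REML = TRUE)
  ))
  fe <- lme4::fixef(fit)
  if (!"treatmentactive" %in% names(fe)) {
    stop("singular design: the treatment term is aliased with ",
         paste(setdiff(c("sequenceII", "period2"), names(fe)), collapse = ", "))
  }
  effect <- unname(fe["treatmentactive"])
  se <- sqrt(diag(as.matrix(stats::vcov(fit)))[["treatmentactive"]])
  tval <- effect / se
  p <- 2 * stats::pt(-abs(tval), df)
  hw <- stats::qt(0.975, df) * se
  structure(list(effect = effect, se = se,
                 ci_low = effect - hw, ci_high = effect + hw,
                 p_value = p, df = df,
                 fixed_effects = fe[intersect(c("sequenceII", "period2"), names(fe))],
                 n_used = n_used, means = means, outcome = outcome),
            class = "crossover_fit")
}

#' @export
print.crossover_fit <- function(x, ...) {
  cat(sprintf("2x2 crossover treatment effect (%s), n = %d subjects\n",
              x$outcome, x$n_used))
  cat(sprintf("  active - placebo: %.3f (95%% CI %.3f to %.3f), p = %.4g (df = %d)\n",
              x$effect, x$ci_low, x$ci_high, x$p_value, x$df))
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Independent two-sample t-test for baseline comparisons
#'
#' Pooled-variance Student's t by default (the printed baseline p-values
#' reproduce under pooled arithmetic); set `var_equal = FALSE` for Welch.
#' Zero pooled variance is handled by convention: equal means give p = 1,
#' unequal means give p = 0.
#'
#' @param x,y Numeric vectors (>= 2 values each).
#' @param var_equal Pool the variances (default `TRUE`).
#' @return List with `t`, `df`, `p`.
#' @export
baseline_t_test <- function(x, y, var_equal = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Two-sample t-test from printed summary statistics
#'
#' Reproduces a pooled (or Welch) two-sample t-test from group means, SDs
#' and sizes, as needed to check published baseline tables.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return List with `t`, `df`, `p`.
#' @examples
#' baseline_t_test_summary(52.0, 6.4, 20, 52.2, 6.5, 20)
#' @export
baseline_t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                    var_equal = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    return(list(t = if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf,
                df = df, p = as.numeric(mean1 == mean2)))
  }
  tval <- (mean1 - mean2) / se
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric point probabilities no larger
#' than that of the observed table (the classical convention). A table with
#' a zero margin carries no information about association; p = 1 is
#' returned by convention with a message.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(7, 9, 13, 11), nrow = 2))
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(tab != round(tab)) || any(!is.finite(tab))) {
    stop("table must be a 2x2 matrix of non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    message("zero margin: p = 1 by convention")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}
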