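#' Compare patient characteristics between device cohorts
#'
#' Produces a Table-1-style screening comparison: categorical covariates
#' are tested with two-sided Fisher's exact tests, continuous covariates
#' with Mann-Whitney U-tests. The per-cohort summary is `n (pct%)` for
#' categorical and `mean (sd)` for continuous variables. Degenerate
#' categorical variables (a single observed level) get p = 1.
#'
#' @param covariates tibble from [build_covariates()].
#' @param group column name of the grouping factor (default
#'   `device_cohort`); exactly two non-empty groups are required.
#' @return A tibble of comparison results: `variable`, `test`, one summary
#'   column per cohort, `p_value`.
#' @export
compare_cohorts <- function(covariates, group = "device_cohort") {
  g <- factor(covariates[[group]])
  if (nlevels(g) != 2 || any(table(g) < 2)) {
    abort("compare_cohorts() needs two groups with at least 2 patients each",
          class = "copdpersist_arg_error")
  }
  lv <- levels(g)
  comorbs <- names(atc_config()$comorbidity_map)
  vars <- c(list(c("gender", "categorical"),
                 c("age_years", "continuous"),
                 c("prescriber_specialist", "categorical"),
                 c("ses_score", "continuous")),
            lapply(comorbs, function(v) c(v, "categorical")),
            list(c("n_comorbidities", "continuous"),
                 c("saba_any", "categorical"),
                 c("ocs_courses_yearly", "continuous"),
                 c("initial_medication", "categorical"),
                 c("dosing_regimen", "continuous")))
  rows <- lapply(vars, function(v) {
    nm <- v[1]; type <- v[2]
    x <- covariates[[nm]]
    if (type == "continuous") {
      p <- suppressWarnings(
        wilcox.test(x[g == lv[1]], x[g == lv[2]], exact = NULL)$p.value)
      if (!is.finite(p)) p <- 1   # zero-variance variable: no evidence
      s1 <- sprintf("%.2f (%.2f)", mean(x[g == lv[1]]), stats::sd(x[g == lv[1]]))
      s2 <- sprintf("%.2f (%.2f)", mean(x[g == lv[2]]), stats::sd(x[g == lv[2]]))
      test <- "mann_whitney"
    } else {
      if (is.logical(x)) x <- factor(x, levels = c(FALSE, TRUE))
      x <- factor(x)
      tab <- table(x, g)
      p <- if (nrow(tab) < 2) 1 else
        min(fisher.test(tab, workspace = 2e6)$p.value, 1)  # fp summation can tip over 1
      lead <- if (nlevels(x) == 2) 2 else 1   # TRUE / "male" count
      s1 <- sprintf("%d (%.1f%%)", tab[lead, 1], 100 * tab[lead, 1] / sum(tab[, 1]))
      s2 <- sprintf("%d (%.1f%%)", tab[lead, 2], 100 * tab[lead, 2] / sum(tab[, 2]))
      test <- "fisher_exact"
    }
    out <- tibble(variable = nm, test = test, s1 = s1, s2 = s2, p_value = p)
    names(out)[names(out) == "s1"] <- lv[1]
    names(out)[names(out) == "s2"] <- lv[2]
    out
  })
  bind_rows(rows)
}

#' Select Cox adjusters from the cohort comparison
#'
#' Variables whose two-cohort comparison reached p < alpha (strict
#' inequality) enter the multivariate model, in the stable order of the
#' comparison table.
#'
#' @param comparisons tibble from [compare_cohorts()].
#' @param alpha significance screen (default 0.05).
#' @return Character vector of variable names.
#' @export
select_adjusters <- function(comparisons, alpha = 0.05) {
  comparisons$variable[comparisons$p_value < alpha]
}

#' Kaplan-Meier persistence curve
#'
#' Right-continuous survival step function for time to discontinuation,
#' overall or per group. With no censoring before the horizon the curve at
#' the horizon equals the empirically persistent fraction.
#'
#' @param time days to discontinuation or censoring (>= 0).
#' @param event 1/TRUE = discontinuation observed, 0/FALSE = censored.
#' @param group optional grouping vector (e.g. device cohort).
#' @return Tibble: `group`, `time`, `n_risk`, `n_event`, `surv`, starting
#'   at time 0 with survival 1.
#' @export
km_curve <- function(time, event, group = NULL) {
  if (any(time < 0)) {
    abort("negative time supplied to km_curve()",
          class = "copdpersist_arg_error")
  }
  event <- as.integer(event)
  if (is.null(group)) group <- rep("overall", length(time))
  df <- data.frame(time = time, event = event, group = group)
  out <- lapply(split(df, df$group), function(d) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    tibble(group = d$group[1],
           time = c(0, fit$time),
           n_risk = c(nrow(d), fit$n.risk),
           n_event = c(0, fit$n.event),
           surv = c(1, fit$surv))
  })
  bind_rows(out)
}

#' Cox proportional-hazards estimate of the device effect
#'
#' Fits a Cox model for time to discontinuation of initial therapy with the
#' multiple-dose device cohort compared against the single-dose reference,
#' optionally adjusted for screening-selected covariates. Ties are handled
#' with the Efron approximation (day-granular discontinuation times are
#' heavily tied); the confidence interval is the Wald interval on the log
#' hazard scale.
#'
#' @param covariates tibble from [build_covariates()].
#' @param persistence per-patient tibble from [cohort_persistence()];
#'   persistent patients are censored at the horizon.
#' @param adjusters character vector of covariate names (possibly empty:
#'   univariate model).
#' @param reference device cohort used as reference (default single-dose).
#' @return A list of class `hazard_result`: `hazard_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `adjusters`, `reference_group`, `n`, `n_events`
#'   and the underlying `fit`.
#' @export
cox_device_effect <- function(covariates, persistence,
                              adjusters = character(),
                              reference = "single_dose_dpi") {
  df <- left_join(covariates, persistence, by = "patient_id")
  if (anyNA(df$persistent)) {
    abort("persistence results missing for some covariate rows",
          class = "copdpersist_arg_error")
  }
  df$event <- as.integer(!df$persistent)
  df$time <- ifelse(df$persistent, df$horizon,
                    pmax(df$discontinuation_day, 0.5))
  if (sum(df$event) == 0) {
    abort("no discontinuation events: the partial likelihood carries no information",
          class = "copdpersist_degenerate_error")
  }
  df$device_cohort <- stats::relevel(factor(df$device_cohort), ref = reference)
  if ("initial_medication" %in% names(df)) {
    df$initial_medication <- stats::relevel(
      factor(df$initial_medication), ref = "formoterol")
  }
  if ("gender" %in% names(df)) df$gender <- factor(df$gender)
  rhs <- paste(c("device_cohort", adjusters), collapse = " + ")
  fit <- survival::coxph(as.formula(paste("survival::Surv(time, event) ~", rhs)),
                         data = df, ties = "efron")
  co <- summary(fit)
  term <- grep("^device_cohort", rownames(co$coefficients), value = TRUE)[1]
  if (is.na(fit$coefficients[term]) || !is.finite(fit$coefficients[term])) {
    abort(paste0("Cox model did not converge; iterations: ", fit$iter),
          class = "copdpersist_convergence_error")
  }
  structure(list(
    hazard_ratio = unname(co$coefficients[term, "exp(coef)"]),
    ci_low = unname(co$conf.int[term, "lower .95"]),
    ci_high = unname(co$conf.int[term, "upper .95"]),
    p_value = unname(co$coefficients[term, "Pr(>|z|)"]),
    adjusters = adjusters,
    reference_group = reference,
    n = nrow(df),
    n_events = sum(df$event),
    fit = fit
  ), class = "hazard_result")
}

#' @export
print.hazard_result <- function(x, ...) {
  cat(sprintf("Cox device effect (vs %s): HR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$reference_group, x$hazard_ratio, x$ci_low, x$ci_high,
              x$p_value))
  cat(sprintf("  n = %d, events = %d; adjusters: %s\n", x$n, x$n_events,
              if (length(x$adjusters)) paste(x$adjusters, collapse = ", ")
              else "(none)"))
  invisible(x)
}
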