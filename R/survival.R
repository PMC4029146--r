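#' Build the survival endpoints from per-patient dates
#'
#' Constructs the three endpoints analysed for a re-irradiated cohort:
#' post-recurrence survival (PRS, from the first day of re-irradiation to
#' death or last follow-up), progression-free survival (PFS, re-irradiation
#' to progression or censoring) and overall survival (OS, from the start of
#' the initial radiotherapy), plus the inter-treatment interval. Durations
#' are calendar-day differences; month values use the fixed 30 days/month
#' convention ([days_to_months()]).
#'
#' @param cohort A tibble with one row per patient and `Date` (or
#'   date-coercible) columns `rt1_start`, `rert_start`, and per-patient
#'   `death_date`, `progression_date`, `last_followup` (NA where the event
#'   was not observed; `last_followup` required for censored patients).
#' @return A tibble with `patient_id`, `interval_days`, `interval_months`,
#'   `prs_days`/`prs_event`, `pfs_days`/`pfs_event`, `os_days`/`os_event`.
#' @export
compute_endpoints <- function(cohort) {
  required <- c("patient_id", "rt1_start", "rert_start")
  missing <- setdiff(required, names(cohort))
  if (length(missing))
    abort_validation(paste0("cohort missing column(s): ",
                            paste(missing, collapse = ", ")))
  as_d <- function(x) as.Date(x)
  rt1 <- as_d(cohort$rt1_start)
  rert <- as_d(cohort$rert_start)
  if (anyNA(rert)) abort_validation("re-irradiation start date missing")
  death <- if ("death_date" %in% names(cohort)) as_d(cohort$death_date) else
    as.Date(rep(NA, nrow(cohort)))
  prog <- if ("progression_date" %in% names(cohort)) as_d(cohort$progression_date) else
    as.Date(rep(NA, nrow(cohort)))
  fu <- if ("last_followup" %in% names(cohort)) as_d(cohort$last_followup) else
    as.Date(rep(NA, nrow(cohort)))
  if (any(!is.na(death) & death < rert))
    abort_validation("death date precedes re-irradiation start")
  if (any(is.na(death) & is.na(fu)))
    abort_validation("censored patient without last follow-up date")
  end <- dplyr::if_else(is.na(death), fu, death)
  prog_end <- dplyr::if_else(is.na(prog), end, prog)
  tibble::tibble(
    patient_id = cohort$patient_id,
    interval_days = as.integer(rert - rt1),
    interval_months = days_to_months(as.integer(rert - rt1)),
    prs_days = as.integer(end - rert),
    prs_event = as.integer(!is.na(death)),
    pfs_days = as.integer(prog_end - rert),
    pfs_event = as.integer(!is.na(prog) | !is.na(death)),
    os_days = as.integer(end - rt1),
    os_event = as.integer(!is.na(death))
  )
}

#' Kaplan-Meier estimate with the cohort's median-survival convention
#'
#' Product-limit estimator (via [survival::survfit()]), overall or by
#' group. The median survival is the smallest time with S(t) <= 0.5,
#' reported as `NA` ("not reached") while S stays above 0.5.
#'
#' @param data A tibble of survival records.
#' @param time,event Column names (strings) of the follow-up time (days)
#'   and event indicator (1 = event, 0 = censored).
#' @param group Optional column name of a grouping factor.
#' @return A `km_fit` object; use [tidy()][generics::tidy] for the curve,
#'   [glance()][generics::glance] for medians, [autoplot()] to plot.
#' @export
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3, 4), event = 1)
#' glance(km_estimate(d, "time", "event"))$median
km_estimate <- function(data, time = "time_days", event = "event",
                        group = NULL) {
  if (nrow(data) == 0L) abort_validation("no survival records")
  if (any(data[[time]] < 0, na.rm = TRUE))
    abort_validation("survival times must be >= 0")
  df <- data.frame(.time = data[[time]], .event = data[[event]])
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(.time, .event) ~ 1, data = df)
    strata <- rep("all", length(fit$time))
  } else {
    df$.group <- factor(data[[group]])
    fit <- survival::survfit(survival::Surv(.time, .event) ~ .group, data = df)
    strata <- if (is.null(fit$strata)) rep(levels(df$.group)[1], length(fit$time)) else
      rep(sub("^\\.group=", "", names(fit$strata)), fit$strata)
  }
  curve <- tibble::tibble(
    group = strata, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, n_censor = fit$n.censor, survival = fit$surv
  )
  medians <- curve |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = sum(.data$n_event) + sum(.data$n_censor),
      events = sum(.data$n_event),
      median = {
        hit <- .data$time[.data$survival <= 0.5]
        if (length(hit)) min(hit) else NA_real_
      },
      .groups = "drop"
    )
  structure(list(curve = curve, medians = medians, survfit = fit),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> Kaplan-Meier estimate\n")
  print(x$medians)
  invisible(x)
}

#' @export
tidy.km_fit <- function(x, ...) x$curve

#' @export
glance.km_fit <- function(x, ...) x$medians

#' Plot Kaplan-Meier curves
#' @param object A `km_fit`.
#' @param ... Unused.
#' @return A ggplot step plot of the survival curves.
#' @export
autoplot.km_fit <- function(object, ...) {
  curve <- object$curve |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1), .x[, c("time", "survival")])) |>
    dplyr::ungroup()
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$survival,
                                      colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time [days]", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank test (via
#' [survival::survdiff()]) with a two-sided p-value. When neither group
#' has any event the statistic is 0 and p = 1.
#'
#' @inheritParams km_estimate
#' @param group Column name of the two-level grouping factor.
#' @return A tibble with `chisq`, `df`, `p`.
#' @export
logrank <- function(data, time = "time_days", event = "event",
                    group = "group") {
  g <- factor(data[[group]])
  if (nlevels(g) != 2L) abort_validation("log-rank needs exactly two groups")
  if (any(table(g) == 0L)) abort_validation("both groups must be non-empty")
  if (sum(data[[event]]) == 0)
    return(tibble::tibble(chisq = 0, df = 1L, p = 1))
  df <- data.frame(.time = data[[time]], .event = data[[event]], .group = g)
  sd <- survival::survdiff(survival::Surv(.time, .event) ~ .group, data = df)
  tibble::tibble(chisq = sd$chisq, df = 1L,
                 p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling (appropriate for
#' day-resolution data with many ties), reporting the hazard ratio
#' exp(beta) with Wald 95% confidence interval and p-value. A constant
#' covariate or a non-converging fit raises an explicit error.
#'
#' @inheritParams km_estimate
#' @param covariate Column name of the covariate (numeric or two-level
#'   factor).
#' @return A `cox_fit` object; [tidy()][generics::tidy] gives one row with
#'   `term`, `estimate` (log HR), `hr`, `conf_low`, `conf_high`,
#'   `std_error`, `statistic`, `p_value`.
#' @export
cox_univariate <- function(data, time = "time_days", event = "event",
                           covariate = "covariate") {
  x <- data[[covariate]]
  if (is.character(x) || is.logical(x)) x <- factor(x)
  xv <- if (is.factor(x)) as.integer(x) else x
  if (length(unique(xv[!is.na(xv)])) < 2L)
    abort_validation(sprintf("covariate '%s' is constant; Cox model not identifiable",
                             covariate))
  df <- data.frame(.time = data[[time]], .event = data[[event]], .x = x)
  # convergence is checked explicitly below, so coxph's "coefficient may be
  # infinite" warnings are redundant here
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph(survival::Surv(.time, .event) ~ .x, data = df,
                      ties = "efron")),
    error = function(e) abort_validation(paste0("Cox fit failed: ",
                                                conditionMessage(e)))
  )
  beta <- unname(stats::coef(fit)[1L])
  se <- sqrt(diag(stats::vcov(fit)))[1L]
  if (!is.finite(beta) || !is.finite(se) || se > 50)
    abort_validation("Cox fit did not converge (possible complete separation)")
  z <- beta / se
  structure(list(
    summary = tibble::tibble(
      term = covariate, estimate = beta, hr = exp(beta),
      conf_low = exp(beta - 1.96 * se), conf_high = exp(beta + 1.96 * se),
      std_error = unname(se), statistic = unname(z),
      p_value = 2 * stats::pnorm(-abs(z))),
    coxph = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cox_fit> %s: HR %.2f (95%%CI %.2f; %.2f), p = %.3g\n",
              s$term, s$hr, s$conf_low, s$conf_high, s$p_value))
  invisible(x)
}

#' @export
tidy.cox_fit <- function(x, ...) x$summary

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$coxph$n, nevent = x$coxph$nevent,
                 logLik = as.numeric(stats::logLik(x$coxph)))
}

#' Two-sample and contingency-table tests
#'
#' The non-survival comparisons used for cohort tables: Mann-Whitney U
#' (unpaired ranks), paired Wilcoxon signed-rank, and Fisher's exact test
#' on a 2x2 count table. All p-values are two-sided. A degenerate paired
#' Wilcoxon with all differences zero returns p = 1 by convention.
#'
#' @param x,y Numeric samples (for `fisher_exact`, pass `table` instead).
#' @param method One of `"mann_whitney"`, `"wilcoxon_paired"`,
#'   `"fisher_exact"`.
#' @param table A 2x2 matrix of counts for `fisher_exact`.
#' @return A tibble with `method`, `statistic`, `p`.
#' @export
#' @examples
#' two_sample_tests(table = matrix(c(2, 0, 0, 2), 2), method = "fisher_exact")
two_sample_tests <- function(x = NULL, y = NULL,
                             method = c("mann_whitney", "wilcoxon_paired",
                                        "fisher_exact"),
                             table = NULL) {
  method <- match.arg(method)
  if (method == "fisher_exact") {
    if (is.null(table) || !all(dim(table) == c(2L, 2L)))
      abort_validation("fisher_exact needs a 2x2 count table")
    ft <- stats::fisher.test(table)
    return(tibble::tibble(method = method, statistic = unname(ft$estimate),
                          p = ft$p.value))
  }
  if (is.null(x) || is.null(y) || !length(x) || !length(y))
    abort_validation("both samples must be non-empty")
  if (method == "wilcoxon_paired") {
    if (length(x) != length(y))
      abort_validation("paired samples must have equal length")
    if (all(x == y))
      return(tibble::tibble(method = method, statistic = 0, p = 1))
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
  }
  tibble::tibble(method = method, statistic = unname(wt$statistic),
                 p = wt$p.value)
}

#' Univariate analysis table across endpoints
#'
#' Fits a univariate Cox model for every covariate x endpoint combination,
#' mirroring the cohort's reporting format (HR, 95% CI, p per endpoint).
#' Covariates that fail to fit (e.g. constant in the cohort) are reported
#' with `NA` and a note rather than aborting the table.
#'
#' @param cohort Patient tibble holding the covariate columns.
#' @param endpoints Output of [compute_endpoints()] for the same patients
#'   (matched by `patient_id`).
#' @param covariates Character vector of covariate column names in
#'   `cohort`.
#' @param endpoint_names Endpoints to analyse, a subset of
#'   `c("prs", "pfs", "os")`.
#' @return A tibble with `variable`, `endpoint`, `hr`, `conf_low`,
#'   `conf_high`, `p`, `note`.
#' @export
univariate_table <- function(cohort, endpoints,
                             covariates,
                             endpoint_names = c("prs", "pfs", "os")) {
  dat <- dplyr::inner_join(cohort, endpoints, by = "patient_id")
  grid <- tidyr::expand_grid(variable = covariates, endpoint = endpoint_names)
  purrr::pmap(grid, function(variable, endpoint) {
    res <- tryCatch(
      tidy(cox_univariate(dat, time = paste0(endpoint, "_days"),
                          event = paste0(endpoint, "_event"),
                          covariate = variable)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      tibble::tibble(variable = variable, endpoint = endpoint,
                     hr = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
                     p = NA_real_, note = "not estimable")
    } else {
      tibble::tibble(variable = variable, endpoint = endpoint,
                     hr = res$hr, conf_low = res$conf_low,
                     conf_high = res$conf_high, p = res$p_value, note = "")
    }
  }) |>
    dplyr::bind_rows()
}
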