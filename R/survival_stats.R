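# Survival layer: Kaplan-Meier estimation, log-rank comparison and Cox
# proportional-hazards models for progression-free survival, built on the
# survival package with Efron tie handling pinned for reproducibility.

#' Kaplan-Meier product-limit estimator
#'
#' @param time positive follow-up times (months).
#' @param event event indicator (1/TRUE = progression or death, 0/FALSE =
#'   censored).
#' @return object of class `km_fit` wrapping `survival::survfit`, with
#'   `S(0) = 1` and right-continuous steps at event times.
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0) stop("no records", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be finite and positive", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  structure(list(fit = fit), class = "km_fit")
}

#' Survival probability at a time point
#'
#' Evaluates the right-continuous Kaplan-Meier step function; `t = 36`
#' months gives the 3-year progression-free survival.
#'
#' @param km a [kaplan_meier()] fit.
#' @param t time(s), months.
#' @return survival probabilities in `[0, 1]`.
#' @export
survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_fit"))
  f <- km$fit
  stats::stepfun(f$time, c(1, f$surv), right = FALSE)(t)
}

#' Kaplan-Meier step table
#'
#' @param km a [kaplan_meier()] fit.
#' @return data.frame with `time`, `n_risk`, `n_event`, `survival`, one
#'   row per distinct time.
#' @export
km_table <- function(km) {
  stopifnot(inherits(km, "km_fit"))
  f <- km$fit
  data.frame(time = f$time, n_risk = f$n.risk, n_event = f$n.event,
             survival = f$surv)
}

#' Two-group log-rank test
#'
#' @param time,event as in [kaplan_meier()].
#' @param group two-level grouping (factor or vector).
#' @return list with `chi2`, `p_value`, `df`.
#' @export
log_rank <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(droplevels(g[!is.na(g)])) < 2) {
    stop("log-rank needs two groups, each with at least one record",
         call. = FALSE)
  }
  sd <- survival::survdiff(
    survival::Surv(time, as.integer(event)) ~ g)
  df <- length(sd$n) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron tie handling (pinned default). Wald
#' 95% confidence intervals and p-values per covariate, for univariate or
#' user-specified multivariate models.
#'
#' @param data data.frame holding the time, event and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param time_col,event_col column names of time and event.
#' @param ties tie-handling method passed to `survival::coxph`.
#' @return data.frame of class `cox_result`: one row per model term with
#'   `term`, `hazard_ratio`, `ci95_low`, `ci95_high`, `p_value`;
#'   attributes `n`, `n_events`, `ties`. Possible complete separation
#'   (|log HR| > 10) is flagged with a warning.
#' @export
cox_ph <- function(data, covariates, time_col = "pfs_months",
                   event_col = "event", ties = "efron") {
  stopifnot(length(covariates) >= 1)
  n_events <- sum(as.integer(data[[event_col]]) == 1, na.rm = TRUE)
  if (n_events < length(covariates) + 1) {
    stop("insufficient events (", n_events, ") for ", length(covariates),
         " covariate(s)", call. = FALSE)
  }
  f <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(f, data = data, ties = ties)
  if (!is.null(fit$info) || any(is.na(stats::coef(fit)))) {
    stop("Cox model did not converge to a full-rank fit", call. = FALSE)
  }
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  out <- data.frame(term = rownames(co),
                    hazard_ratio = unname(co[, "exp(coef)"]),
                    ci95_low = unname(ci[, "lower .95"]),
                    ci95_high = unname(ci[, "upper .95"]),
                    p_value = unname(co[, "Pr(>|z|)"]),
                    stringsAsFactors = FALSE)
  if (any(abs(co[, "coef"]) > 10)) {
    warning("very large |log HR|: possible complete separation",
            call. = FALSE)
  }
  attr(out, "n") <- s$n
  attr(out, "n_events") <- s$nevent
  attr(out, "ties") <- ties
  attr(out, "fit") <- fit
  class(out) <- c("cox_result", class(out))
  out
}

#' Survival report over grouping metrics
#'
#' For each metric, dichotomizes patients at the cohort median
#' ([median_split()]), estimates per-group Kaplan-Meier curves and 3-year
#' PFS (`S(36)`), runs the log-rank test and a univariate Cox model for
#' the low-vs-high contrast (reference: high). A multivariate model is
#' then fit for `multivariate_metric`, adjusting for every clinical
#' covariate whose own univariate Cox p-value is below `alpha`.
#'
#' @param summaries per-patient summary data.frame (from
#'   [patient_roi_summary()] rows) with `patient_id` and the metric
#'   columns.
#' @param clinical clinical data.frame with `patient_id`, `pfs_months`,
#'   `event` and covariates.
#' @param metrics character vector of summary columns to analyze.
#' @param multivariate_metric metric entering the multivariate model
#'   (default: first of `metrics`); `NULL` skips it.
#' @param covariates clinical covariates screened for the multivariate
#'   model (default: all non-outcome clinical columns).
#' @param alpha univariate screening threshold (default 0.05).
#' @return list of class `survival_report`: `by_metric` (one row per
#'   metric: split value, group sizes, 3-year PFS per group in percent,
#'   log-rank chi2/p, low-vs-high HR with CI and p), `km` (per metric, the
#'   per-group [km_table()]s), `covariate_screen` (univariate Cox over
#'   clinical covariates) and `multivariate` ([cox_ph()] result or
#'   `NULL`).
#' @export
survival_report <- function(summaries, clinical, metrics,
                            multivariate_metric = metrics[1],
                            covariates = NULL, alpha = 0.05) {
  dat <- merge(summaries, clinical, by = "patient_id")
  if (is.null(covariates)) {
    covariates <- setdiff(names(clinical),
                          c("patient_id", "pfs_months", "event"))
  }
  rows <- list()
  km_out <- list()
  group_of <- function(metric) {
    ms <- median_split(dat[[metric]], ids = dat$patient_id)
    ms$labels
  }
  for (m in metrics) {
    if (!m %in% names(dat)) stop("unknown metric: ", m, call. = FALSE)
    lab <- group_of(m)
    ok <- !is.na(lab)
    sub <- dat[ok, ]
    lab <- droplevels(lab[ok])
    sub$grp_low <- as.integer(lab == "low")
    km_hi <- kaplan_meier(sub$pfs_months[lab == "high"],
                          sub$event[lab == "high"])
    km_lo <- kaplan_meier(sub$pfs_months[lab == "low"],
                          sub$event[lab == "low"])
    lr <- log_rank(sub$pfs_months, sub$event, lab)
    cx <- cox_ph(sub, "grp_low")
    rows[[m]] <- data.frame(
      metric = m,
      split_value = stats::median(dat[[m]], na.rm = TRUE),
      n_high = sum(lab == "high"), n_low = sum(lab == "low"),
      pfs3y_high_pct = 100 * survival_at(km_hi, 36),
      pfs3y_low_pct = 100 * survival_at(km_lo, 36),
      logrank_chi2 = lr$chi2, logrank_p = lr$p_value,
      hr_low_vs_high = cx$hazard_ratio[1],
      hr_ci95_low = cx$ci95_low[1], hr_ci95_high = cx$ci95_high[1],
      cox_p = cx$p_value[1],
      stringsAsFactors = FALSE)
    km_out[[m]] <- list(high = km_table(km_hi), low = km_table(km_lo))
  }
  by_metric <- do.call(rbind, rows)
  rownames(by_metric) <- NULL

  screen <- lapply(covariates, function(v) {
    if (length(unique(dat[[v]][!is.na(dat[[v]])])) < 2) return(NULL)
    cx <- tryCatch(cox_ph(dat, v), error = function(e) NULL)
    if (is.null(cx)) return(NULL)
    data.frame(covariate = v, hazard_ratio = cx$hazard_ratio[1],
               ci95_low = cx$ci95_low[1], ci95_high = cx$ci95_high[1],
               p_value = cx$p_value[1], stringsAsFactors = FALSE)
  })
  screen <- do.call(rbind, screen)

  multi <- NULL
  if (!is.null(multivariate_metric)) {
    lab <- group_of(multivariate_metric)
    ok <- !is.na(lab)
    sub <- dat[ok, ]
    sub$ratio_low <- as.integer(lab[ok] == "low")
    sel <- if (is.null(screen)) character(0) else
      screen$covariate[screen$p_value < alpha]
    multi <- tryCatch(cox_ph(sub, c(sel, "ratio_low")),
                      error = function(e) {
                        warning("multivariate model not fit: ",
                                conditionMessage(e), call. = FALSE)
                        NULL
                      })
  }
  structure(list(by_metric = by_metric, km = km_out,
                 covariate_screen = screen, multivariate = multi),
            class = "survival_report")
}

#' @export
print.survival_report <- function(x, ...) {
  cat("<survival_report>\n")
  print(x$by_metric, row.names = FALSE)
  if (!is.null(x$multivariate)) {
    cat("multivariate model:\n")
    print(as.data.frame(x$multivariate), row.names = FALSE)
  }
  invisible(x)
}
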