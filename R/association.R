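# Association layer: median dichotomization, linear-regression
# correlation, Mann-Whitney U, Fisher's exact test, and the
# clinicopathological association table.

#' Split patients into high/low groups at the cohort median
#'
#' A patient is `high` iff their value is strictly greater than the
#' median; values equal to the median go to `low`. With an odd number of
#' distinct values (e.g. 81) this yields the (n-1)/2 high, (n+1)/2 low
#' split. `NA` values receive an `NA` label and are excluded from the
#' grouping only, never from the cohort.
#'
#' @param values numeric metric values, one per patient.
#' @param ids optional patient identifiers (defaults to `names(values)`).
#' @return object of class `group_labeling`: list with `labels` (factor
#'   `high`/`low`, named by `ids`), `split_value`, `n_high`, `n_low`.
#' @export
median_split <- function(values, ids = names(values)) {
  def <- !is.na(values)
  if (sum(def) < 2) {
    stop("median_split needs at least 2 defined values", call. = FALSE)
  }
  med <- stats::median(values[def])
  lab <- ifelse(values > med, "high", "low")
  lab[!def] <- NA
  labels <- factor(lab, levels = c("high", "low"))
  if (!is.null(ids)) names(labels) <- ids
  if (all(labels[def] == "low")) {
    warning("all values at or below the median; every patient labeled low",
            call. = FALSE)
  }
  structure(list(labels = labels, split_value = med,
                 n_high = sum(labels == "high", na.rm = TRUE),
                 n_low = sum(labels == "low", na.rm = TRUE)),
            class = "group_labeling")
}

#' @export
print.group_labeling <- function(x, ...) {
  cat(sprintf("<group_labeling> split at %g: %d high / %d low\n",
              x$split_value, x$n_high, x$n_low))
  invisible(x)
}

#' Correlation by ordinary least squares
#'
#' Fits `y ~ x` by OLS and reports the slope, intercept, Pearson r and the
#' two-sided p-value for slope != 0. Pairs with an undefined member are
#' dropped (with a message).
#'
#' @param x,y paired numeric vectors (per-field or per-patient values).
#' @return list with `slope`, `intercept`, `pearson_r`, `p_value`, `n`.
#' @export
linreg_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) message(sum(!ok), " pair(s) with undefined values dropped")
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 defined pairs", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("zero variance in x: slope undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["x", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       pearson_r = stats::cor(x, y),
       p_value = unname(cf["x", "Pr(>|t|)"]),
       n = length(x))
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' corrections. `U` is the number of (a, b) pairs with `a > b`.
#'
#' @param a,b numeric samples, both non-empty.
#' @return list with `U`, `p_value`, `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  exact <- (length(a) + length(b) <= 20) && !any(duplicated(c(a, b)))
  w <- stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  list(U = unname(w$statistic), p_value = w$p.value,
       method = if (exact) "exact" else "normal")
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Conditional (hypergeometric) exact test with the probability-ordering
#' two-sided p-value: the sum of probabilities of all tables with the
#' observed margins whose probability does not exceed that of the observed
#' table. The odds ratio is the conditional maximum-likelihood estimate.
#'
#' @param x 2x2 matrix of non-negative integer counts (rows = metric
#'   group, columns = clinical category), or the count `a` with `b`, `c`,
#'   `d` supplied.
#' @param b,c,d remaining counts when `x` is scalar `a`.
#' @return list with `odds_ratio`, `p_value`, `table`.
#' @export
fisher_exact_2x2 <- function(x, b = NULL, c = NULL, d = NULL) {
  if (!is.matrix(x)) {
    x <- matrix(c(x, b, c, d), nrow = 2, byrow = TRUE)
  }
  if (!all(dim(x) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(x) == 0) stop("empty table", call. = FALSE)
  ft <- stats::fisher.test(x)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = x)
}

#' Clinicopathological association table for one grouping
#'
#' For each clinical variable, tests association with the high/low
#' grouping: binary/categorical variables (exactly two observed levels)
#' get a 2x2 Fisher exact test; continuous variables get group medians,
#' ranges and a Mann-Whitney p-value. Variables with a single observed
#' level are skipped with a warning.
#'
#' @param clinical clinical data.frame (must contain `patient_id`).
#' @param grouping a [median_split()] result whose labels are named by
#'   patient id.
#' @param exclude columns ignored (identifiers and outcome by default).
#' @return data.frame: `variable`, `type`, `summary_high`, `summary_low`,
#'   `statistic`, `p_value`, `significant` (p < 0.05).
#' @export
clinico_association_table <- function(clinical, grouping,
                                      exclude = c("patient_id",
                                                  "pfs_months", "event")) {
  stopifnot(inherits(grouping, "group_labeling"))
  lab <- grouping$labels[match(clinical$patient_id, names(grouping$labels))]
  vars <- setdiff(names(clinical), exclude)
  rows <- list()
  for (v in vars) {
    val <- clinical[[v]]
    ok <- !is.na(val) & !is.na(lab)
    lv <- unique(val[ok])
    if (length(lv) < 2) {
      warning("variable '", v, "' has a single observed level; skipped",
              call. = FALSE)
      next
    }
    if (is.numeric(val) && length(lv) > 2) {
      hi <- val[ok & lab == "high"]
      lo <- val[ok & lab == "low"]
      mw <- mann_whitney_u(hi, lo)
      rows[[v]] <- data.frame(
        variable = v, type = "continuous",
        summary_high = sprintf("%g (%g-%g)", stats::median(hi), min(hi),
                               max(hi)),
        summary_low = sprintf("%g (%g-%g)", stats::median(lo), min(lo),
                              max(lo)),
        statistic = mw$U, p_value = mw$p_value,
        stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(lab[ok], levels = c("high", "low")),
                   factor(val[ok]))
      fe <- fisher_exact_2x2(unclass(tab)[, , drop = FALSE])
      lev <- colnames(tab)
      rows[[v]] <- data.frame(
        variable = v, type = "categorical",
        summary_high = sprintf("%s:%d/%s:%d", lev[1], tab[1, 1], lev[2],
                               tab[1, 2]),
        summary_low = sprintf("%s:%d/%s:%d", lev[1], tab[2, 1], lev[2],
                              tab[2, 2]),
        statistic = fe$odds_ratio, p_value = fe$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variable = character(), type = character(),
                      summary_high = character(), summary_low = character(),
                      statistic = numeric(), p_value = numeric())
  }
  out$significant <- out$p_value < 0.05
  rownames(out) <- NULL
  out
}
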