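# Statistical summary of stride metrics: per-metric simple linear
# regressions against stride time, condition contrasts, and variance
# comparisons. Strides are pooled across feet (left-right symmetry) and, when
# several runs are supplied, across runs; no mixed-effects structure is
# fitted. Residuals are returned so external tools can run distributional
# diagnostics.

REGRESSION_METRICS <- c("t_stance", "t_swing", "t_ps", "clearance_m", "ke_m",
                        "theta_bounce_deg", "gf_m")

#' Simple linear regression of stride time on a metric
#'
#' Ordinary least squares with stride time as the response and the metric as
#' the predictor, reporting the variance explained R^2, the slope b with its
#' significance p_b (t-statistic on the slope), and the intercept.
#'
#' @param table a `stride_metrics` table.
#' @param metric column name of the predictor.
#' @return One-row data.frame of class `regression_summary`: `metric`, `n`,
#'   `r_squared`, `slope`, `intercept`, `p_slope`; the model residuals are
#'   attached as attribute `"residuals"`.
#' @export
regress_vs_stride_time <- function(table, metric) {
  if (!metric %in% names(table)) stop("unknown metric column: ", metric)
  x <- table[[metric]]
  y <- table$t_stride
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 finite paired values", call. = FALSE)
  if (stats::sd(x[ok]) == 0) {
    stop("constant predictor: slope undefined for ", metric, call. = FALSE)
  }
  fit <- stats::lm(y[ok] ~ x[ok])
  sm <- summary(fit)
  out <- data.frame(metric = metric, n = sum(ok),
                    r_squared = sm$r.squared,
                    slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    p_slope = sm$coefficients[2, 4])
  attr(out, "residuals") <- unname(stats::residuals(fit))
  class(out) <- c("regression_summary", "data.frame")
  out
}

#' Regressions of stride time on every standard metric
#'
#' @param table a `stride_metrics` table.
#' @param metrics metric columns to regress (default: stance and swing time,
#'   stance percentage, clearance, kinetic-energy proxy, bounce angle, GRF
#'   proxy).
#' @return data.frame with one row per metric.
#' @export
regress_all_metrics <- function(table, metrics = REGRESSION_METRICS) {
  rows <- lapply(metrics, function(m) {
    tryCatch(regress_vs_stride_time(table, m), error = function(e) NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean and SD of each metric in a table
#' @keywords internal
condition_summary <- function(table, condition = "") {
  cols <- c("t_stride", "t_stance", "t_swing", "t_ps", "clearance_m", "ke_m",
            "theta_break_deg", "theta_prop_deg", "theta_bounce_deg", "gf_m")
  data.frame(condition = condition, metric = cols,
             mean = vapply(cols, function(cn) mean(table[[cn]], na.rm = TRUE),
                           0),
             sd = vapply(cols, function(cn) stats::sd(table[[cn]],
                                                      na.rm = TRUE), 0),
             n = vapply(cols, function(cn) sum(is.finite(table[[cn]])), 0),
             row.names = NULL)
}

#' Compare ascending and descending conditions
#'
#' Two-sample t-tests (pooled variance) comparing ascent and descent for the
#' stance percentage `t_ps`, clearance and bounce angle; one-sample t-tests
#' of the GRF proxy against zero within each condition; and an F-test of
#' Var(t_swing) against Var(t_stance) within each condition (the stair
#' geometry constrains the swing, so its variance is expected smaller).
#' Degenerate cells (zero variance) are flagged rather than tested.
#'
#' @param ascent,descent `stride_metrics` tables.
#' @return List of class `condition_contrast` with elements `tests`
#'   (data.frame: test, metric, condition, estimate, statistic, df, p_value,
#'   note) and `summary` (per-condition means and SDs).
#' @export
compare_conditions <- function(ascent, descent) {
  if (nrow(ascent) < 2 || nrow(descent) < 2) {
    stop("need at least 2 strides per condition", call. = FALSE)
  }
  tests <- list()
  add <- function(...) tests[[length(tests) + 1]] <<- data.frame(...)
  for (m in c("t_ps", "clearance_m", "theta_bounce_deg")) {
    a <- ascent[[m]]; d <- descent[[m]]
    a <- a[is.finite(a)]; d <- d[is.finite(d)]
    if (stats::sd(c(a, d)) == 0) {
      add(test = "two-sample t", metric = m, condition = "ascent-descent",
          estimate = mean(a) - mean(d), statistic = NA_real_, df = NA_real_,
          p_value = NA_real_, note = "zero variance: t undefined")
    } else {
      tt <- stats::t.test(a, d, var.equal = TRUE)
      add(test = "two-sample t", metric = m, condition = "ascent-descent",
          estimate = mean(a) - mean(d), statistic = unname(tt$statistic),
          df = unname(tt$parameter), p_value = tt$p.value, note = "")
    }
  }
  for (cond in c("ascent", "descent")) {
    tab <- if (cond == "ascent") ascent else descent
    g <- tab$gf_m[is.finite(tab$gf_m)]
    if (stats::sd(g) == 0) {
      add(test = "one-sample t", metric = "gf_m", condition = cond,
          estimate = mean(g), statistic = NA_real_, df = NA_real_,
          p_value = NA_real_, note = "zero variance: t undefined")
    } else {
      tt <- stats::t.test(g, mu = 0)
      add(test = "one-sample t", metric = "gf_m", condition = cond,
          estimate = mean(g), statistic = unname(tt$statistic),
          df = unname(tt$parameter), p_value = tt$p.value, note = "")
    }
    sw <- tab$t_swing[is.finite(tab$t_swing)]
    st <- tab$t_stance[is.finite(tab$t_stance)]
    if (stats::sd(sw) == 0 || stats::sd(st) == 0) {
      add(test = "F variance ratio", metric = "t_swing/t_stance",
          condition = cond, estimate = NA_real_, statistic = NA_real_,
          df = NA_real_, p_value = NA_real_,
          note = "zero variance: F undefined")
    } else {
      ft <- stats::var.test(sw, st)
      add(test = "F variance ratio", metric = "t_swing/t_stance",
          condition = cond, estimate = unname(ft$estimate),
          statistic = unname(ft$statistic), df = unname(ft$parameter[1]),
          p_value = ft$p.value, note = "")
    }
  }
  out <- list(tests = do.call(rbind, tests),
              summary = rbind(condition_summary(ascent, "ascent"),
                              condition_summary(descent, "descent")))
  class(out) <- "condition_contrast"
  out
}

#' @export
print.condition_contrast <- function(x, ...) {
  cat("Condition contrasts:\n")
  print(x$tests, digits = 4)
  cat("\nPer-condition summaries (mean +/- SD):\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write a regression/contrast report to CSV and a text summary
#'
#' @param regressions data.frame from [regress_all_metrics()], or `NULL`.
#' @param contrast a `condition_contrast`, or `NULL`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(regressions, contrast, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(regressions)) {
    utils::write.csv(regressions, file.path(dir, "regressions.csv"),
                     row.names = FALSE)
  }
  if (!is.null(contrast)) {
    utils::write.csv(contrast$tests, file.path(dir, "contrasts.csv"),
                     row.names = FALSE)
    utils::write.csv(contrast$summary, file.path(dir, "summaries.csv"),
                     row.names = FALSE)
  }
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  if (!is.null(regressions)) {
    writeLines("Stride-time regressions (t_stride ~ metric):", con)
    utils::capture.output(print(regressions, digits = 4), file = con)
  }
  if (!is.null(contrast)) {
    utils::capture.output(print(contrast), file = con)
  }
  invisible(dir)
}
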