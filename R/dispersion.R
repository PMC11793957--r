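# Variance-heterogeneity analyses: is risk taking more variable among
# participants with fewer resources?

#' Two-sample variance-ratio F test
#'
#' Compares the sample variances of two groups of observations with the
#' classical F statistic `var(low) / var(high)` and a two-sided p-value.
#' The naming reflects the package's use: `low` is the low-resource group
#' whose variance is predicted to be larger.
#'
#' @param low,high Numeric vectors of outcome values (each of length >= 2
#'   with positive variance).
#' @return An object of class `dispersion_result`: `variance_low`,
#'   `variance_high`, `ratio` (low/high), `statistic` (the same F), the
#'   degrees-of-freedom pair `df`, and two-sided `p_value`.
#' @export
variance_ratio_test <- function(low, high) {
  low <- low[is.finite(low)]; high <- high[is.finite(high)]
  if (length(low) < 2L || length(high) < 2L)
    stop_invalid("each group needs at least 2 observations")
  v_low <- var(low); v_high <- var(high)
  if (v_low == 0 || v_high == 0)
    stop_invalid("degenerate group with zero variance")
  f <- v_low / v_high
  df <- c(length(low) - 1L, length(high) - 1L)
  pr <- pf(f, df[1], df[2])
  out <- list(variance_low = v_low, variance_high = v_high, ratio = f,
              statistic = f, df = df,
              p_value = min(1, 2 * min(pr, 1 - pr)),
              n = c(length(low), length(high)))
  class(out) <- "dispersion_result"
  out
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Variance ratio (low/high): %.3f, F(%d, %d) = %.3f, two-sided p = %.3g\n",
              x$ratio, x$df[1], x$df[2], x$statistic, x$p_value))
  invisible(x)
}

#' Squared-residual regression for variance heterogeneity
#'
#' Stage 1 regresses the outcome on resources plus controls by ordinary
#' least squares -- deliberately without random effects or a changepoint,
#' so between-individual variance is not absorbed. Stage 2 regresses the
#' squared stage-1 residuals on resources; a negative slope means larger
#' deviations from the fitted line at the bottom of the resource
#' distribution. Both variables are standardised in stage 2, so the slope
#' is a standardized coefficient.
#'
#' @inheritParams fit_segmented_at
#' @return A list of class `sqres_fit`: standardized `slope`, `se`,
#'   two-sided `p_value`, and `n`.
#' @export
squared_residual_regression <- function(panel, resource_var,
                                        response = "risk_count",
                                        covariates = c("z_age", "gender")) {
  check_columns(panel, c(resource_var, response, covariates))
  d <- data.frame(.y = panel[[response]], .r = panel[[resource_var]])
  for (v in covariates) d[[v]] <- panel[[v]]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < length(covariates) + 3L)
    stop_invalid("too few complete observations")
  stage1 <- lm(as.formula(paste(".y ~ .r +",
                                paste(covariates, collapse = " + "))),
               data = d)
  res2 <- residuals(stage1)^2
  if (max(res2) < 1e-12) {   # constant response: residuals are all zero
    out <- list(slope = 0, se = NA_real_, p_value = NA_real_, n = nrow(d))
  } else {
    z <- function(x) if (sd(x) == 0) x * 0 else (x - mean(x)) / sd(x)
    stage2 <- lm(z(res2) ~ z(d$.r))
    sm <- summary(stage2)$coefficients
    out <- list(slope = sm[2, 1], se = sm[2, 2], p_value = sm[2, 4],
                n = nrow(d))
  }
  class(out) <- "sqres_fit"
  out
}

#' @export
print.sqres_fit <- function(x, ...) {
  cat(sprintf("Squared-residual regression: standardized slope %.4f (se %.4f), p = %.3g, n = %d\n",
              x$slope, x$se, x$p_value, x$n))
  invisible(x)
}

#' Variance-ratio sweep over resource thresholds
#'
#' For each percentile threshold between `pmin` and `pmax` (default the 1st
#' percentile to the median), compares the variance of the outcome below
#' versus above the threshold. Per-threshold p-values are two-sided and
#' uncorrected; a Holm-adjusted column over the swept thresholds is
#' reported alongside.
#'
#' @inheritParams fit_segmented_at
#' @param pmin,pmax,step Percentile grid of thresholds (defaults 1, 50, 1).
#' @return A data frame of class `sweep_curve` with columns `percentile`,
#'   `threshold`, `n_below`, `n_above`, `var_below`, `var_above`, `ratio`,
#'   `statistic`, `p_value`, `p_holm`. Thresholds leaving an empty or
#'   degenerate side are dropped (recorded in attribute `"skipped"`).
#' @export
variance_sweep <- function(panel, resource_var, response = "risk_count",
                           pmin = 1, pmax = 50, step = 1) {
  check_columns(panel, c(resource_var, response))
  check_number(pmin, "pmin", lo = 0, hi = 100)
  check_number(pmax, "pmax", lo = pmin, hi = 100)
  d <- panel[is.finite(panel[[resource_var]]) & !is.na(panel[[response]]), ]
  r <- d[[resource_var]]; y <- d[[response]]
  pcts <- seq(pmin, pmax, by = step)
  rows <- list(); skipped <- numeric(0)
  for (p in pcts) {
    thr <- quantile(r, p / 100, names = FALSE)
    below <- y[r <= thr]; above <- y[r > thr]
    res <- tryCatch(variance_ratio_test(below, above), error = function(e) NULL)
    if (is.null(res)) { skipped <- c(skipped, p); next }
    rows[[length(rows) + 1L]] <- data.frame(
      percentile = p, threshold = thr,
      n_below = res$n[1], n_above = res$n[2],
      var_below = res$variance_low, var_above = res$variance_high,
      ratio = res$ratio, statistic = res$statistic, p_value = res$p_value)
  }
  if (length(rows) == 0L)
    stop_invalid("no feasible threshold in the requested percentile range")
  out <- do.call(rbind, rows)
  out$p_holm <- holm_bonferroni(out$p_value)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("sweep_curve", "data.frame")
  out
}

#' @export
plot.sweep_curve <- function(x, ...) {
  plot(x$percentile, x$ratio, type = "b", xlab = "threshold percentile",
       ylab = "variance ratio (below / above)", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Within-person stability of risk taking versus resources
#'
#' Computes each participant's over-time variance in the outcome (over
#' participants with at least two completed waves) and regresses it on the
#' participant's mean resource level, both standardised. A negative slope
#' means participants with fewer resources are less stable in their risk
#' taking over time.
#'
#' @inheritParams fit_segmented_at
#' @return A list of class `stability_fit`: standardized `slope`, `se`,
#'   `p_value`, `n_participants`, and the per-participant table.
#' @export
within_person_stability <- function(panel, resource_var,
                                    response = "risk_count",
                                    id = "participant_id") {
  check_columns(panel, c(resource_var, response, id))
  d <- panel[!is.na(panel[[response]]) & is.finite(panel[[resource_var]]), ]
  split_y <- split(d[[response]], d[[id]])
  split_r <- split(d[[resource_var]], d[[id]])
  keep <- lengths(split_y) >= 2L
  if (!any(keep))
    stop_invalid("no participant has two or more completed waves")
  per <- data.frame(
    participant_id = names(split_y)[keep],
    var_response = vapply(split_y[keep], var, numeric(1)),
    mean_resources = vapply(split_r[keep], mean, numeric(1))
  )
  if (nrow(per) < 10L)
    warning("within-person stability estimated from fewer than 10 participants")
  z <- function(x) if (sd(x) == 0) x * 0 else (x - mean(x)) / sd(x)
  if (sd(per$var_response) == 0) {
    out <- list(slope = 0, se = NA_real_, p_value = NA_real_,
                n_participants = nrow(per), participants = per)
  } else {
    fit <- lm(z(per$var_response) ~ z(per$mean_resources))
    sm <- summary(fit)$coefficients
    out <- list(slope = sm[2, 1], se = sm[2, 2], p_value = sm[2, 4],
                n_participants = nrow(per), participants = per)
  }
  class(out) <- "stability_fit"
  out
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf("Within-person stability: standardized slope %.4f (se %.4f), p = %.3g, n = %d participants\n",
              x$slope, x$se, x$p_value, x$n_participants))
  invisible(x)
}

#' Intra-class correlation from a random-intercept decomposition
#'
#' Fits an intercept-only random-intercept model (REML) of the variable on
#' participant and returns the share of total variance attributable to
#' stable between-participant differences.
#'
#' @param panel A data frame with repeated measures.
#' @param variable Name of the column to decompose.
#' @param id Participant id column.
#' @return The ICC, a number in `[0, 1]`.
#' @export
icc <- function(panel, variable = "risk_count", id = "participant_id") {
  check_columns(panel, c(variable, id))
  d <- data.frame(.y = panel[[variable]], .id = factor(panel[[id]]))
  d <- d[complete.cases(d), ]
  if (max(table(d$.id)) < 2L)
    stop_invalid("ICC undefined: no participant has repeated measures")
  within_var <- tapply(d$.y, d$.id, var)
  within_var <- within_var[!is.na(within_var)]
  if (all(within_var == 0)) return(1)
  fit <- lme4::lmer(.y ~ 1 + (1 | .id), data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  between <- vc$vcov[vc$grp == ".id"]
  within <- vc$vcov[vc$grp == "Residual"]
  between / (between + within)
}

#' Cronbach's alpha of a multi-item scale
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of the item
#' sum)` over complete rows.
#'
#' @param items A data frame or matrix with one column per item (>= 2
#'   columns, >= 2 complete rows).
#' @return The alpha coefficient (can be negative for unrelated items).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (ncol(m) < 2L) stop_invalid("need at least 2 items")
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L) stop_invalid("need at least 2 complete rows")
  total_var <- var(rowSums(m))
  if (total_var == 0)
    stop_invalid("alpha undefined: the item sum has zero variance")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' The three preregistered variance-heterogeneity tests, Holm-corrected
#'
#' Runs the family of dispersion tests as one analysis: (i) the variance
#' ratio of the outcome between observations answering "very difficult" to
#' the financial-strain question and all others, (ii) the squared-residual
#' regression on objective resources and (iii) on subjective resources.
#' The three p-values are Holm-Bonferroni corrected jointly.
#'
#' @param panel A processed panel (needs `financial_strain`,
#'   `objective_resources`, `subjective_resources` and the outcome).
#' @inheritParams fit_segmented_at
#' @return A data frame with one row per test: `test`, `estimate` (variance
#'   ratio or standardized slope), `p_value`, `p_holm`.
#' @export
p2_family_tests <- function(panel, response = "risk_count",
                            covariates = c("z_age", "gender")) {
  check_columns(panel, c("financial_strain", "objective_resources",
                         "subjective_resources", response))
  strained <- panel$financial_strain == "very difficult"
  vr <- variance_ratio_test(panel[[response]][strained & !is.na(strained)],
                            panel[[response]][!strained & !is.na(strained)])
  sq_obj <- squared_residual_regression(panel, "objective_resources",
                                        response, covariates)
  sq_subj <- squared_residual_regression(panel, "subjective_resources",
                                         response, covariates)
  out <- data.frame(
    test = c("strain_variance_ratio", "squared_residuals_objective",
             "squared_residuals_subjective"),
    estimate = c(vr$ratio, sq_obj$slope, sq_subj$slope),
    p_value = c(vr$p_value, sq_obj$p_value, sq_subj$p_value)
  )
  out$p_holm <- holm_bonferroni(out$p_value)
  out
}
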