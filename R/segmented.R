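# Segmented (broken-stick) mixed-effects models with maximum-likelihood
# changepoint search. All models are Gaussian random-intercept models
# fitted by ML (not REML) so deviances are comparable across fits.

segmented_frame <- function(panel, resource_var, cp, response, id,
                            covariates) {
  check_columns(panel, c(resource_var, response, id, covariates))
  r <- panel[[resource_var]]
  d <- data.frame(
    .y = panel[[response]],
    .x1 = pmin(r - cp, 0),
    .x2 = pmax(r - cp, 0),
    .id = factor(panel[[id]])
  )
  for (v in covariates) d[[v]] <- panel[[v]]
  d <- d[complete.cases(d), , drop = FALSE]
  d
}

lmer_ml <- function(formula, data, warm_theta = NULL) {
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  if (is.null(warm_theta))
    lme4::lmer(formula, data = data, REML = FALSE, control = ctrl)
  else
    lme4::lmer(formula, data = data, REML = FALSE, control = ctrl,
               start = warm_theta)
}

coef_table <- function(fit) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             statistic = unname(z), p_value = unname(p),
             stringsAsFactors = FALSE)
}

#' Segmented mixed model at a fixed changepoint
#'
#' Fits the broken-stick random-intercept model
#' `y = b0 + beta1 * (r - cp) * (r <= cp) + beta2 * (r - cp) * (r > cp)
#' + controls + participant intercept` by maximum likelihood, with the two
#' regression lines constrained to meet at the changepoint `cp`. Slope
#' tests are two-sided Wald tests conditional on the changepoint. Scaled
#' coefficients (continuous predictors and the response expressed in
#' standard-deviation units) are reported alongside the raw ones.
#'
#' @param panel A processed panel data frame.
#' @param resource_var Name of the resource column (e.g.
#'   `"objective_resources"` or `"subjective_resources"`).
#' @param cp The changepoint, in resource units.
#' @param response,id Column names of the outcome and participant id.
#' @param covariates Fixed-effect control columns (default standardized age
#'   and gender).
#' @param min_side Minimum observations required on each side of `cp`.
#' @return An object of class `segmented_fit`: changepoint, `beta0`
#'   (level at the changepoint), `beta1`/`beta2` (slopes below/above) with
#'   standard errors and p-values, scaled coefficients, deviance, variance
#'   components and the share of observations below the changepoint.
#' @export
fit_segmented_at <- function(panel, resource_var, cp,
                             response = "risk_count",
                             id = "participant_id",
                             covariates = c("z_age", "gender"),
                             min_side = 20) {
  d <- segmented_frame(panel, resource_var, cp, response, id, covariates)
  n_below <- sum(d$.x1 < 0)
  n_above <- sum(d$.x2 > 0)
  if (min(n_below, n_above) < min_side)
    stop_invalid("changepoint %g leaves %d/%d observations below/above; need >= %d per side",
                 cp, n_below, n_above, min_side)
  if (var(d$.y) == 0) stop_invalid("response has zero variance")
  form <- as.formula(paste(".y ~ .x1 + .x2 +",
                           paste(covariates, collapse = " + "),
                           "+ (1 | .id)"))
  fit <- lmer_ml(form, d)
  tab <- coef_table(fit)
  sd_y <- sd(d$.y)
  sd_r <- sd(panel[[resource_var]], na.rm = TRUE)
  scaled <- tab$estimate / sd_y
  for (i in seq_len(nrow(tab))) {
    v <- tab$term[i]
    if (v %in% c(".x1", ".x2")) scaled[i] <- tab$estimate[i] * sd_r / sd_y
    else if (v %in% covariates && is.numeric(d[[v]]))
      scaled[i] <- tab$estimate[i] * sd(d[[v]]) / sd_y
  }
  tab$scaled <- scaled
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(
    changepoint = cp,
    beta0 = tab$estimate[tab$term == "(Intercept)"],
    beta1 = tab$estimate[tab$term == ".x1"],
    beta2 = tab$estimate[tab$term == ".x2"],
    coefficients = tab,
    deviance = -2 * as.numeric(logLik(fit)),
    logLik = as.numeric(logLik(fit)),
    var_participant = vc$vcov[vc$grp == ".id"],
    var_residual = vc$vcov[vc$grp == "Residual"],
    share_below = mean(panel[[resource_var]] <= cp, na.rm = TRUE),
    n_obs = nrow(d),
    resource_var = resource_var,
    model = fit
  )
  class(out) <- "segmented_fit"
  out
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("Segmented mixed model on %s (n = %d)\n", x$resource_var,
              x$n_obs))
  cat(sprintf("  changepoint: %.4g (%.1f%% of observations below)\n",
              x$changepoint, 100 * x$share_below))
  tb <- x$coefficients
  b1 <- tb[tb$term == ".x1", ]; b2 <- tb[tb$term == ".x2", ]
  cat(sprintf("  slope below: %.4g (se %.3g, p = %.3g)\n",
              b1$estimate, b1$se, b1$p_value))
  cat(sprintf("  slope above: %.4g (se %.3g, p = %.3g)\n",
              b2$estimate, b2$se, b2$p_value))
  cat(sprintf("  deviance: %.2f\n", x$deviance))
  invisible(x)
}

candidate_changepoints <- function(r, grid, step, min_side) {
  r <- r[is.finite(r)]
  n <- length(r)
  rs <- sort(r)
  lo <- rs[min_side + 1L]           # > min_side obs strictly below is not
  hi <- rs[n - min_side]            # required; <= cp counts as 'below'
  cps <- if (is.numeric(grid)) {
    grid
  } else if (identical(grid, "observed")) {
    unique(rs)
  } else if (identical(grid, "percentile")) {
    unique(quantile(r, seq(step, 100 - step, by = step) / 100,
                    names = FALSE))
  } else {
    stop_invalid("`grid` must be \"percentile\", \"observed\" or a numeric vector")
  }
  admissible <- vapply(cps, function(cp)
    sum(r <= cp) >= min_side && sum(r > cp) >= min_side, logical(1))
  cps <- cps[admissible]
  if (length(cps) == 0L)
    stop_invalid("no admissible changepoint candidates (min_side = %d)",
                 min_side)
  sort(cps)
}

#' Maximum-likelihood changepoint search for the segmented mixed model
#'
#' Fits the segmented model of [fit_segmented_at()] at every candidate
#' changepoint and returns the fit with the smallest deviance, together
#' with the full deviance profile. Candidates are, by default, an evenly
#' spaced percentile grid of the resource distribution; `grid = "observed"`
#' uses every unique observed value, and a numeric vector supplies explicit
#' candidates. Each candidate must leave at least `min_side` observations
#' on each side. Ties in deviance are broken towards the smallest
#' changepoint.
#'
#' @inheritParams fit_segmented_at
#' @param grid `"percentile"` (default), `"observed"`, or a numeric vector
#'   of candidate changepoints.
#' @param step Percentile step of the default grid (default 0.5, i.e. 199
#'   candidates).
#' @return A `segmented_fit` (the minimum-deviance fit) with an additional
#'   `profile` component: a data frame of candidate changepoints, their
#'   percentile in the resource distribution, and deviances.
#' @export
fit_segmented_mixed <- function(panel, resource_var,
                                response = "risk_count",
                                id = "participant_id",
                                covariates = c("z_age", "gender"),
                                grid = "percentile", step = 0.5,
                                min_side = 20) {
  r <- panel[[resource_var]]
  cps <- candidate_changepoints(r, grid, step, min_side)
  form <- as.formula(paste(".y ~ .x1 + .x2 +",
                           paste(covariates, collapse = " + "),
                           "+ (1 | .id)"))
  dev <- rep(NA_real_, length(cps))
  theta <- NULL
  best <- NULL
  best_dev <- Inf
  n_failed <- 0L
  for (i in seq_along(cps)) {
    d <- segmented_frame(panel, resource_var, cps[i], response, id,
                         covariates)
    fit <- tryCatch(lmer_ml(form, d, warm_theta = theta),
                    error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    theta <- lme4::getME(fit, "theta")
    dev[i] <- -2 * as.numeric(logLik(fit))
    if (dev[i] < best_dev - 1e-12) {    # strict improvement: ties keep the
      best_dev <- dev[i]                # earlier (smaller) changepoint
      best <- cps[i]
    }
  }
  if (is.null(best))
    stop_invalid("all %d candidate fits failed to converge", length(cps))
  if (n_failed > 0L)
    warning(sprintf("%d of %d candidate fits failed and were skipped",
                    n_failed, length(cps)))
  out <- fit_segmented_at(panel, resource_var, best, response = response,
                          id = id, covariates = covariates,
                          min_side = min_side)
  pct <- ecdf(r[is.finite(r)])
  out$profile <- data.frame(changepoint = cps,
                            percentile = 100 * pct(cps),
                            deviance = dev)
  out$cp_percentile <- 100 * pct(best)
  out
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down familywise-error correction: the sorted p-values are
#' multiplied by decreasing factors `m, m-1, ..., 1`, cumulative maxima are
#' enforced, results are capped at 1 and returned in the input order.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_bonferroni <- function(pvalues) {
  if (!is.numeric(pvalues) || length(pvalues) == 0L ||
      any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_invalid("`pvalues` must all lie in [0, 1]")
  p.adjust(pvalues, method = "holm")
}
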