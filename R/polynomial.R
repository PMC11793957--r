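# Polynomial random-intercept models and their comparison by AIC and
# likelihood-ratio tests against the linear model.

#' Polynomial mixed model of risk taking on resources
#'
#' Fits a Gaussian random-intercept model of the outcome on an orthogonal
#' polynomial basis of the resource variable plus fixed-effect controls,
#' by maximum likelihood (so AICs and deviances are comparable across
#' degrees). The fitted fixed-effect curve is analysed for stationary and
#' inflection points within the observed resource range, and the fit
#' records whether an inflection point falls in the lower half of the
#' resource distribution -- the signature of a V-shape flattening out.
#'
#' @inheritParams fit_segmented_at
#' @param degree Polynomial degree (>= 1).
#' @return An object of class `poly_fit` with the coefficient table (on the
#'   orthogonal basis), log-likelihood, AIC, variance components, a fitted
#'   curve (data frame over a resource grid), stationary and inflection
#'   points, and `inflection_in_lower_half`.
#' @export
fit_polynomial_mixed <- function(panel, resource_var, degree = 3,
                                 response = "risk_count",
                                 id = "participant_id",
                                 covariates = c("z_age", "gender")) {
  check_number(degree, "degree", lo = 1)
  check_columns(panel, c(resource_var, response, id, covariates))
  d <- data.frame(.y = panel[[response]], .r = panel[[resource_var]],
                  .id = factor(panel[[id]]))
  for (v in covariates) d[[v]] <- panel[[v]]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0L) stop_invalid("no complete observations")
  if (var(d$.y) == 0)
    stop_invalid("response has zero variance; degenerate fit")
  form <- as.formula(paste(".y ~ poly(.r, ", degree, ") +",
                           paste(covariates, collapse = " + "),
                           "+ (1 | .id)"))
  fit <- lmer_ml(form, d)
  tab <- coef_table(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))

  # fixed-effect curve at reference covariate values, and its shape
  grid <- seq(min(d$.r), max(d$.r), length.out = 401)
  nd <- d[rep(1L, length(grid)), , drop = FALSE]
  nd$.r <- grid
  nd$.id <- d$.id[1]
  for (v in covariates)
    nd[[v]] <- if (is.numeric(d[[v]])) 0 else sort(unique(d[[v]]))[1]
  curve_y <- predict(fit, newdata = nd, re.form = NA)
  # recover raw-basis coefficients exactly from the curve
  raw_fit <- lm(curve_y ~ poly(grid, degree, raw = TRUE))
  raw_coef <- coef(raw_fit)[-1]
  real_roots <- function(coefs) {
    # roots of sum coefs[k] * x^(k-1); coefs ascending, may be length 0
    if (length(coefs) == 0L || all(abs(coefs) < 1e-12)) return(numeric(0))
    z <- polyroot(coefs)
    re <- Re(z)[abs(Im(z)) < 1e-6]
    re[re >= min(grid) & re <= max(grid)]
  }
  deriv_coef <- function(coefs) {
    if (length(coefs) <= 1L) return(numeric(0))
    coefs[-1] * seq_len(length(coefs) - 1L)
  }
  c_full <- c(coef(raw_fit)[1], raw_coef)
  d1 <- deriv_coef(c_full)
  d2 <- deriv_coef(d1)
  stationary <- real_roots(d1)
  inflection <- real_roots(d2)
  med_r <- median(d$.r)
  out <- list(
    degree = degree,
    coefficients = tab,
    logLik = as.numeric(logLik(fit)),
    AIC = AIC(fit),
    deviance = -2 * as.numeric(logLik(fit)),
    var_participant = vc$vcov[vc$grp == ".id"],
    var_residual = vc$vcov[vc$grp == "Residual"],
    curve = data.frame(resources = grid, fitted = curve_y),
    stationary_points = stationary,
    inflection_points = inflection,
    inflection_in_lower_half = any(inflection < med_r),
    n_obs = nrow(d),
    resource_var = resource_var,
    model = fit
  )
  class(out) <- "poly_fit"
  out
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("Degree-%d polynomial mixed model on %s (n = %d)\n",
              x$degree, x$resource_var, x$n_obs))
  cat(sprintf("  AIC: %.1f | logLik: %.1f\n", x$AIC, x$logLik))
  if (length(x$inflection_points))
    cat(sprintf("  inflection point(s) at %s (lower half: %s)\n",
                paste(signif(x$inflection_points, 4), collapse = ", "),
                x$inflection_in_lower_half))
  invisible(x)
}

#' Compare polynomial degrees by AIC and likelihood-ratio tests
#'
#' Fits degrees 1..`max_degree`, tabulates AICs, tests each higher-degree
#' model against the linear one with a chi-squared likelihood-ratio test
#' (degrees of freedom equal to the degree difference), and selects the
#' degree with the smallest AIC.
#'
#' @inheritParams fit_polynomial_mixed
#' @param max_degree Highest degree to fit (>= 1).
#' @return An object of class `poly_comparison`: the AIC/LRT table, the
#'   selected degree, and the list of per-degree fits.
#' @export
compare_polynomials <- function(panel, resource_var, max_degree = 5,
                                response = "risk_count",
                                id = "participant_id",
                                covariates = c("z_age", "gender")) {
  check_number(max_degree, "max_degree", lo = 1)
  fits <- vector("list", max_degree)
  for (deg in seq_len(max_degree)) {
    fits[[deg]] <- tryCatch(
      fit_polynomial_mixed(panel, resource_var, degree = deg,
                           response = response, id = id,
                           covariates = covariates),
      error = function(e) e)
  }
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!ok[1]) stop_invalid("the linear fit failed: %s",
                           conditionMessage(fits[[1]]))
  tab <- data.frame(
    degree = seq_len(max_degree),
    AIC = vapply(seq_len(max_degree), function(d)
      if (ok[d]) fits[[d]]$AIC else NA_real_, numeric(1)),
    logLik = vapply(seq_len(max_degree), function(d)
      if (ok[d]) fits[[d]]$logLik else NA_real_, numeric(1))
  )
  tab$lrt_vs_linear <- 2 * (tab$logLik - tab$logLik[1])
  tab$df <- tab$degree - 1L
  tab$p_lrt <- ifelse(tab$df > 0,
                      pchisq(tab$lrt_vs_linear, tab$df, lower.tail = FALSE),
                      NA_real_)
  selected <- tab$degree[which.min(tab$AIC)]
  fits[!ok] <- list(NULL)
  out <- list(table = tab, selected_degree = selected, fits = fits,
              resource_var = resource_var)
  class(out) <- "poly_comparison"
  out
}

#' @export
print.poly_comparison <- function(x, ...) {
  cat(sprintf("Polynomial comparison on %s (selected degree: %d)\n",
              x$resource_var, x$selected_degree))
  print(x$table, row.names = FALSE, digits = 5)
  invisible(x)
}
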