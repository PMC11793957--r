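# Descriptive analyses: extreme-behaviour prevalence in the tails of the
# resource distribution, mean resources by bet count, strain-group
# summaries, and the time-discounting contrast.

#' Classify extreme risk-taking behaviour
#'
#' A respondent accepting no bets is a risk avoider; one accepting more
#' than four is a risk taker (they necessarily preferred a gamble to a sure
#' amount with a higher expected payoff); anything else is neither.
#'
#' @param count Bet counts in 0..7 (vectorised; `NA` propagates).
#' @return A factor with levels `avoider`, `neither`, `taker`.
#' @export
classify_extremes <- function(count) {
  if (!is.numeric(count) || any(!is.na(count) & (count < 0 | count > 7)))
    stop_invalid("`count` must lie in 0..7")
  lab <- ifelse(count == 0, "avoider", ifelse(count >= 5, "taker", "neither"))
  factor(lab, levels = c("avoider", "neither", "taker"))
}

# 2x2 Pearson chi-squared (no continuity correction) of being in `class`
# inside vs outside the tail subset.
tail_chisq <- function(in_class, in_tail) {
  tab <- table(factor(in_class, levels = c(FALSE, TRUE)),
               factor(in_tail, levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = NA_real_, p_value = NA_real_, degenerate = TRUE))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       degenerate = FALSE)
}

#' Prevalence of extreme risk taking in the resource tails
#'
#' Builds the observation-level prevalence table: for the full sample and
#' for the bottom and top `tail_pct` per cent of observations on each
#' resource variable, the share of risk takers and avoiders, the mean and
#' variance of the bet count, and chi-squared tests (2x2 Pearson, no
#' continuity correction) comparing each tail category with the rest of
#' the sample, separately for takers and avoiders. A two-sided variance
#' F test of the category against the rest of the sample is also reported.
#'
#' @param panel A processed panel.
#' @param tail_pct Tail size in per cent of observations (default 5).
#' @param resources Resource columns to cut tails on.
#' @inheritParams fit_segmented_at
#' @return A data frame of class `extreme_table` with one row per category.
#' @export
extreme_prevalence_table <- function(panel, tail_pct = 5,
                                     resources = c("objective_resources",
                                                   "subjective_resources"),
                                     response = "risk_count") {
  check_columns(panel, c(resources, response))
  check_number(tail_pct, "tail_pct", lo = .Machine$double.eps, hi = 50)
  y <- panel[[response]]
  classify <- classify_extremes
  rows <- list(category_stats("full sample", y, classify))
  for (rv in resources) {
    r <- panel[[rv]]
    qlo <- quantile(r, tail_pct / 100, na.rm = TRUE, names = FALSE)
    qhi <- quantile(r, 1 - tail_pct / 100, na.rm = TRUE, names = FALSE)
    for (side in c("bottom", "top")) {
      in_tail <- if (side == "bottom") r <= qlo else r >= qhi
      in_tail[is.na(in_tail)] <- FALSE
      if (!any(in_tail)) stop_invalid("empty %s tail on %s", side, rv)
      lab <- sprintf("%s %g%% %s", side, tail_pct,
                     sub("_resources", "", rv))
      row <- category_stats(lab, y[in_tail], classify)
      cls_all <- classify(y)
      for (what in c("taker", "avoider")) {
        ct <- tail_chisq(cls_all == what, in_tail)
        row[[paste0("chisq_", what, "s")]] <- ct$statistic
        row[[paste0("p_", what, "s")]] <- ct$p_value
      }
      vr <- tryCatch(
        variance_ratio_test(y[in_tail], y[!in_tail]),
        error = function(e) NULL)
      row$var_ratio_vs_rest <- if (is.null(vr)) NA_real_ else vr$ratio
      row$p_var <- if (is.null(vr)) NA_real_ else vr$p_value
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- merge_rows(rows)
  class(out) <- c("extreme_table", "data.frame")
  out
}

category_stats <- function(label, counts, classify) {
  cls <- classify(counts)
  data.frame(
    category = label,
    pct_takers = 100 * mean(cls == "taker", na.rm = TRUE),
    pct_avoiders = 100 * mean(cls == "avoider", na.rm = TRUE),
    mean_count = mean(counts, na.rm = TRUE),
    var_count = var(counts[!is.na(counts)]),
    n = sum(!is.na(counts)),
    stringsAsFactors = FALSE
  )
}

merge_rows <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  out <- do.call(rbind, lapply(rows, function(r) {
    for (c in setdiff(cols, names(r))) r[[c]] <- NA_real_
    r[cols]
  }))
  rownames(out) <- NULL
  out
}

#' Mean resources by number of risky bets
#'
#' Summarises the average level of each resource variable among
#' observations choosing each possible number of risky bets, pooling
#' counts six and seven into one bin so the top group is large enough.
#' Standard errors are of the mean.
#'
#' @inheritParams extreme_prevalence_table
#' @return A data frame with `count_bin`, `resource`, `mean`, `se`, `n`.
#' @export
mean_resources_by_count <- function(panel,
                                    resources = c("objective_resources",
                                                  "subjective_resources"),
                                    response = "risk_count") {
  check_columns(panel, c(resources, response))
  y <- panel[[response]]
  bin <- ifelse(y >= 6, "6-7", as.character(y))
  bins <- c(as.character(0:5), "6-7")
  rows <- list()
  for (rv in resources) {
    for (b in bins) {
      vals <- panel[[rv]][bin == b & !is.na(bin)]
      vals <- vals[is.finite(vals)]
      rows[[length(rows) + 1L]] <- data.frame(
        count_bin = b, resource = rv,
        mean = if (length(vals)) mean(vals) else NA_real_,
        se = if (length(vals) > 1L) sd(vals) / sqrt(length(vals)) else NA_real_,
        n = length(vals), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Risk taking by financial-strain answer
#'
#' @inheritParams extreme_prevalence_table
#' @return A data frame with one row per strain category: `mean_count`,
#'   `var_count`, `n`, ordered from "very difficult" to
#'   "living comfortably".
#' @export
strain_group_summary <- function(panel, response = "risk_count") {
  check_columns(panel, c("financial_strain", response))
  y <- panel[[response]]
  strain <- factor(panel$financial_strain, levels = strain_levels())
  out <- do.call(rbind, lapply(levels(strain), function(lv) {
    v <- y[strain == lv & !is.na(strain) & !is.na(y)]
    data.frame(financial_strain = lv,
               mean_count = if (length(v)) mean(v) else NA_real_,
               var_count = if (length(v) > 1) var(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  out[out$n > 0, , drop = FALSE]
}

#' Time-discounting contrast in the resource tails
#'
#' Replicates the extreme-prevalence table with the time-discounting
#' battery: high discounters chose only immediate rewards (7 of 7), low
#' discounters never did (0 of 7). Under the desperation-threshold account
#' high -- but not low -- discounting should be elevated at the bottom of
#' the resource distribution, whereas a pure comprehension-error account
#' would elevate both.
#'
#' @inheritParams extreme_prevalence_table
#' @return A data frame of class `extreme_table` with `pct_high`,
#'   `pct_low`, chi-squared contrasts and variance ratios per category.
#' @export
discounting_contrast <- function(panel, tail_pct = 5,
                                 resources = c("objective_resources",
                                               "subjective_resources")) {
  check_columns(panel, c(resources, "discount_count"))
  check_number(tail_pct, "tail_pct", lo = .Machine$double.eps, hi = 50)
  y <- panel$discount_count
  stats_row <- function(label, v) {
    data.frame(category = label,
               pct_high = 100 * mean(v == 7, na.rm = TRUE),
               pct_low = 100 * mean(v == 0, na.rm = TRUE),
               mean_count = mean(v, na.rm = TRUE),
               var_count = var(v[!is.na(v)]),
               n = sum(!is.na(v)), stringsAsFactors = FALSE)
  }
  rows <- list(stats_row("full sample", y))
  for (rv in resources) {
    r <- panel[[rv]]
    qlo <- quantile(r, tail_pct / 100, na.rm = TRUE, names = FALSE)
    qhi <- quantile(r, 1 - tail_pct / 100, na.rm = TRUE, names = FALSE)
    for (side in c("bottom", "top")) {
      in_tail <- if (side == "bottom") r <= qlo else r >= qhi
      in_tail[is.na(in_tail)] <- FALSE
      if (!any(in_tail)) stop_invalid("empty %s tail on %s", side, rv)
      lab <- sprintf("%s %g%% %s", side, tail_pct, sub("_resources", "", rv))
      row <- stats_row(lab, y[in_tail])
      for (what in c("high", "low")) {
        cls <- if (what == "high") y == 7 else y == 0
        ct <- tail_chisq(cls, in_tail)
        row[[paste0("chisq_", what)]] <- ct$statistic
        row[[paste0("p_", what)]] <- ct$p_value
      }
      vr <- tryCatch(variance_ratio_test(y[in_tail], y[!in_tail]),
                     error = function(e) NULL)
      row$var_ratio_vs_rest <- if (is.null(vr)) NA_real_ else vr$ratio
      row$p_var <- if (is.null(vr)) NA_real_ else vr$p_value
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- merge_rows(rows)
  class(out) <- c("extreme_table", "data.frame")
  out
}

#' Correlation of answer consistency with resources
#'
#' Point-biserial correlation (with a two-sided test) between the
#' consistency flag of the gamble battery and each resource variable; a
#' null correlation speaks against comprehension differences across the
#' resource distribution.
#'
#' @inheritParams extreme_prevalence_table
#' @return A data frame with `resource`, `r`, `p_value`, `n`; `r` is `NA`
#'   (with a warning) when the flag has no variance.
#' @export
consistency_by_resources <- function(panel,
                                     resources = c("objective_resources",
                                                   "subjective_resources")) {
  check_columns(panel, c(resources, "consistent"))
  flag <- as.numeric(panel$consistent)
  rows <- lapply(resources, function(rv) {
    r <- panel[[rv]]
    keep <- !is.na(flag) & is.finite(r)
    if (sum(keep) < 3L || sd(flag[keep]) == 0) {
      warning(sprintf("consistency flag degenerate for %s", rv))
      return(data.frame(resource = rv, r = NA_real_, p_value = NA_real_,
                        n = sum(keep)))
    }
    ct <- cor.test(flag[keep], r[keep])
    data.frame(resource = rv, r = unname(ct$estimate),
               p_value = ct$p.value, n = sum(keep))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
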