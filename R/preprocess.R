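#' Objective resources: log2 income-to-costs ratio
#'
#' Income and unavoidable costs are logged base 2 (adding one euro because
#' of zeroes) and differenced, so the measure is the log of the ratio of
#' income to unavoidable costs: 0 means income just covers costs, 1 means
#' income is twice costs, negative values mean costs exceeded income.
#'
#' @param income,costs Monthly amounts in euros, non-negative (vectorised;
#'   `NA` propagates).
#' @return Resources in log2-ratio units.
#' @export
objective_resources <- function(income, costs) {
  ok <- function(x) is.numeric(x) && all(is.na(x) | (is.finite(x) & x >= 0))
  if (!ok(income) || !ok(costs))
    stop_invalid("`income` and `costs` must be non-negative euros")
  log2(income + 1) - log2(costs + 1)
}

#' Subjective resources from the three insecurity items
#'
#' The three 0--100 self-assessed risks (destitution, losing suitable
#' housing, losing suitable employment) are summed, reverse coded against
#' the maximum of 300, and square-root transformed to tame the right skew
#' of respondents reporting near-zero risk.
#'
#' @param item1,item2,item3 Item scores in `[0, 100]` (vectorised; `NA`
#'   propagates).
#' @return Subjective resources in square-root units, in `[0, sqrt(300)]`.
#' @export
subjective_resources <- function(item1, item2, item3) {
  ok <- function(x) is.numeric(x) && all(is.na(x) | (x >= 0 & x <= 100))
  if (!ok(item1) || !ok(item2) || !ok(item3))
    stop_invalid("items must lie in [0, 100]")
  sqrt(300 - (item1 + item2 + item3))
}

check_battery <- function(choices, n_items = 7L) {
  if (is.data.frame(choices)) choices <- as.matrix(choices)
  if (is.vector(choices)) choices <- matrix(choices, nrow = 1L)
  if (ncol(choices) != n_items)
    stop_invalid("battery must have exactly %d choices", n_items)
  if (!all(choices %in% c(0, 1, NA)))
    stop_invalid("battery choices must be binary (0/1)")
  choices
}

#' Number of risky bets in a gamble battery
#'
#' @param choices A vector of 7 binary choices (1 = chose the gamble), or a
#'   matrix/data frame with one battery per row. Batteries containing `NA`
#'   yield `NA`.
#' @return Integer count(s) in 0..7.
#' @export
risk_count <- function(choices) {
  m <- check_battery(choices)
  as.integer(rowSums(m))
}

#' Consistency of a gamble battery
#'
#' A battery is inconsistent when the respondent refused the gamble against
#' some sure amount yet accepted it against a larger sure amount -- i.e.
#' turned down a bet more profitable than one they took. Equivalently, a
#' consistent battery is a run of gamble choices followed by a run of safe
#' choices.
#'
#' @inheritParams risk_count
#' @return Logical flag(s): `TRUE` when consistent.
#' @export
consistency_flag <- function(choices) {
  m <- check_battery(choices)
  apply(m, 1L, function(row) {
    if (anyNA(row)) return(NA)
    all(diff(row) <= 0)
  })
}

#' Number of immediate choices in a delay battery
#'
#' @param choices A vector of 7 binary choices (1 = chose the immediate
#'   100 euros), or a matrix/data frame of batteries. High counts mean
#'   steep time discounting.
#' @return Integer count(s) in 0..7.
#' @export
discount_count <- function(choices) {
  m <- check_battery(choices)
  as.integer(rowSums(m))
}

raw_panel_columns <- function() {
  c("participant_id", "wave", "country", "age", "gender", "income", "costs",
    paste0("subj_item_", 1:3),
    paste0("gamble_choice_", 1:7),
    paste0("delay_choice_", 1:7),
    "financial_strain")
}

#' Derive the analysis variables from a raw panel
#'
#' Applies the resource transformations and battery counts row-wise and
#' standardises age within the analysis sample. Rows are never dropped:
#' a battery or resource measure with missing ingredients is `NA` for that
#' variable only, and the shares of missing batteries, of negative
#' objective resources and of inconsistent batteries are recorded as
#' attributes (`"report"`).
#'
#' @param panel A raw panel data frame with the schema produced by
#'   [generate_panel()] (see `raw_panel_columns()` internally).
#' @return A data frame with one row per completed participant-wave and
#'   columns `participant_id`, `wave`, `country`, `age`, `z_age`, `gender`,
#'   `income`, `costs`, `objective_resources`, `subjective_resources`,
#'   `risk_count`, `consistent`, `discount_count`, `financial_strain`.
#' @export
preprocess_panel <- function(panel) {
  check_columns(panel, raw_panel_columns(), where = "raw panel")
  if (nrow(panel) == 0L) {
    out <- panel[, c("participant_id", "wave", "country", "age", "gender",
                     "income", "costs", "financial_strain")]
    out$z_age <- numeric(0)
    out$objective_resources <- numeric(0)
    out$subjective_resources <- numeric(0)
    out$risk_count <- integer(0)
    out$consistent <- logical(0)
    out$discount_count <- integer(0)
    return(out)
  }
  gm <- as.matrix(panel[paste0("gamble_choice_", 1:7)])
  dm <- as.matrix(panel[paste0("delay_choice_", 1:7)])
  out <- data.frame(
    participant_id = panel$participant_id,
    wave = panel$wave,
    country = panel$country,
    age = panel$age,
    z_age = as.numeric(scale(panel$age)),
    gender = panel$gender,
    income = panel$income,
    costs = panel$costs,
    objective_resources = objective_resources(panel$income, panel$costs),
    subjective_resources = subjective_resources(panel$subj_item_1,
                                                panel$subj_item_2,
                                                panel$subj_item_3),
    risk_count = risk_count(gm),
    consistent = consistency_flag(gm),
    discount_count = discount_count(dm),
    financial_strain = panel$financial_strain,
    stringsAsFactors = FALSE
  )
  attr(out, "report") <- list(
    n_rows = nrow(out),
    n_missing_risk_battery = sum(is.na(out$risk_count)),
    n_missing_delay_battery = sum(is.na(out$discount_count)),
    share_negative_objective = mean(out$objective_resources < 0, na.rm = TRUE),
    share_inconsistent = mean(!out$consistent, na.rm = TRUE)
  )
  out
}
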