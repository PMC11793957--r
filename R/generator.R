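#' Configuration of the synthetic survey-panel generator
#'
#' Defaults emulate a twelve-wave monthly panel of 472 adults from France
#' and the UK: a lognormal household income (median 3000 euros, mean about
#' 3437), unavoidable costs as a Beta-distributed fraction of income,
#' individual desperation thresholds, persistent behavioural heterogeneity
#' tuned so that bet counts have an intra-class correlation near 0.48, and
#' three subjective insecurity items sharing a latent standing tuned so
#' that their Cronbach's alpha is near 0.87.
#'
#' @param n_participants,n_waves Panel dimensions (defaults 472 and 12).
#' @param p_france Share of French participants (the rest are British).
#' @param response_shape1,response_shape2 Beta parameters of each
#'   participant's per-wave response probability; the default mean of
#'   0.8375 targets about 10.05 completed waves out of 12, and the spread
#'   reproduces the over-dispersion of completion counts seen in real
#'   volunteer panels.
#' @param income_log_mean,income_log_sd Log-scale location and total spread
#'   of monthly income; defaults give median 3000 and mean about 3437 euros.
#' @param income_within_sd Wave-to-wave log-income spread (part of
#'   `income_log_sd`).
#' @param cost_frac_shape1,cost_frac_shape2 Beta parameters of each
#'   participant's typical unavoidable-cost fraction of income.
#' @param cost_within_sd Log-scale wave noise on the cost fraction; its
#'   upper tail produces the rare months in which costs exceed income.
#' @param threshold_mean,threshold_sd Individual desperation thresholds in
#'   euros of monthly disposable income (income minus unavoidable costs).
#' @param below_gain,above_gain Multipliers on the model-implied deviation
#'   of the bet count from the risk-neutral count, applied below and above
#'   the threshold. Setting `below_gain = 0` switches off the desperate
#'   risk-taking arm while leaving the vulnerable arm intact.
#' @param count_sd_between,count_sd_within Standard deviations of the
#'   persistent and wave-level additive shifts on the latent bet count;
#'   together with the resource-driven signal these set the ICC.
#' @param count_baseline_shift Constant added to the latent bet count;
#'   aligns the population mean number of accepted bets (about 2.3 of 7)
#'   with the surveyed level.
#' @param tremble Per-choice response-error probability; the default of
#'   0.012 yields roughly the observed share of inconsistent batteries.
#' @param age_shape,age_rate,age_min,age_max Gamma-shifted age distribution
#'   (adults over 25, few over 45).
#' @param p_women Share of women.
#' @param age_effect,gender_effect Additive effects on the latent bet count
#'   per standard deviation of age and for women (defaults -0.085
#'   and -0.19).
#' @param subj_scale Euros of disposable income per logistic unit of
#'   perceived insecurity.
#' @param subj_trait_sd,subj_within_sd Persistent and wave-level spread of
#'   perceived insecurity on the logistic scale.
#' @param item_sd Independent per-item noise on the 0--100 scale; sets the
#'   internal consistency (alpha) of the three items.
#' @param strain_probs Population shares of the five financial-strain
#'   answers, ordered from "very difficult" to "living comfortably".
#' @param discount_mean,discount_trait_sd,discount_within_sd Latent
#'   time-discounting trait (immediate-choice count scale).
#' @param discount_below_shift Additive steepening of time discounting in
#'   below-threshold months.
#' @param model,task The [utility_model()] and [gamble_task()] driving bet
#'   choices.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(n_participants = 472,
                         n_waves = 12,
                         p_france = 232 / 472,
                         response_shape1 = 3.35,
                         response_shape2 = 0.65,
                         income_log_mean = log(3000),
                         income_log_sd = 0.52,
                         income_within_sd = 0.15,
                         cost_frac_shape1 = 9,
                         cost_frac_shape2 = 11,
                         cost_within_sd = 0.22,
                         threshold_mean = 500,
                         threshold_sd = 300,
                         below_gain = 1,
                         above_gain = 1,
                         count_sd_between = 1,
                         count_sd_within = 0.85,
                         count_baseline_shift = -0.45,
                         tremble = 0.012,
                         age_shape = 1.8,
                         age_rate = 0.12,
                         age_min = 25,
                         age_max = 80,
                         p_women = 0.5,
                         age_effect = -0.085,
                         gender_effect = -0.19,
                         subj_scale = 800,
                         subj_trait_sd = 0.8,
                         subj_within_sd = 0.35,
                         item_sd = 15,
                         strain_probs = c(0.05, 0.15, 0.30, 0.30, 0.20),
                         discount_mean = 2.5,
                         discount_trait_sd = 1.6,
                         discount_within_sd = 0.6,
                         discount_below_shift = 2,
                         model = utility_model(),
                         task = gamble_task()) {
  cfg <- as.list(environment())
  check_number(n_participants, "n_participants", lo = 1)
  check_number(n_waves, "n_waves", lo = 1)
  check_number(tremble, "tremble", lo = 0)
  if (tremble >= 0.5) stop_invalid("`tremble` must be below 0.5")
  for (nm in c("income_within_sd", "cost_within_sd", "threshold_sd",
               "count_sd_between", "count_sd_within", "subj_trait_sd",
               "subj_within_sd", "item_sd", "discount_trait_sd",
               "discount_within_sd"))
    check_number(cfg[[nm]], nm, lo = 0)
  if (income_within_sd >= income_log_sd)
    stop_invalid("`income_within_sd` must be below `income_log_sd`")
  if (length(strain_probs) != 5L || any(strain_probs <= 0) ||
      abs(sum(strain_probs) - 1) > 1e-8)
    stop_invalid("`strain_probs` must be 5 positive shares summing to 1")
  structure(cfg, class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("Synthetic panel config: %d participants x %d waves\n",
              x$n_participants, x$n_waves))
  cat(sprintf("  income: lognormal(meanlog %.3f, sdlog %.2f); threshold N(%g, %g) euros\n",
              x$income_log_mean, x$income_log_sd, x$threshold_mean,
              x$threshold_sd))
  cat(sprintf("  count heterogeneity: between %.2f, within %.2f; tremble %.3f\n",
              x$count_sd_between, x$count_sd_within, x$tremble))
  invisible(x)
}

strain_levels <- function() {
  c("very difficult", "quite difficult", "just about getting by",
    "doing alright", "living comfortably")
}

# Cutoff battery of `count` risky choices followed by safe ones, with
# independent per-choice trembles.
battery_from_count <- function(count, n_items, tremble) {
  base <- outer(count, seq_len(n_items), ">=")
  if (tremble > 0) {
    flips <- matrix(runif(length(base)) < tremble, nrow = nrow(base))
    base <- xor(base, flips)
  }
  storage.mode(base) <- "integer"
  base
}

#' Generate a synthetic survey panel
#'
#' Simulates the full longitudinal survey: persistent participant traits
#' (income level, cost fraction, desperation threshold, behavioural and
#' perceptual dispositions) plus wave-level shocks determine monthly income
#' and costs; each wave's gamble battery is produced by the
#' desperation-threshold model evaluated at disposable income minus the
#' individual threshold, shifted by age, gender and the participant's
#' persistent disposition, and subjected to a trembling hand. Subjective
#' insecurity items, financial-strain answers and a delay battery (which
#' steepens in below-threshold months) complete the schema. Missing waves
#' are absent rows.
#'
#' @param cfg A [panel_config()].
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A data frame with one row per completed participant-wave and the
#'   raw survey schema (`participant_id`, `wave`, `country`, `age`,
#'   `gender`, `income`, `costs`, `subj_item_1..3`, `gamble_choice_1..7`,
#'   `delay_choice_1..7`, `financial_strain`). Per-participant simulation
#'   truth (threshold, dispositions) is attached as attribute `"truth"`.
#' @export
generate_panel <- function(cfg = panel_config(), seed = NULL) {
  stopifnot(inherits(cfg, "panel_config"))
  with_seed(seed, {
    n <- as.integer(cfg$n_participants)
    w <- as.integer(cfg$n_waves)
    n_items <- length(cfg$task$safe_amounts)

    # persistent participant traits
    country <- ifelse(runif(n) < cfg$p_france, "FR", "UK")
    gender <- ifelse(runif(n) < cfg$p_women, "woman", "man")
    age <- clamp(cfg$age_min + rgamma(n, cfg$age_shape, cfg$age_rate),
                 cfg$age_min, cfg$age_max)
    z_age <- as.numeric(scale(age))
    mu_income <- rnorm(n, cfg$income_log_mean,
                       sqrt(cfg$income_log_sd^2 - cfg$income_within_sd^2))
    frac <- rbeta(n, cfg$cost_frac_shape1, cfg$cost_frac_shape2)
    tau <- rnorm(n, cfg$threshold_mean, cfg$threshold_sd)
    eta <- rnorm(n, 0, cfg$count_sd_between)
    nu <- rnorm(n, 0, cfg$subj_trait_sd)
    disc <- rnorm(n, cfg$discount_mean, cfg$discount_trait_sd)
    p_resp <- rbeta(n, cfg$response_shape1, cfg$response_shape2)

    # wave grid and missingness
    id <- rep(seq_len(n), each = w)
    wave <- rep(seq_len(w), times = n)
    present <- runif(n * w) < p_resp[id]
    id <- id[present]; wave <- wave[present]
    m <- length(id)
    if (m == 0L) stop_invalid("configuration produced an empty panel")

    income <- round(exp(mu_income[id] + rnorm(m, 0, cfg$income_within_sd)))
    costs <- round(income * frac[id] * exp(rnorm(m, 0, cfg$cost_within_sd)))
    x <- income - costs - tau[id]    # euros relative to own threshold

    # gamble battery via the threshold model
    base <- predicted_bet_count(x, cfg$model, cfg$task, tremble = 0)
    neutral <- sum(cfg$task$safe_amounts < cfg$task$risk_neutral_value)
    gain <- ifelse(x <= 0, cfg$below_gain, cfg$above_gain)
    latent <- neutral + cfg$count_baseline_shift + gain * (base - neutral) +
      eta[id] + rnorm(m, 0, cfg$count_sd_within) +
      cfg$age_effect * z_age[id] +
      cfg$gender_effect * (gender[id] == "woman")
    count <- clamp(round(latent), 0, n_items)
    gm <- battery_from_count(count, n_items, cfg$tremble)

    # subjective insecurity items on a shared latent standing
    insec_latent <- -x / cfg$subj_scale + nu[id] +
      rnorm(m, 0, cfg$subj_within_sd)
    insec <- 100 * plogis(insec_latent)
    items <- vapply(1:3, function(k)
      clamp(round(insec + rnorm(m, 0, cfg$item_sd)), 0, 100), numeric(m))

    # financial strain: ranked insecurity cut at the configured shares
    # (the most insecure `strain_probs[1]` share answers "very difficult")
    strain_latent <- insec_latent + rnorm(m, 0, 0.5)
    qs <- quantile(strain_latent, cumsum(rev(cfg$strain_probs))[-5],
                   names = FALSE)
    strain_idx <- 5L - findInterval(strain_latent, qs)
    strain <- factor(strain_levels()[clamp(strain_idx, 1L, 5L)],
                     levels = strain_levels(), ordered = TRUE)

    # delay battery: independent trait, steeper below the threshold
    dlat <- disc[id] + cfg$discount_below_shift * (x <= 0) +
      rnorm(m, 0, cfg$discount_within_sd)
    dcount <- clamp(round(dlat), 0, n_items)
    dm <- battery_from_count(dcount, n_items, cfg$tremble)

    panel <- data.frame(
      participant_id = id,
      wave = wave,
      country = country[id],
      age = age[id],
      gender = gender[id],
      income = income,
      costs = costs,
      stringsAsFactors = FALSE
    )
    for (k in 1:3) panel[[paste0("subj_item_", k)]] <- items[, k]
    for (k in seq_len(n_items))
      panel[[paste0("gamble_choice_", k)]] <- gm[, k]
    for (k in seq_len(n_items))
      panel[[paste0("delay_choice_", k)]] <- dm[, k]
    panel$financial_strain <- strain
    panel <- panel[order(panel$participant_id, panel$wave), ]
    rownames(panel) <- NULL
    attr(panel, "truth") <- data.frame(
      participant_id = seq_len(n), threshold = tau, count_shift = eta,
      insecurity_shift = nu, discount_trait = disc,
      response_prob = p_resp
    )
    panel
  })
}

#' Diagnostics of a generated (or real) panel
#'
#' Computes the calibration statistics the generator is tuned against, from
#' the panel alone: the intra-class correlation of bet counts (share of
#' variance between participants, from a random-intercept decomposition),
#' Cronbach's alpha of the three subjective items, income moments, mean and
#' spread of bet counts, mean completed waves, and the share of
#' inconsistent batteries.
#'
#' @param panel A raw panel with the [generate_panel()] schema.
#' @return A list of class `generator_diagnostics`.
#' @export
validate_generator <- function(panel) {
  check_columns(panel, raw_panel_columns(), where = "panel")
  if (nrow(panel) == 0L) stop_invalid("panel is empty")
  proc <- preprocess_panel(panel)
  waves_per_id <- table(panel$participant_id)
  icc_val <- if (max(waves_per_id) < 2L) NA_real_ else
    icc(proc, "risk_count")
  out <- list(
    n_participants = length(waves_per_id),
    n_obs = nrow(panel),
    icc_risk_count = icc_val,
    cronbach_alpha = cronbach_alpha(panel[paste0("subj_item_", 1:3)]),
    income_mean = mean(panel$income),
    income_median = median(panel$income),
    income_sd = sd(panel$income),
    mean_bet_count = mean(proc$risk_count, na.rm = TRUE),
    sd_bet_count = sd(proc$risk_count, na.rm = TRUE),
    mean_waves_completed = mean(waves_per_id),
    share_inconsistent = mean(!proc$consistent, na.rm = TRUE),
    share_negative_objective = mean(proc$objective_resources < 0, na.rm = TRUE)
  )
  class(out) <- "generator_diagnostics"
  out
}

#' @export
print.generator_diagnostics <- function(x, ...) {
  cat(sprintf("Panel: %d participants, %d observations (mean %.2f waves)\n",
              x$n_participants, x$n_obs, x$mean_waves_completed))
  cat(sprintf("  ICC(risk count) = %.3f | Cronbach's alpha = %.3f\n",
              x$icc_risk_count, x$cronbach_alpha))
  cat(sprintf("  income mean %.0f / median %.0f / sd %.0f euros\n",
              x$income_mean, x$income_median, x$income_sd))
  cat(sprintf("  bet count mean %.2f (sd %.2f); %.1f%% inconsistent; %.1f%% negative resources\n",
              x$mean_bet_count, x$sd_bet_count, 100 * x$share_inconsistent,
              100 * x$share_negative_objective))
  invisible(x)
}

#' Simulate a processed panel directly from a segmented (or linear) truth
#'
#' A lightweight simulator for parameter-recovery and calibration studies:
#' resources are a persistent participant level plus wave shocks, and the
#' response follows the broken-stick model
#' `y = b0 + beta1 * (r - cp) * (r <= cp) + beta2 * (r - cp) * (r > cp)`
#' plus a participant random intercept and residual noise. With
#' `beta1 == beta2` the truth is linear. The changepoint is placed at a
#' percentile of the realised resource distribution.
#'
#' @param n_participants,n_waves Panel dimensions.
#' @param cp_percentile Location of the true changepoint as a fraction of
#'   the resource distribution (default 0.2).
#' @param beta1,beta2 Slopes below and above the changepoint (response
#'   units per resource unit).
#' @param intercept Response level at the changepoint.
#' @param sd_participant,sd_resid Random-intercept and residual standard
#'   deviations.
#' @param resource_between_sd,resource_within_sd Spread of persistent and
#'   wave-level resource components.
#' @param seed Optional integer seed.
#' @return A processed-style data frame with `participant_id`, `wave`,
#'   `resources`, `risk_count`, `z_age`, `gender`, and attribute `"truth"`
#'   (the changepoint and slopes used).
#' @export
simulate_segmented_panel <- function(n_participants = 472, n_waves = 10,
                                     cp_percentile = 0.2,
                                     beta1 = -1.5, beta2 = 0.15,
                                     intercept = 2.3,
                                     sd_participant = 1, sd_resid = 1,
                                     resource_between_sd = 0.8,
                                     resource_within_sd = 0.6,
                                     seed = NULL) {
  with_seed(seed, {
    n <- n_participants; w <- n_waves
    id <- rep(seq_len(n), each = w)
    r <- rep(rnorm(n, 0, resource_between_sd), each = w) +
      rnorm(n * w, 0, resource_within_sd)
    cp <- quantile(r, cp_percentile, names = FALSE)
    b <- rep(rnorm(n, 0, sd_participant), each = w)
    y <- intercept + beta1 * pmin(r - cp, 0) + beta2 * pmax(r - cp, 0) +
      b + rnorm(n * w, 0, sd_resid)
    out <- data.frame(
      participant_id = id,
      wave = rep(seq_len(w), times = n),
      resources = r,
      risk_count = y,
      z_age = rep(rnorm(n), each = w),
      gender = rep(ifelse(runif(n) < 0.5, "woman", "man"), each = w),
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- list(cp = cp, cp_percentile = cp_percentile,
                               beta1 = beta1, beta2 = beta2)
    out
  })
}
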