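#' Desperation-threshold utility model
#'
#' Constructs the utility function used throughout the package. Resources
#' `r` (in euros) are first expressed in sigmoid units,
#' `u = (r - threshold) / scale`, and utility is
#' `plogis(u) + slope * u * (u > 0)`: a sigmoid that is convex below the
#' threshold (little left to lose), steep around it (basic needs), and
#' asymptotically linear above it (ordinary diminishing-free returns).
#' Setting `sigmoid = FALSE` drops the sigmoid component entirely and gives
#' the purely linear utility `slope * u`, the risk-neutral benchmark.
#'
#' @param threshold Resource level (euros) at which basic needs are exactly
#'   met. Utility equals 0.5 there (for the sigmoid family).
#' @param scale Euros per sigmoid unit; controls how abrupt the threshold
#'   region is. The default of 100 maps the elicitation ladder
#'   (100--700 euros) onto 1--7 units.
#' @param slope Marginal utility per sigmoid unit above the threshold
#'   (default 1/50), i.e. the gentle linear growth once needs are secured.
#' @param sigmoid If `FALSE`, use a globally linear utility instead.
#' @return An object of class `utility_model`.
#' @seealso [utility()], [certainty_equivalent()], [ce_curve()]
#' @examples
#' m <- utility_model()
#' utility(c(-1000, 0, 800), m)
#' @export
utility_model <- function(threshold = 0, scale = 100, slope = 1 / 50,
                          sigmoid = TRUE) {
  check_number(threshold, "threshold")
  check_number(scale, "scale", lo = .Machine$double.eps)
  check_number(slope, "slope", lo = 0)
  structure(
    list(threshold = threshold, scale = scale, slope = slope,
         sigmoid = isTRUE(sigmoid)),
    class = "utility_model"
  )
}

#' Purely linear utility
#'
#' Convenience constructor for the risk-neutral benchmark: utility
#' proportional to resources, with no threshold region.
#'
#' @inheritParams utility_model
#' @return A `utility_model` with `sigmoid = FALSE`.
#' @export
linear_utility_model <- function(slope = 1 / 50, scale = 100) {
  utility_model(threshold = 0, scale = scale, slope = slope, sigmoid = FALSE)
}

#' @export
print.utility_model <- function(x, ...) {
  cat(if (x$sigmoid) "Desperation-threshold utility\n" else "Linear utility\n")
  cat(sprintf("  threshold: %g euros | scale: %g euros/unit | slope: %g per unit\n",
              x$threshold, x$scale, x$slope))
  invisible(x)
}

#' Evaluate utility at a resource level
#'
#' @param r Resources in euros (vectorised; must be finite).
#' @param model A [utility_model()].
#' @return Utility values (dimensionless).
#' @export
utility <- function(r, model = utility_model()) {
  if (!is.numeric(r) || length(r) == 0L || !all(is.finite(r)))
    stop_invalid("`r` must be finite numeric resources (euros)")
  u <- (r - model$threshold) / model$scale
  if (model$sigmoid) plogis(u) + model$slope * u * (u > 0) else model$slope * u
}

#' The elicitation gamble
#'
#' A multiple-price-list battery: a fixed gamble (default a 50% chance of
#' 800 euros, otherwise nothing) offered against an ascending ladder of sure
#' amounts (default 100, 200, ..., 700 euros).
#'
#' @param win_amount Gamble prize in euros.
#' @param win_probability Probability of winning, strictly in (0, 1).
#' @param safe_amounts Strictly increasing ladder of sure amounts (euros).
#' @return An object of class `gamble_task` with the derived
#'   `risk_neutral_value = win_probability * win_amount`.
#' @export
gamble_task <- function(win_amount = 800, win_probability = 0.5,
                        safe_amounts = seq(100, 700, by = 100)) {
  check_number(win_amount, "win_amount", lo = .Machine$double.eps)
  check_number(win_probability, "win_probability")
  if (win_probability <= 0 || win_probability >= 1)
    stop_invalid("`win_probability` must lie strictly between 0 and 1")
  if (!is.numeric(safe_amounts) || length(safe_amounts) == 0L ||
      any(!is.finite(safe_amounts)) || any(diff(safe_amounts) <= 0))
    stop_invalid("`safe_amounts` must be a strictly increasing numeric ladder")
  structure(
    list(win_amount = win_amount, win_probability = win_probability,
         safe_amounts = safe_amounts,
         risk_neutral_value = win_probability * win_amount),
    class = "gamble_task"
  )
}

#' @export
print.gamble_task <- function(x, ...) {
  cat(sprintf("Gamble: %.0f%% chance of %g euros (EV %g) vs sure %s\n",
              100 * x$win_probability, x$win_amount, x$risk_neutral_value,
              paste(x$safe_amounts, collapse = ", ")))
  invisible(x)
}

#' Expected utility of the gamble at a resource level
#'
#' @inheritParams utility
#' @param task A [gamble_task()].
#' @return `p * U(r + win) + (1 - p) * U(r)`, vectorised over `r`.
#' @export
gamble_expected_utility <- function(r, model = utility_model(),
                                    task = gamble_task()) {
  p <- task$win_probability
  p * utility(r + task$win_amount, model) + (1 - p) * utility(r, model)
}

#' Certainty equivalent of the gamble
#'
#' The sure amount `c` such that `U(r + c)` equals the expected utility of
#' the gamble at resources `r`. Because utility is strictly increasing the
#' root is unique in `[0, win_amount]`; it is located by bisection.
#' A certainty equivalent above the gamble's expected value means the agent
#' is taking risk at that resource level; below it, avoiding risk.
#'
#' @inheritParams gamble_expected_utility
#' @param tol Absolute bisection tolerance in euros (default 0.01).
#' @return Certainty equivalents in euros, vectorised over `r`.
#' @export
certainty_equivalent <- function(r, model = utility_model(),
                                 task = gamble_task(), tol = 0.01) {
  check_number(tol, "tol", lo = .Machine$double.eps)
  target <- gamble_expected_utility(r, model, task)
  vapply(seq_along(r), function(i) {
    lo <- 0
    hi <- task$win_amount
    f_lo <- utility(r[i] + lo, model) - target[i]
    f_hi <- utility(r[i] + hi, model) - target[i]
    if (f_lo > 1e-12 || f_hi < -1e-12)
      stop("certainty_equivalent: root not bracketed; utility not monotone?")
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (utility(r[i] + mid, model) - target[i] < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Certainty-equivalent curve over a resource grid
#'
#' Evaluates the certainty equivalent on a grid of resource levels and
#' labels each point's regime: `risk_taking` when the certainty equivalent
#' exceeds the gamble's expected value, `risk_avoidance` when it falls
#' short, `risk_neutral` when it matches within `neutral_tol`.
#'
#' @inheritParams certainty_equivalent
#' @param r_grid Sorted finite grid of resource levels (euros).
#' @param neutral_tol Half-width (euros) of the band around the risk-neutral
#'   value classified as neutral; defaults to ten times the solver tolerance.
#' @return A data frame (class `ce_curve`) with columns `resources`,
#'   `certainty_equivalent` and `regime`.
#' @export
ce_curve <- function(model = utility_model(), task = gamble_task(),
                     r_grid = seq(-800, 800, by = 10), tol = 0.01,
                     neutral_tol = 10 * tol) {
  if (!is.numeric(r_grid) || length(r_grid) == 0L || any(!is.finite(r_grid)))
    stop_invalid("`r_grid` must be a non-empty finite numeric grid")
  if (is.unsorted(r_grid, strictly = FALSE))
    stop_invalid("`r_grid` must be sorted increasing")
  ce <- certainty_equivalent(r_grid, model, task, tol = tol)
  rnv <- task$risk_neutral_value
  regime <- ifelse(abs(ce - rnv) <= neutral_tol, "risk_neutral",
                   ifelse(ce > rnv, "risk_taking", "risk_avoidance"))
  out <- data.frame(resources = r_grid, certainty_equivalent = ce,
                    regime = factor(regime, levels = c("risk_taking",
                                                       "risk_neutral",
                                                       "risk_avoidance")))
  class(out) <- c("ce_curve", "data.frame")
  out
}

#' @export
plot.ce_curve <- function(x, ...) {
  plot(x$resources, x$certainty_equivalent, type = "l",
       xlab = "resources (euros)", ylab = "certainty equivalent (euros)", ...)
  graphics::abline(h = attr(x, "risk_neutral_value"), lty = 2)
  invisible(x)
}

#' Resource level where the regime switches
#'
#' Locates the point, moving rightward along the resource axis, where the
#' certainty-equivalent curve crosses the gamble's expected value from above
#' -- the switch from risk taking (desperation) to risk avoidance
#' (vulnerability). The crossing is found on a grid and refined by linear
#' interpolation between the bracketing grid points.
#'
#' @inheritParams certainty_equivalent
#' @param lower,upper,step Grid specification in euros.
#' @return A list with `switch_point` (euros), `n_crossings` found on the
#'   grid, and the `ce_curve` used.
#' @export
regime_switch_point <- function(model = utility_model(), task = gamble_task(),
                                lower = -800, upper = 0, step = 10,
                                tol = 0.01) {
  grid <- seq(lower, upper, by = step)
  curve <- ce_curve(model, task, grid, tol = tol, neutral_tol = 0)
  excess <- curve$certainty_equivalent - task$risk_neutral_value
  sign_change <- which(excess[-length(excess)] > 0 & excess[-1] <= 0)
  if (length(sign_change) == 0L)
    stop_invalid("no downward crossing of the risk-neutral value in [%g, %g]",
                 lower, upper)
  i <- sign_change[1]
  # linear interpolation within the bracketing step
  x0 <- grid[i]; x1 <- grid[i + 1]
  y0 <- excess[i]; y1 <- excess[i + 1]
  sp <- x0 + (x1 - x0) * y0 / (y0 - y1)
  list(switch_point = sp, n_crossings = length(sign_change), curve = curve)
}

#' Predicted number of risky bets on the ladder
#'
#' For each sure amount in the ladder the agent prefers the gamble when its
#' expected utility strictly exceeds the utility of the sure amount; the
#' prediction is the number of gambles preferred. A trembling hand flips
#' each of the binary choices independently with probability `tremble`.
#'
#' @inheritParams gamble_expected_utility
#' @param tremble Per-choice error probability in `[0, 0.5)`.
#' @param seed Optional integer seed used (and then restored) when
#'   `tremble > 0`.
#' @return Integer bet counts in `0..length(safe_amounts)`, vectorised
#'   over `r`.
#' @export
predicted_bet_count <- function(r, model = utility_model(),
                                task = gamble_task(), tremble = 0,
                                seed = NULL) {
  check_number(tremble, "tremble", lo = 0)
  if (tremble >= 0.5) stop_invalid("`tremble` must be below 0.5")
  prefer <- bet_preference_matrix(r, model, task)
  if (tremble > 0) {
    prefer <- with_seed(seed, {
      flips <- matrix(runif(length(prefer)) < tremble, nrow = nrow(prefer))
      xor(prefer, flips)
    })
  }
  as.integer(rowSums(prefer))
}

# n x n_ladder logical matrix: TRUE where the gamble is strictly preferred
# to the sure amount.
bet_preference_matrix <- function(r, model, task) {
  eu <- gamble_expected_utility(r, model, task)
  sure <- vapply(task$safe_amounts,
                 function(x) utility(r + x, model), numeric(length(r)))
  sure <- matrix(sure, nrow = length(r))
  eu > sure
}

#' Simulate noisily observed resources and certainty equivalents
#'
#' Draws agents with true resources uniform on `resource_range`, computes
#' each agent's exact certainty equivalent under the model, then adds
#' independent Gaussian observation noise to both coordinates: large on
#' resources (they are hard to measure) and small on certainty equivalents.
#' The sharp V-shaped curve then appears as a triangular scatter whose
#' vertical spread is widest at low observed resources -- the mechanism
#' behind the prediction that risk taking is more variable among the poor.
#'
#' @inheritParams certainty_equivalent
#' @param n_agents Number of simulated agents.
#' @param resource_range Interval (euros) for true resources.
#' @param resource_noise_sd,ce_noise_sd Observation noise standard
#'   deviations in euros (defaults 500 and 50).
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return A data frame with `true_resources`, `observed_resources`,
#'   `observed_ce`.
#' @export
simulate_noisy_scatter <- function(model = utility_model(),
                                   task = gamble_task(),
                                   n_agents = 1000,
                                   resource_range = c(-800, 800),
                                   resource_noise_sd = 500,
                                   ce_noise_sd = 50,
                                   seed = NULL, tol = 0.01) {
  if (!is.numeric(n_agents) || length(n_agents) != 1L || n_agents < 1)
    stop_invalid("`n_agents` must be a positive count")
  check_number(resource_noise_sd, "resource_noise_sd", lo = 0)
  check_number(ce_noise_sd, "ce_noise_sd", lo = 0)
  if (length(resource_range) != 2L || diff(resource_range) <= 0)
    stop_invalid("`resource_range` must be an increasing interval")
  with_seed(seed, {
    true_r <- runif(n_agents, resource_range[1], resource_range[2])
    ce <- certainty_equivalent(true_r, model, task, tol = tol)
    data.frame(
      true_resources = true_r,
      observed_resources = true_r + rnorm(n_agents, 0, resource_noise_sd),
      observed_ce = ce + rnorm(n_agents, 0, ce_noise_sd)
    )
  })
}
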