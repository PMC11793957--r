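test_that("utility evaluates the threshold form correctly", {
  m <- utility_model()
  expect_equal(utility(0, m), 0.5)
  expect_equal(utility(-1000, m), plogis(-10), tolerance = 1e-12)
  expect_equal(utility(-1000, m), 4.539787e-05, tolerance = 1e-5)
  expect_equal(utility(800, m), plogis(8) + 8 / 50, tolerance = 1e-12)
  expect_equal(utility(800, m), 1.1596646, tolerance = 1e-6)
  expect_error(utility(NaN, m), "finite")
  expect_error(utility(Inf, m), "finite")
})

test_that("utility is increasing, convex below and concave above the threshold", {
  m <- utility_model()
  below <- seq(-2000, -50, by = 10)
  above <- seq(50, 600, by = 10)
  expect_true(all(diff(utility(seq(-3000, 3000, by = 10), m)) > 0))
  # second differences: positive (convex) below, negative (concave) just above
  expect_true(all(diff(diff(utility(below, m))) > 0))
  expect_true(all(diff(diff(utility(above, m))) < 0))
  # far above, the linear term dominates: second differences vanish
  far <- seq(5000, 6000, by = 10)
  expect_lt(max(abs(diff(diff(utility(far, m))))), 1e-8)
})

test_that("expected gamble utility matches its definition", {
  m <- utility_model()
  task <- gamble_task()
  expect_equal(gamble_expected_utility(-400, m, task), 0.54, tolerance = 1e-9)
  # deep in the linear regime the gamble is worth its expected value shift
  r <- 30000
  expect_equal(gamble_expected_utility(r, m, task), utility(r + 400, m),
               tolerance = 1e-4)
  # degenerate-gamble limit: as p -> 1 expected utility -> utility(r + win)
  near <- gamble_task(win_probability = 1 - 1e-9)
  expect_equal(gamble_expected_utility(-100, m, near),
               utility(700, m), tolerance = 1e-6)
  expect_error(gamble_task(win_probability = 1), "strictly")
  expect_error(gamble_task(safe_amounts = c(100, 100, 200)), "increasing")
})

test_that("certainty equivalent solves the indifference equation", {
  m <- utility_model()
  task <- gamble_task()
  # linear utility: risk neutral, CE equals the expected value
  expect_equal(certainty_equivalent(0, linear_utility_model(), task), 400,
               tolerance = 0.02)
  expect_equal(certainty_equivalent(-5000, linear_utility_model(), task),
               400, tolerance = 0.02)
  # deep linear regime of the threshold model
  expect_equal(certainty_equivalent(20000, m, task), 400, tolerance = 0.5)
  # risk taking below, avoidance just above the switch
  expect_gt(certainty_equivalent(-600, m, task), 400)
  expect_lt(certainty_equivalent(-200, m, task), 400)
  # agreement with an independent root finder
  for (r in c(-700, -350, -50, 120, 900)) {
    target <- gamble_expected_utility(r, m, task)
    root <- uniroot(function(c) utility(r + c, m) - target,
                    c(0, 800), tol = 1e-9)$root
    expect_equal(certainty_equivalent(r, m, task), root, tolerance = 0.02)
  }
})

test_that("certainty equivalents respect Jensen's inequality by regime", {
  task <- gamble_task()
  withr::with_seed(7, {
    for (i in 1:20) {
      m <- utility_model(scale = runif(1, 60, 300),
                         slope = runif(1, 0.005, 0.05))
      # support entirely above the threshold: concave(-then-linear) region
      r_above <- runif(1, 50, 2000)
      expect_lte(certainty_equivalent(r_above, m, task),
                 task$risk_neutral_value + 0.02)
      # support entirely below the threshold: convex region
      r_below <- -task$win_amount - runif(1, 50, 2000)
      expect_gte(certainty_equivalent(r_below, m, task),
                 task$risk_neutral_value - 0.02)
    }
  })
})

test_that("the certainty equivalent is invariant to utility rescaling", {
  task <- gamble_task()
  ces <- vapply(c(0.001, 1 / 50, 0.4, 3),
                function(s) certainty_equivalent(-123,
                                                 linear_utility_model(slope = s),
                                                 task),
                numeric(1))
  expect_lt(max(ces) - min(ces), 0.05)
})

test_that("the CE curve crosses the risk-neutral value once, near -400", {
  m <- utility_model()
  task <- gamble_task()
  sw <- regime_switch_point(m, task, lower = -800, upper = 800, step = 10)
  expect_equal(sw$n_crossings, 1L)
  expect_gt(sw$switch_point, -450)
  expect_lt(sw$switch_point, -350)
  # the switch lies below the threshold
  expect_lt(sw$switch_point, m$threshold)
  # convergence to risk neutrality far above the threshold
  cc <- ce_curve(m, task, r_grid = 50 * m$scale)
  expect_lt(abs(cc$certainty_equivalent - 400), 1)
  # a grid wholly in the linear regime is classified risk neutral
  lin <- ce_curve(m, task, r_grid = seq(40000, 41000, by = 100),
                  neutral_tol = 1)
  expect_true(all(lin$regime == "risk_neutral"))
  expect_equal(nrow(ce_curve(m, task, r_grid = 0)), 1L)
  expect_error(ce_curve(m, task, r_grid = numeric(0)), "grid")
  expect_error(ce_curve(m, task, r_grid = c(3, 1, 2)), "sorted")
})

test_that("predicted bet counts follow the certainty equivalent cutoff", {
  task <- gamble_task()
  m <- utility_model()
  # risk-neutral agent strictly prefers the gamble to 100, 200, 300 only
  expect_identical(predicted_bet_count(0, linear_utility_model(), task), 3L)
  # concave region just above the threshold: avoids nearly all bets
  expect_identical(predicted_bet_count(100, utility_model(slope = 0), task),
                   0L)
  # count equals the position of the CE within the ladder
  withr::with_seed(3, {
    rs <- runif(40, -2000, 3000)
    for (r in rs) {
      ce <- certainty_equivalent(r, m, task)
      if (min(abs(ce - task$safe_amounts)) > 0.5) {
        expect_identical(predicted_bet_count(r, m, task),
                         as.integer(sum(task$safe_amounts < ce)))
      }
    }
  })
  # tremble is reproducible under a seed and bounded
  c1 <- predicted_bet_count(rep(-100, 50), m, task, tremble = 0.1, seed = 9)
  c2 <- predicted_bet_count(rep(-100, 50), m, task, tremble = 0.1, seed = 9)
  expect_identical(c1, c2)
  expect_true(all(c1 >= 0 & c1 <= 7))
  expect_error(predicted_bet_count(0, m, task, tremble = 0.5), "0.5")
})

test_that("noisy observation of the CE curve spreads the low-resource side", {
  m <- utility_model()
  task <- gamble_task()
  # zero noise reproduces the deterministic curve
  s0 <- simulate_noisy_scatter(m, task, n_agents = 50,
                               resource_noise_sd = 0, ce_noise_sd = 0,
                               seed = 5)
  expect_equal(s0$observed_resources, s0$true_resources)
  expect_equal(s0$observed_ce,
               certainty_equivalent(s0$true_resources, m, task),
               tolerance = 1e-9)
  # default noise: more CE variance below the median observed resources
  s <- simulate_noisy_scatter(m, task, n_agents = 4000, seed = 11)
  lowhalf <- s$observed_resources < median(s$observed_resources)
  expect_gt(var(s$observed_ce[lowhalf]), var(s$observed_ce[!lowhalf]))
  # a range deep in the linear regime gives CE about 400 plus noise
  s_lin <- simulate_noisy_scatter(m, task, n_agents = 400,
                                  resource_range = c(30000, 40000),
                                  seed = 2)
  expect_lt(abs(mean(s_lin$observed_ce) - 400), 10)
  expect_error(simulate_noisy_scatter(m, task, n_agents = 0), "positive")
})
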