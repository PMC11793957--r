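test_that("variance ratio test matches the F distribution and var.test", {
  x <- c(1, 2, 3, 5, 8, 4)
  y <- c(2, 2.5, 3, 3.2, 2.8, 2.1)
  res <- variance_ratio_test(x, y)
  ref <- var.test(x, y)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$ratio, var(x) / var(y))
  # identical groups: ratio one, p one
  same <- variance_ratio_test(x, x)
  expect_equal(same$ratio, 1)
  expect_equal(same$p_value, 1)
  # reciprocity: swapping groups inverts the ratio, keeps the p-value
  swapped <- variance_ratio_test(y, x)
  expect_equal(res$ratio * swapped$ratio, 1)
  expect_equal(res$p_value, swapped$p_value)
  # a true 4x variance ratio is detected
  withr::with_seed(10, {
    a <- rnorm(500, 0, 2); b <- rnorm(500, 0, 1)
    big <- variance_ratio_test(a, b)
    expect_gt(big$ratio, 3)
    expect_lt(big$ratio, 5)
    expect_lt(big$p_value, 0.001)
  })
  # df edge: two observations per group is valid
  expect_identical(variance_ratio_test(c(1, 2), c(3, 5))$df, c(1L, 1L))
  expect_error(variance_ratio_test(c(1, 1, 1), y), "zero variance")
  expect_error(variance_ratio_test(1, y), "at least 2")
})

test_that("squared-residual regression detects low-resource heteroscedasticity", {
  het <- toy_processed_panel(n_participants = 150, n_waves = 5, seed = 3,
                             hetero = TRUE)
  fit <- squared_residual_regression(het, "objective_resources")
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_value, 0.05)
  # constant response: all residuals zero, slope zero
  flat <- het
  flat$risk_count <- 3
  expect_equal(squared_residual_regression(flat,
                                           "objective_resources")$slope, 0)
})

test_that("the variance sweep is elevated under threshold structure and flat under the null", {
  proc <- preprocess_panel(generate_panel(
    panel_config(n_participants = 300, n_waves = 6), seed = 19))
  sw <- variance_sweep(proc, "subjective_resources", pmin = 5, pmax = 50,
                       step = 5)
  expect_true(all(sw$ratio > 1))
  # the ratio rises towards the low tail
  expect_gt(sw$ratio[1], sw$ratio[nrow(sw)])
  expect_equal(sw$p_holm, holm_bonferroni(sw$p_value))
  # permutation null: shuffling resources against counts flattens the curve
  null_proc <- proc
  null_proc$subjective_resources <-
    withr::with_seed(4, sample(proc$subjective_resources))
  sw0 <- variance_sweep(null_proc, "subjective_resources", pmin = 5,
                        pmax = 50, step = 5)
  expect_lt(max(abs(sw0$ratio - 1)), 0.25)
  expect_lt(mean(sw0$p_value < 0.05), 0.3)
  # single-point sweep
  sw1 <- variance_sweep(proc, "subjective_resources", pmin = 25, pmax = 25)
  expect_identical(nrow(sw1), 1L)
})

test_that("within-person stability relates time variance to mean resources", {
  proc <- preprocess_panel(generate_panel(
    panel_config(n_participants = 300, n_waves = 6), seed = 23))
  st <- within_person_stability(proc, "subjective_resources")
  expect_lt(st$slope, 0)
  expect_lt(st$p_value, 0.05)
  expect_identical(st$n_participants, nrow(st$participants))
  # constant counts per person: zero variance everywhere, zero slope
  flat <- proc
  flat$risk_count <- as.integer(flat$participant_id %% 3)
  expect_equal(within_person_stability(flat,
                                       "subjective_resources")$slope, 0)
  # tiny samples work but warn
  two <- proc[proc$participant_id %in% 1:2, ]
  expect_warning(within_person_stability(two, "subjective_resources"),
                 "fewer than 10")
  one_wave <- proc[!duplicated(proc$participant_id), ]
  expect_error(within_person_stability(one_wave, "subjective_resources"),
               "two or more")
})

test_that("the ICC decomposes between and within variance", {
  d <- data.frame(participant_id = rep(1:20, each = 4),
                  risk_count = rep(1:20, each = 4))
  expect_equal(icc(d), 1)
  withr::with_seed(2, {
    iid <- data.frame(participant_id = rep(1:200, each = 5),
                      risk_count = rnorm(1000))
    expect_lt(icc(iid), 0.05)
  })
  # known mix: between sd 1, within sd 1 gives ICC near one half
  withr::with_seed(3, {
    mix <- data.frame(participant_id = rep(1:300, each = 6),
                      risk_count = rep(rnorm(300), each = 6) + rnorm(1800))
    expect_lt(abs(icc(mix) - 0.5), 0.08)
  })
  expect_error(icc(d[!duplicated(d$participant_id), ]), "repeated")
})

test_that("Cronbach's alpha behaves at its anchors", {
  withr::with_seed(5, {
    common <- rnorm(400)
    same <- data.frame(a = common, b = common, c = common)
    expect_equal(cronbach_alpha(same), 1)
    indep <- data.frame(a = rnorm(400), b = rnorm(400), c = rnorm(400))
    expect_lt(abs(cronbach_alpha(indep)), 0.2)
    # loading 1 with unit noise on 3 items: alpha = 3r/(1+2r), r = 1/2
    noisy <- data.frame(a = common + rnorm(400), b = common + rnorm(400),
                        c = common + rnorm(400))
    expect_lt(abs(cronbach_alpha(noisy) - 3 * 0.5 / 2), 0.1)
  })
  expect_error(cronbach_alpha(data.frame(a = 1:5)), "2 items")
  expect_error(cronbach_alpha(data.frame(a = c(1, 1), b = c(1, 1))),
               "zero variance")
})

test_that("the preregistered dispersion family is Holm-corrected jointly", {
  proc <- preprocess_panel(generate_panel(
    panel_config(n_participants = 250, n_waves = 5), seed = 29))
  fam <- p2_family_tests(proc)
  expect_identical(nrow(fam), 3L)
  expect_equal(fam$p_holm, holm_bonferroni(fam$p_value))
  expect_gt(fam$estimate[1], 1)        # strained group more variable
  expect_true(all(fam$estimate[2:3] < 0))  # residuals shrink with resources
})
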