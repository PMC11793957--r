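test_that("extreme-behaviour classification uses the preregistered cutoffs", {
  expect_identical(as.character(classify_extremes(c(0, 4, 5, 7, 2))),
                   c("avoider", "neither", "taker", "taker", "neither"))
  expect_error(classify_extremes(8), "0..7")
  # the three classes partition any sample
  withr::with_seed(1, {
    counts <- sample(0:7, 200, replace = TRUE)
    cls <- classify_extremes(counts)
    expect_equal(sum(prop.table(table(cls))), 1)
  })
})

test_that("2x2 chi-squared agrees with the direct formula", {
  withr::with_seed(6, {
    for (i in 1:10) {
      tab <- matrix(sample(5:60, 4), 2)
      ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
      expect_lt(abs(unname(ref$statistic) - oracle_chisq_2x2(tab)), 1e-10)
    }
  })
})

test_that("prevalence tables show both extremes inflated at the bottom", {
  proc <- preprocess_panel(generate_panel(
    panel_config(n_participants = 350, n_waves = 6), seed = 13))
  tab <- extreme_prevalence_table(proc)
  full <- tab[tab$category == "full sample", ]
  for (rv in c("objective", "subjective")) {
    bottom <- tab[tab$category == sprintf("bottom 5%% %s", rv), ]
    expect_gt(bottom$pct_avoiders, full$pct_avoiders)
    expect_gt(bottom$pct_takers, full$pct_takers)
    expect_gt(bottom$var_ratio_vs_rest, 1)
  }
  expect_equal(sum(tab$category == "full sample"), 1)
  # permutation oracle: shuffled resources remove the tail excess
  null_proc <- proc
  null_proc$objective_resources <-
    withr::with_seed(2, sample(proc$objective_resources))
  null_tab <- extreme_prevalence_table(null_proc,
                                       resources = "objective_resources")
  nb <- null_tab[null_tab$category == "bottom 5% objective", ]
  expect_gt(nb$p_avoiders, 0.001)
  expect_gt(nb$p_takers, 0.001)
  # halves comparison still runs
  halves <- extreme_prevalence_table(proc, tail_pct = 50,
                                     resources = "objective_resources")
  expect_identical(nrow(halves), 3L)
  # a degenerate panel flags its chi-squared as missing
  allav <- proc
  allav$risk_count <- 0
  deg <- extreme_prevalence_table(allav, resources = "objective_resources")
  expect_true(all(deg$pct_avoiders == 100))
  expect_true(is.na(deg$chisq_takers[2]))
})

test_that("mean resources by bet count form an inverted V", {
  proc <- preprocess_panel(generate_panel(
    panel_config(n_participants = 350, n_waves = 6), seed = 13))
  mr <- mean_resources_by_count(proc)
  for (rv in c("objective_resources", "subjective_resources")) {
    sub <- mr[mr$resource == rv, ]
    mid <- sub$mean[sub$count_bin %in% c("2", "3", "4")]
    expect_lt(sub$mean[sub$count_bin == "0"], min(mid))
    expect_lt(sub$mean[sub$count_bin == "6-7"], min(mid))
  }
  expect_identical(nrow(mr), 14L)
  # empty bins are reported as missing, not dropped silently
  few <- proc[proc$risk_count %in% c(2, 3), ]
  mr2 <- mean_resources_by_count(few, resources = "objective_resources")
  expect_true(all(is.na(mr2$mean[mr2$count_bin == "0"])))
  expect_identical(mr2$n[mr2$count_bin == "0"], 0L)
})

test_that("strain groups order mean and variance as predicted", {
  proc <- preprocess_panel(generate_panel(
    panel_config(n_participants = 350, n_waves = 6), seed = 13))
  ss <- strain_group_summary(proc)
  expect_identical(ss$financial_strain[1], "very difficult")
  expect_equal(ss$var_count[1], max(ss$var_count))
  expect_lt(ss$mean_count[1], ss$mean_count[nrow(ss)] + 1)
  same <- proc
  same$risk_count <- 2L
  expect_true(all(strain_group_summary(same)$var_count == 0))
})

test_that("time discounting is asymmetric in the bottom tail", {
  proc <- preprocess_panel(generate_panel(
    panel_config(n_participants = 350, n_waves = 6), seed = 13))
  dc <- discounting_contrast(proc)
  full <- dc[dc$category == "full sample", ]
  for (rv in c("objective", "subjective")) {
    bottom <- dc[dc$category == sprintf("bottom 5%% %s", rv), ]
    expect_gt(bottom$pct_high, full$pct_high)       # steep discounting up
    # and it rises far more than flat discounting does
    expect_gt(bottom$pct_high - full$pct_high,
              bottom$pct_low - full$pct_low)
  }
  alls <- proc
  alls$discount_count <- 7L
  tab <- discounting_contrast(alls, resources = "objective_resources")
  expect_true(all(tab$pct_high == 100))
})

test_that("consistency is uncorrelated with resources by construction", {
  proc <- preprocess_panel(generate_panel(
    panel_config(n_participants = 350, n_waves = 6), seed = 13))
  cb <- consistency_by_resources(proc)
  expect_true(all(abs(cb$r) < 0.08))
  allc <- proc
  allc$consistent <- TRUE
  expect_warning(
    out <- consistency_by_resources(allc, resources = "objective_resources"),
    "degenerate")
  expect_true(all(is.na(out$r)))
  # perfectly resource-sorted flags give a large correlation
  sorted <- proc
  sorted$consistent <- proc$objective_resources >
    median(proc$objective_resources)
  cs <- consistency_by_resources(sorted,
                                 resources = "objective_resources")
  expect_gt(abs(cs$r), 0.5)
})
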