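# Independent oracles used across test files.

# Brute-force pair scan: a battery is inconsistent if the gamble was
# refused against some sure amount but accepted against a larger one.
oracle_consistent <- function(choices) {
  n <- length(choices)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (choices[i] == 0 && choices[j] == 1) return(FALSE)
    }
  }
  TRUE
}

# All 128 possible 7-item batteries, one per row.
all_batteries <- function() {
  as.matrix(expand.grid(rep(list(0:1), 7)))
}

# Pearson chi-squared on a 2x2 table, from the definition.
oracle_chisq_2x2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Hand-coded Holm step-down adjustment.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# A small processed-style panel with known structure, for descriptive and
# dispersion unit tests.
toy_processed_panel <- function(n_participants = 60, n_waves = 4,
                                seed = 1, hetero = FALSE) {
  withr::with_seed(seed, {
    id <- rep(seq_len(n_participants), each = n_waves)
    res <- rep(rnorm(n_participants), each = n_waves) +
      rnorm(n_participants * n_waves, 0, 0.5)
    sdv <- if (hetero) ifelse(res < quantile(res, 0.2), 2, 1) else 1
    y <- pmin(pmax(round(2.3 + 0.2 * res +
                           rep(rnorm(n_participants), each = n_waves) +
                           rnorm(length(res), 0, sdv)), 0), 7)
    data.frame(
      participant_id = id,
      wave = rep(seq_len(n_waves), n_participants),
      objective_resources = res,
      subjective_resources = res + rnorm(length(res), 0, 0.3),
      risk_count = y,
      discount_count = pmin(pmax(round(3 - 0.2 * res +
                                         rnorm(length(res))), 0), 7),
      consistent = runif(length(res)) > 0.06,
      z_age = rep(rnorm(n_participants), each = n_waves),
      gender = rep(sample(c("man", "woman"), n_participants, TRUE),
                   each = n_waves),
      financial_strain = factor(
        sample(c("very difficult", "quite difficult",
                 "just about getting by", "doing alright",
                 "living comfortably"), length(res), TRUE),
        levels = c("very difficult", "quite difficult",
                   "just about getting by", "doing alright",
                   "living comfortably"), ordered = TRUE)
    )
  })
}
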