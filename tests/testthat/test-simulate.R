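test_that("trial grid is the full factorial, exactly once", {
  g <- build_trial_grid(default_design)
  expect_equal(nrow(g), 72)
  expect_equal(nrow(unique(g)), 72)

  d1 <- task_design(distances = 5, selfish_amounts = 130)
  expect_equal(nrow(build_trial_grid(d1)), 1)

  d2 <- task_design(distances = c(1, 4, 9),
                    selfish_amounts = c(130, 150, 170, 190))
  g2 <- build_trial_grid(d2, seed = 7)
  expect_equal(nrow(unique(g2)), length(d2$distances) *
                 length(d2$selfish_amounts))
  # randomization keeps distance blocks contiguous
  expect_equal(sum(diff(match(g2$distance, d2$distances)) != 0), 2)
})

test_that("design validation rejects malformed designs", {
  expect_error(task_design(distances = c(3, 2)), "increasing")
  expect_error(task_design(selfish_amounts = c(100, 120)), "generous")
  expect_error(task_design(rt_floor = 7), "response_window")
  expect_error(task_design(payout_rate = 1.2), "payout_rate")
})

test_that("softmax choice probability follows the value difference", {
  ag <- agent_params(k = 0.1, V = 170, sigma = 0.05)
  # equal subjective values: 130 + 170/(1 + 0.1*10) = 215
  expect_equal(choice_probability(ag, 10, 215), 0.5)
  # zero inverse temperature: value-blind
  ag0 <- agent_params(k = 0.1, V = 170, sigma = 0)
  expect_equal(choice_probability(ag0, c(1, 100), c(130, 290)),
               c(0.5, 0.5))
  # hand-evaluated logistic: sigma*(290 - 215) = 3.75
  expect_equal(choice_probability(ag, 10, 290), stats::plogis(3.75),
               tolerance = 1e-12)
  # strictly increasing in amount, decreasing in V
  amounts <- seq(130, 290, 20)
  expect_true(all(diff(choice_probability(ag, 10, amounts)) > 0))
  ags <- lapply(c(100, 170, 240), function(v)
    agent_params(k = 0.1, V = v, sigma = 0.05))
  ps <- vapply(ags, choice_probability, numeric(1), distance = 10,
               selfish_amount = 230)
  expect_true(all(diff(ps) < 0))
})

test_that("participant simulation is seed-deterministic and matches the softmax law", {
  ag <- agent_params(k = 0.2, V = 280, sigma = 0.05)
  expect_error(simulate_participant(ag), "seed")
  a <- softmax_trials(ag, seed = 42)
  b <- softmax_trials(ag, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 72)

  # near-deterministic agent chooses by the value threshold
  agd <- agent_params(k = 0.2, V = 280, sigma = 50)
  tr <- softmax_trials(agd, seed = 9)
  thr <- 130 + 280 / (1 + 0.2 * tr$distance)
  clear <- abs(tr$selfish_amount - thr) > 0.5
  expect_gte(mean((tr$choice[clear] == "selfish") ==
                    (tr$selfish_amount[clear] > thr[clear])), 0.99)

  # Monte-Carlo law of large numbers on one repeated trial
  p <- choice_probability(ag, 10, 230)
  one <- task_design(distances = 10, selfish_amounts = 230)
  n <- 4000
  hits <- vapply(seq_len(n), function(i) {
    simulate_participant(ag, design = one, seed = i)$choice == "selfish"
  }, logical(1))
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(hits) - p), 3 * se)
})

test_that("diffusion simulator matches the analytic hitting probability", {
  cases <- list(c(2, 0.3, 1), c(1.5, 0.5, 0), c(1, 0.6, -0.8))
  for (cs in cases) {
    pp <- ddm_params(alpha = cs[1], beta = cs[2], delta = cs[3],
                     tau = 0.2)
    s <- simulate_ddm_trial(pp, seed = 33, n = 8000)
    expect_true(all(s$rt > pp$tau, na.rm = TRUE))
    p_cl <- if (cs[3] == 0) cs[2] else
      (1 - exp(-2 * cs[3] * cs[2] * cs[1])) /
      (1 - exp(-2 * cs[3] * cs[1]))
    phat <- mean(s$boundary == "upper", na.rm = TRUE)
    se <- sqrt(p_cl * (1 - p_cl) / nrow(s))
    expect_lt(abs(phat - p_cl), 4 * se)
  }
  expect_error(simulate_ddm_trial(ddm_params(), seed = 1, dt = 0),
               "positive")
})

test_that("cohort generator delivers the cell structure and contamination", {
  tr <- small_cohort(n_per_cell = 10, seed = 202, mode = "ddm",
                     fast_guess_rate = 0.05, skip_rate = 0)
  meta <- unique(tr[, c("participant_id", "sex", "condition")])
  expect_equal(nrow(meta), 40)
  expect_equal(unname(c(table(meta$sex, meta$condition))), rep(10, 4))
  expect_equal(nrow(tr), 40 * 72)

  # injected fast guesses within binomial 95% bounds of the rate
  scored <- tr$choice != "skipped"
  n_fast <- sum(scored & tr$rt < default_design$rt_floor)
  n <- sum(scored)
  expect_lt(abs(n_fast / n - 0.05), 1.96 * sqrt(0.05 * 0.95 / n) + 1e-9)

  # zero dispersion: all participants share the expected choice curve
  tr0 <- small_cohort(n_per_cell = 4, seed = 7, mode = "softmax",
                      dispersion = list(k = 0, V = 0, sigma = 0,
                                        alpha = 0, beta = 0, delta = 0,
                                        tau = 0),
                      fast_guess_rate = 0, skip_rate = 0)
  tp <- attr(tr0, "truth_params")
  expect_equal(length(unique(tp$k)), 1)
  expect_equal(length(unique(tp$V)), 1)

  # skipped trials carry no rt and scored trials always do (ddm mode)
  trs <- small_cohort(n_per_cell = 2, seed = 9, mode = "ddm",
                      skip_rate = 0.2)
  expect_true(all(is.na(trs$rt[trs$choice == "skipped"])))
  expect_true(all(!is.na(trs$rt[trs$choice != "skipped"])))
})
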