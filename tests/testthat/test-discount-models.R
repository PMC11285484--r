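test_that("hyperbolic value follows v = V/(1+kD)", {
  expect_equal(hyperbolic_value(150, 0.08, 0), 150)
  expect_equal(hyperbolic_value(150, 0, c(1, 50, 100)), rep(150, 3))
  expect_equal(hyperbolic_value(170, 0.05, 20), 85)
  expect_error(hyperbolic_value(-1, 0.1, 1))
})

test_that("least-squares fit recovers noiseless hyperbolic profiles", {
  D <- default_design$distances
  pr <- profile_from_forgone(hyperbolic_value(150, 0.08, D))
  fit <- fit_hyperbolic(pr)
  expect_lt(abs(fit$k - 0.08) / 0.08, 1e-3)
  expect_lt(abs(fit$V - 150) / 150, 1e-3)
  expect_equal(fit$log_k, log(fit$k))
  expect_true(fit$converged)

  flat <- fit_hyperbolic(profile_from_forgone(rep(90, 8)))
  expect_true(flat$flat)
  expect_equal(flat$k, 1e-6)
  expect_error(fit_hyperbolic(profile_from_forgone(c(10, 20),
                                                   distances = c(1, 2))),
               "3 finite points")
})

test_that("least-squares fit recovers k from noisy profiles in the median", {
  set.seed(2024)
  D <- default_design$distances
  truth <- hyperbolic_value(150, 0.08, D)
  ks <- replicate(1000, {
    y <- truth + stats::rnorm(8, 0, 10)
    fit_hyperbolic(profile_from_forgone(y))$k
  })
  expect_lt(abs(median(ks) - 0.08) / 0.08, 0.1)
})

test_that("trial negative log-likelihood matches hand arithmetic and is additive", {
  ag <- agent_params(k = 0.1, V = 170, sigma = 0.05)
  eq <- data.frame(distance = 10, selfish_amount = 215, choice = "selfish")
  expect_equal(trial_negative_loglik(ag, eq), log(2), tolerance = 1e-12)
  one <- data.frame(distance = 10, selfish_amount = 290,
                    choice = "selfish")
  expect_equal(trial_negative_loglik(ag, one), -log(stats::plogis(3.75)),
               tolerance = 1e-12)
  t1 <- softmax_trials(ag, seed = 5)[1:30, ]
  t2 <- softmax_trials(ag, seed = 6)[1:40, ]
  expect_equal(trial_negative_loglik(ag, rbind(t1, t2)),
               trial_negative_loglik(ag, t1) +
                 trial_negative_loglik(ag, t2))
  expect_error(trial_negative_loglik(ag, t1[0, ]), "empty")
})

test_that("MLE applies the fast-guess filter and counts trials", {
  ag <- agent_params(k = 0.2, V = 280, sigma = 0.05)
  tr <- simulate_participant(ag, ddm_params(), seed = 12, mode = "hybrid")
  tr$rt[1:5] <- 0.1   # inject 5 fast guesses
  fit <- fit_mle(tr)
  expect_equal(fit$n_trials_used, 67)
  expect_error(fit_mle(tr[1:10, ]), "at least 20")
})

test_that("MLE estimates are invariant to trial order and flag value-blind data", {
  ag <- agent_params(k = 0.2, V = 280, sigma = 0.05)
  tr <- softmax_trials(ag, seed = 21)
  f1 <- fit_mle(tr)
  f2 <- fit_mle(tr[rev(seq_len(nrow(tr))), ])
  expect_equal(f1$k, f2$k, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)

  coin <- softmax_trials(agent_params(k = 0.2, V = 280, sigma = 0),
                         seed = 31)
  fc <- fit_mle(coin)
  expect_true(fc$weakly_identified)
  expect_lt(fc$sigma, 0.01)
})

test_that("MLE and least squares agree on dense noiseless data", {
  # near-deterministic choices at a fine amount grid approximate the
  # noiseless discount curve
  d <- task_design(selfish_amounts = seq(130, 290, 5))
  ag <- agent_params(k = 0.15, V = 140, sigma = 5)
  tr <- simulate_participant(ag, design = d, seed = 8)
  mle <- fit_mle(tr, design = d)
  pr <- discount_profile(tr, d)
  hyp <- fit_hyperbolic(pr)
  expect_lt(abs(mle$k - hyp$k), 0.05)
  expect_lt(abs(mle$V - hyp$V), 20)
  expect_lt(abs(mle$k - 0.15), 0.05)
})

test_that("the generating parameters sit near the likelihood optimum", {
  set.seed(55)
  ag <- agent_params(k = 0.2, V = 250, sigma = 0.05)
  worse <- 0
  for (i in 1:20) {
    tr <- softmax_trials(ag, seed = 1000 + i)
    nll0 <- trial_negative_loglik(ag, tr)
    pert <- agent_params(k = 0.2 * exp(stats::runif(1, -1, 1)),
                         V = 250 + stats::runif(1, -80, 80),
                         sigma = 0.05 * exp(stats::runif(1, -1, 1)))
    if (trial_negative_loglik(pert, tr) < nll0) worse <- worse + 1
  }
  expect_lte(worse, 5)  # consistency holds in expectation
})
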