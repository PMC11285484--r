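test_that("Wiener density obeys reflection symmetry to machine precision", {
  rts <- seq(0.25, 4, by = 0.05)
  p1 <- ddm_params(alpha = 1.5, beta = 0.4, delta = 0.8, tau = 0.2)
  p2 <- ddm_params(alpha = 1.5, beta = 0.6, delta = -0.8, tau = 0.2)
  expect_equal(wiener_log_density(rts, "lower", p1),
               wiener_log_density(rts, "upper", p2), tolerance = 1e-14)
  # rt at or below tau has zero density
  expect_identical(wiener_log_density(c(0.1, 0.2), "upper", p1),
                   c(-Inf, -Inf))
})

test_that("Wiener density integrates to unit mass over both boundaries", {
  grid <- list(c(1.5, 0.4, 0.8, 0.2), c(1.0, 0.5, 0.0, 0.3),
               c(2.5, 0.3, -1.2, 0.15))
  for (g in grid) {
    p <- ddm_params(alpha = g[1], beta = g[2], delta = g[3], tau = g[4])
    f <- function(t, b) exp(wiener_log_density(t, b, p))
    m <- stats::integrate(f, p$tau, 60, b = "upper",
                          rel.tol = 1e-9)$value +
      stats::integrate(f, p$tau, 60, b = "lower", rel.tol = 1e-9)$value
    expect_lt(abs(m - 1), 1e-4)
    expect_true(all(is.finite(
      wiener_log_density(seq(p$tau + 0.01, 5, 0.1), "upper", p)) |
        wiener_log_density(seq(p$tau + 0.01, 5, 0.1), "upper", p) ==
        -Inf))
  }
})

test_that("Wiener density agrees with the Euler simulation oracle", {
  p <- ddm_params(alpha = 1.5, beta = 0.4, delta = 0.8, tau = 0.2)
  s <- simulate_ddm_trial(p, seed = 99, n = 40000)
  up <- s$rt[s$boundary == "upper"]
  # conditional cdf of upper-boundary rts from the density
  f <- function(t) exp(wiener_log_density(t, "upper", p))
  pu <- stats::integrate(f, p$tau, 60, rel.tol = 1e-9)$value
  cdf <- vapply(seq(0.3, 4, by = 0.1), function(q)
    stats::integrate(f, p$tau, q, rel.tol = 1e-8)$value / pu, numeric(1))
  emp <- stats::ecdf(up)(seq(0.3, 4, by = 0.1))
  expect_lt(max(abs(cdf - emp)), 0.015)
})

test_that("hdi finds the narrowest interval", {
  set.seed(31)
  z <- stats::rnorm(1e6)
  h <- hdi(z)
  expect_lt(abs(h[1] + 1.96), 0.02)
  expect_lt(abs(h[2] - 1.96), 0.02)
  expect_equal(hdi(rep(3.5, 200)), c(3.5, 3.5))
  # right-skewed: strictly narrower than equal-tailed
  x <- stats::rexp(5e4)
  h2 <- hdi(x)
  et <- stats::quantile(x, c(0.025, 0.975))
  expect_lt(h2[2] - h2[1], et[2] - et[1])
  # exhaustive scan oracle at small n
  xs <- sort(stats::rlnorm(500))
  nk <- ceiling(0.95 * 500)
  widths <- xs[nk:500] - xs[1:(500 - nk + 1)]
  i <- which.min(widths)
  expect_equal(hdi(xs), c(xs[i], xs[i + nk - 1]))
  expect_error(hdi(stats::rnorm(50)), "100")
})

test_that("rank-normalized split R-hat separates mixed from unmixed chains", {
  set.seed(77)
  iid <- matrix(stats::rnorm(4000), ncol = 4)
  expect_lt(rhat(iid), 1.01)
  expect_gte(rhat(iid), 0.99)  # can dip just below 1 by sampling noise
  apart <- cbind(stats::rnorm(500), stats::rnorm(500, 5),
                 stats::rnorm(500), stats::rnorm(500, 5))
  expect_gt(rhat(apart), 1.5)
  expect_error(rhat(matrix(stats::rnorm(100), ncol = 1)), "2 chains")
})

test_that("credible difference follows the 95% HDI rule", {
  tr <- small_cohort(n_per_cell = 3, seed = 5, mode = "ddm")
  fit <- fit_hierarchical_ddm(tr, chains = 2, iter = 400, seed = 2)
  expect_s3_class(fit, "ddm_posterior")
  expect_true(all(fit$hdi_95[, "low"] <= fit$hdi_95[, "high"]))
  verdicts <- vapply(ddm_effect_coefficients(), function(cf)
    credible_group_difference(fit, cf), character(1))
  manual <- ifelse(fit$hdi_95[ddm_effect_coefficients(), "low"] > 0 |
                     fit$hdi_95[ddm_effect_coefficients(), "high"] < 0,
                   "credible", "not_credible")
  expect_equal(unname(verdicts), unname(manual))
  expect_error(credible_group_difference(fit, "nonsense"), "unknown")
})

test_that("hierarchical fit demands a seed and full cells", {
  tr <- small_cohort(n_per_cell = 3, seed = 5, mode = "ddm")
  expect_error(fit_hierarchical_ddm(tr), "seed")
  one_cell <- tr[tr$sex == "female" & tr$condition == "control", ]
  expect_error(fit_hierarchical_ddm(one_cell, seed = 1), "cell")
})

test_that("an injected drift effect is detected and shrinks with sample size", {
  base <- ddm_params()
  shifted <- ddm_params(delta = base$delta + 1.0)
  mk_cells <- function() list(
    female_control = list(agent = agent_params(), ddm = base),
    female_androstadienone = list(agent = agent_params(), ddm = shifted),
    male_control = list(agent = agent_params(), ddm = base),
    male_androstadienone = list(agent = agent_params(), ddm = shifted))
  fit_n <- function(n, seed) {
    tr <- simulate_cohort(cohort_truth(n_per_cell = n,
                                       cells = mk_cells()),
                          seed = seed, mode = "ddm")
    fit_hierarchical_ddm(tr, chains = 2, iter = 800, seed = seed)
  }
  f_small <- fit_n(4, 61)
  f_large <- fit_n(10, 62)
  expect_equal(credible_group_difference(f_large, "delta_condition"),
               "credible")
  err_small <- abs(f_small$group_mean["delta_condition"] - 1.0)
  err_large <- abs(f_large$group_mean["delta_condition"] - 1.0)
  expect_lt(err_large, 0.4)
  expect_lt(err_large, err_small + 0.15)
})

test_that("null-coefficient HDIs cover zero at the nominal rate", {
  # many scaled-down null cohorts; coverage of the 12 zero effects
  set.seed(300)
  n_sims <- 50
  covered <- 0L; total <- 0L
  d_small <- task_design(distances = c(1, 5, 20, 100),
                         selfish_amounts = seq(130, 290, 40))
  for (s in seq_len(n_sims)) {
    tr <- simulate_cohort(cohort_truth(n_per_cell = 3),
                          design = d_small, seed = 9000 + s,
                          mode = "ddm")
    fit <- fit_hierarchical_ddm(tr, chains = 2, iter = 300,
                                seed = 9000 + s, sweeps = 2)
    h <- fit$hdi_95[ddm_effect_coefficients(), , drop = FALSE]
    covered <- covered + sum(h[, "low"] <= 0 & h[, "high"] >= 0)
    total <- total + nrow(h)
  }
  # binomial tolerance around 0.95 (hierarchical shrinkage keeps
  # null-coefficient coverage at or above nominal)
  expect_gte(covered / total, 0.90)
})
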