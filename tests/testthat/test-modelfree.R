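amounts9 <- default_design$selfish_amounts

test_that("exclusive choosers are imputed half an increment outside the range", {
  all_gen <- fit_indifference_point(rep("generous", 9), amounts9)
  expect_equal(all_gen$indifference_point, 300)
  expect_equal(all_gen$method, "imputed_high")
  all_sel <- fit_indifference_point(rep("selfish", 9), amounts9)
  expect_equal(all_sel$indifference_point, 120)
  expect_equal(all_sel$method, "imputed_low")
})

test_that("perfect separation takes the gap midpoint", {
  ch <- ifelse(amounts9 <= 210, "generous", "selfish")
  f <- fit_indifference_point(ch, amounts9)
  expect_equal(f$indifference_point, 220)
  expect_equal(f$method, "separation_midpoint")
  # noiseless monotone data equals brute-force bisection of the step
  for (cut in c(150, 190, 250)) {
    ch <- ifelse(amounts9 < cut, "generous", "selfish")
    below <- max(amounts9[amounts9 < cut])
    above <- min(amounts9[amounts9 >= cut])
    f <- fit_indifference_point(ch, amounts9)
    expect_equal(f$indifference_point, (below + above) / 2)
  }
})

test_that("logistic route recovers a known indifference point", {
  set.seed(404)
  true_ip <- 190; sigma <- 0.1
  est <- replicate(500, {
    p <- stats::plogis(sigma * (amounts9 - true_ip))
    ch <- ifelse(stats::runif(9) < p, "selfish", "generous")
    fit_indifference_point(ch, amounts9)$indifference_point
  })
  # choices at this sigma are close to a step, so single-fit estimates
  # cluster at the neighbouring separation midpoints; the replicate mean
  # centres on the generating indifference point
  expect_lt(abs(mean(est) - true_ip), 5)
  expect_true(all(est >= 120 & est <= 300))
})

test_that("amount forgone is the indifference point minus the generous amount", {
  expect_equal(amount_forgone(300), 170)
  expect_equal(amount_forgone(130), 0)
  expect_equal(amount_forgone(120), -10)
  expect_error(amount_forgone(500), "outside")
  expect_equal(amount_forgone(NA_real_), NA_real_)
})

test_that("AUC hits its analytic extremes and hand-computed values", {
  d <- default_design
  expect_equal(compute_auc(profile_from_forgone(rep(170, 8)), d)$auc, 1)
  expect_equal(compute_auc(profile_from_forgone(rep(0, 8)), d)$auc, 0)
  # hand trapezoid: full generosity through distance 50, none at 100
  pr <- profile_from_forgone(c(rep(170, 7), 0))
  expect_equal(compute_auc(pr, d)$auc, 0.75)
  # the -10 imputation is clipped to 0 inside the AUC only
  pr2 <- profile_from_forgone(rep(-10, 8))
  expect_equal(compute_auc(pr2, d)$auc, 0)
  expect_equal(pr2$amount_forgone, rep(-10, 8))
  expect_error(compute_auc(profile_from_forgone(1, distances = 1), d),
               "2 distances")
})

test_that("AUC is monotone and invariant to collinear interior points", {
  set.seed(11)
  for (i in 1:20) {
    y1 <- sort(stats::runif(8, 0, 170), decreasing = TRUE)
    bump <- stats::runif(8, 0, 170 - y1)
    a1 <- compute_auc(profile_from_forgone(y1), default_design)$auc
    a2 <- compute_auc(profile_from_forgone(y1 + bump), default_design)$auc
    expect_gte(a2, a1 - 1e-12)
  }
  # adding a distance on the chord joining its neighbours changes nothing
  d5 <- task_design(distances = c(1, 10, 100))
  y <- c(150, 100, 20)
  a <- compute_auc(profile_from_forgone(y, distances = d5$distances),
                   d5)$auc
  d6 <- task_design(distances = c(1, 10, 55, 100))
  mid <- 100 + (55 - 10) / (100 - 10) * (20 - 100)
  a6 <- compute_auc(profile_from_forgone(c(150, 100, mid, 20),
                                         distances = d6$distances), d6)$auc
  expect_equal(a6, a)
})

test_that("profiles are estimated per participant and distance, skipping skipped trials", {
  tr <- small_cohort(n_per_cell = 2, seed = 77, skip_rate = 0.1)
  pr <- discount_profile(tr)
  expect_equal(sort(unique(pr$distance)), default_design$distances)
  expect_equal(length(unique(pr$participant_id)), 8)
  expect_true(all(pr$indifference_point >= 120 &
                    pr$indifference_point <= 300))
  expect_equal(pr$amount_forgone, pr$indifference_point - 130)
  auc <- compute_auc(pr)
  expect_true(all(auc$auc >= 0 & auc$auc <= 1))
})
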