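#' Hyperbolic discounting value
#'
#' Amount forgone predicted at social distance `D`: `V / (1 + k * D)`.
#'
#' @param V generosity intercept (HKD, >= 0).
#' @param k discount rate (>= 0).
#' @param D social distance(s) (>= 0).
#' @return Predicted amount forgone in HKD.
#' @export
hyperbolic_value <- function(V, k, D) {
  stopifnot(V >= 0, k >= 0, all(D >= 0))
  V / (1 + k * D)
}

# deterministic bounds shared by both fitting routes
.k_bounds <- c(1e-6, 10)
.V_bounds <- c(0, 1000)
.sigma_bounds <- c(1e-6, 10)

#' Least-squares hyperbolic fit to a discounting profile
#'
#' Fits `amount_forgone ~ V / (1 + k * distance)` by ordinary least
#' squares: a log-spaced grid over `k` (with the conditionally optimal
#' `V` solved in closed form at each `k`) followed by local refinement of
#' the best grid point with `optim`. The procedure is deterministic. A
#' profile with no curvature (identical forgone amounts everywhere) pins
#' `k` at its lower bound and raises the `flat` flag.
#'
#' @param profile a single participant's rows from [discount_profile()],
#'   or any data frame with `distance` and `amount_forgone` columns; at
#'   least 3 finite points are required.
#' @return A one-row data frame: `participant_id`, `k`, `log_k`, `V`,
#'   `sse`, `converged`, `flat`, `n_points`.
#' @export
fit_hyperbolic <- function(profile) {
  pr <- profile[is.finite(profile$amount_forgone), , drop = FALSE]
  if (nrow(pr) < 3)
    stop("fit_hyperbolic needs at least 3 finite points")
  id <- if ("participant_id" %in% names(pr)) as.character(pr$participant_id[1])
        else NA_character_
  D <- pr$distance
  y <- pr$amount_forgone

  if (stats::var(y) == 0) {
    return(data.frame(participant_id = id, k = .k_bounds[1],
                      log_k = log(.k_bounds[1]), V = max(mean(y), 0),
                      sse = sum((y - max(mean(y), 0))^2),
                      converged = FALSE, flat = TRUE, n_points = nrow(pr)))
  }

  v_hat <- function(k) {
    h <- 1 / (1 + k * D)
    max(sum(y * h) / sum(h * h), 0)
  }
  sse_k <- function(k) {
    V <- v_hat(k)
    sum((y - V / (1 + k * D))^2)
  }
  kgrid <- exp(seq(log(1e-4), log(.k_bounds[2]), length.out = 60))
  s <- vapply(kgrid, sse_k, numeric(1))
  k0 <- kgrid[which.min(s)]
  obj <- function(par) {
    k <- exp(par[1]); V <- par[2]
    sum((y - V / (1 + k * D))^2)
  }
  opt <- stats::optim(c(log(k0), v_hat(k0)), obj, method = "L-BFGS-B",
                      lower = c(log(.k_bounds[1]), .V_bounds[1]),
                      upper = c(log(.k_bounds[2]), .V_bounds[2]))
  k <- exp(opt$par[1])
  data.frame(participant_id = id, k = k, log_k = log(k), V = opt$par[2],
             sse = opt$value, converged = opt$convergence == 0,
             flat = FALSE, n_points = nrow(pr))
}

#' Negative log-likelihood of scored trials under the softmax rule
#'
#' Sum of `-log p` over trials, where `p` is the softmax probability of
#' the observed choice given the subjective values: the selfish option at
#' its face amount, the generous option at
#' `generous_amount + V / (1 + k * D)`.
#'
#' @param agent an [agent_params()].
#' @param trials data frame with `distance`, `selfish_amount`, `choice`
#'   columns (scored trials only).
#' @param design a [task_design()].
#' @return Scalar negative log-likelihood.
#' @export
trial_negative_loglik <- function(agent, trials, design = task_design()) {
  stopifnot(inherits(agent, "agent_params"))
  if (nrow(trials) == 0L) stop("empty trial set")
  stopifnot(all(trials$choice %in% c("selfish", "generous")))
  vg <- design$generous_amount + agent$V / (1 + agent$k * trials$distance)
  dv <- agent$sigma * (trials$selfish_amount - vg)
  sel <- trials$choice == "selfish"
  -sum(stats::plogis(ifelse(sel, dv, -dv), log.p = TRUE))
}

#' Trial-level maximum likelihood fit of the discounting parameters
#'
#' Maximizes the softmax likelihood over `(log k, V, log sigma)` with a
#' deterministic 3 x 3 x 3 multistart grid and L-BFGS-B refinement.
#' Skipped trials and trials faster than `rt_floor` (fast guesses) are
#' excluded first; trials with no recorded response time (choice-only
#' simulation) are kept. At least `min_trials` scored trials must remain.
#' A fitted `sigma` at the edge of its bounds flags weak identification
#' (the likelihood is flat in `k` and `V` when choices are value-blind).
#'
#' @param trials one participant's trial data frame.
#' @param design a [task_design()].
#' @param rt_floor fast-guess threshold in seconds.
#' @param min_trials minimum scored trials required after filtering.
#' @return A one-row data frame: `participant_id`, `k`, `log_k`, `V`,
#'   `sigma`, `loglik`, `converged`, `weakly_identified`, `n_trials_used`.
#' @export
fit_mle <- function(trials, design = task_design(),
                    rt_floor = design$rt_floor, min_trials = 20) {
  id <- if ("participant_id" %in% names(trials))
    as.character(trials$participant_id[1]) else NA_character_
  tr <- trials[trials$choice != "skipped", , drop = FALSE]
  tr <- tr[is.na(tr$rt) | tr$rt >= rt_floor, , drop = FALSE]
  n_used <- nrow(tr)
  if (n_used < min_trials)
    stop("fit_mle needs at least ", min_trials, " scored trials (",
         n_used, " available)")
  D <- tr$distance
  A <- tr$selfish_amount
  sel <- tr$choice == "selfish"
  g <- design$generous_amount

  nll <- function(par) {
    k <- exp(par[1]); V <- par[2]; s <- exp(par[3])
    dv <- s * (A - (g + V / (1 + k * D)))
    -sum(stats::plogis(ifelse(sel, dv, -dv), log.p = TRUE))
  }
  starts <- expand.grid(k = c(0.02, 0.2, 1), V = c(50, 170, 400),
                        sigma = c(0.01, 0.05, 0.2))
  lower <- c(log(.k_bounds[1]), .V_bounds[1], log(.sigma_bounds[1]))
  upper <- c(log(.k_bounds[2]), .V_bounds[2], log(.sigma_bounds[2]))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(log(starts$k[i]), starts$V[i], log(starts$sigma[i]))
    opt <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(data.frame(participant_id = id, k = NA_real_, log_k = NA_real_,
                      V = NA_real_, sigma = NA_real_, loglik = NA_real_,
                      converged = FALSE, weakly_identified = NA,
                      n_trials_used = n_used))
  }
  k <- exp(best$par[1]); V <- best$par[2]; s <- exp(best$par[3])
  # if sigma spreads choice log-odds by less than one logit across the
  # whole amount range, the likelihood is essentially flat in (k, V)
  weak <- s * diff(range(A)) < 1 || s >= .sigma_bounds[2] / 2
  data.frame(participant_id = id, k = k, log_k = log(k), V = V, sigma = s,
             loglik = -best$value, converged = best$convergence == 0,
             weakly_identified = weak, n_trials_used = n_used)
}

#' Fit every participant of a dataset
#'
#' Convenience wrappers applying [fit_hyperbolic()] or [fit_mle()]
#' per participant; participants whose data do not meet the
#' preconditions are returned with `NA` estimates and a warning count.
#'
#' @param trials a long-format trial data frame.
#' @param design a [task_design()].
#' @param ... passed to the per-participant fitter.
#' @return A data frame with one row per participant.
#' @export
fit_mle_cohort <- function(trials, design = task_design(), ...) {
  parts <- split(trials, trials$participant_id)
  rows <- lapply(names(parts), function(id) {
    tryCatch(fit_mle(parts[[id]], design, ...),
             error = function(e)
               data.frame(participant_id = id, k = NA_real_,
                          log_k = NA_real_, V = NA_real_, sigma = NA_real_,
                          loglik = NA_real_, converged = FALSE,
                          weakly_identified = NA, n_trials_used = 0L))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' @rdname fit_mle_cohort
#' @param profiles a profile data frame from [discount_profile()].
#' @export
fit_hyperbolic_cohort <- function(profiles, ...) {
  parts <- split(profiles, profiles$participant_id)
  rows <- lapply(names(parts), function(id) {
    tryCatch(fit_hyperbolic(parts[[id]], ...),
             error = function(e)
               data.frame(participant_id = id, k = NA_real_,
                          log_k = NA_real_, V = NA_real_, sse = NA_real_,
                          converged = FALSE, flat = NA, n_points = 0L))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
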