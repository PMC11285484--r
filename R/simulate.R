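#' Probability of the selfish choice under the softmax rule
#'
#' The generous option is valued at `generous_amount + V / (1 + k * D)`
#' (the participant's own 130 HKD plus the discounted premium of sharing);
#' the selfish option is valued at its face amount. The selfish choice
#' probability is the logistic function of `sigma` times the value
#' difference.
#'
#' @param agent an [agent_params()].
#' @param distance social distance(s) `D`.
#' @param selfish_amount selfish payoff(s) in HKD.
#' @param design a [task_design()]; supplies the generous amount.
#' @return Probability (vector) of choosing the selfish option, in (0, 1).
#' @examples
#' choice_probability(agent_params(k = 0.1, V = 170, sigma = 0.05), 10, 290)
#' @export
choice_probability <- function(agent, distance, selfish_amount,
                               design = task_design()) {
  stopifnot(inherits(agent, "agent_params"))
  value_generous <- design$generous_amount +
    agent$V / (1 + agent$k * distance)
  stats::plogis(agent$sigma * (selfish_amount - value_generous))
}

#' Simulate a single drift-diffusion trial
#'
#' Euler-Maruyama walk starting at `beta * alpha` with drift `delta` and
#' unit diffusion, absorbed at 0 (lower) or `alpha` (upper); the reported
#' response time is the hitting time plus the non-decision time `tau`.
#' A Brownian-bridge crossing check within each step corrects most of the
#' discretization bias of the plain Euler scheme.
#'
#' @param ddm a [ddm_params()].
#' @param seed integer seed (required).
#' @param n number of trials.
#' @param dt Euler step in seconds.
#' @param t_max maximum decision time before the walk is abandoned
#'   (boundary reported as `NA`).
#' @param bridge logical; apply the bridge crossing correction.
#' @return A data frame with columns `boundary` (`"upper"`, `"lower"`, or
#'   `NA`) and `rt` (seconds).
#' @export
simulate_ddm_trial <- function(ddm, seed, n = 1, dt = 0.001, t_max = 30,
                               bridge = TRUE) {
  stopifnot(inherits(ddm, "ddm_params"))
  if (missing(seed) || is.null(seed))
    stop("a seed is required for stochastic simulation")
  if (dt <= 0) stop("step size must be positive")
  sim <- with_preserved_seed(seed,
    .ddm_sim_cpp(as.integer(n), ddm$alpha, ddm$beta, ddm$delta, ddm$tau,
                 dt, t_max, bridge))
  data.frame(
    boundary = c("lower", "upper")[sim$boundary + 1L],
    rt = sim$rt)
}

# boundary convention shared by the generator and the hierarchical fit:
# the upper boundary is the selfish choice
.upper_boundary_choice <- "selfish"

# draw one (choice, rt) pair per grid row according to the generator mode;
# RNG state is managed by the caller
.simulate_records <- function(agent, ddm, grid, design, mode, dt) {
  n <- nrow(grid)
  if (mode == "softmax") {
    p <- choice_probability(agent, grid$distance, grid$selfish_amount,
                            design)
    choice <- ifelse(stats::runif(n) < p, "selfish", "generous")
    return(data.frame(distance = grid$distance,
                      selfish_amount = grid$selfish_amount,
                      choice = choice, rt = NA_real_))
  }
  sim <- .ddm_sim_cpp(n, ddm$alpha, ddm$beta, ddm$delta, ddm$tau, dt, 30,
                      TRUE)
  up <- sim$boundary == 1L
  choice <- ifelse(is.na(sim$boundary), "skipped",
                   ifelse(up, .upper_boundary_choice, "generous"))
  rt <- sim$rt
  if (mode == "hybrid") {
    # choices from the softmax agent; diffusion rts conditioned on the
    # matching boundary by rejection (bounded number of redraws)
    p <- choice_probability(agent, grid$distance, grid$selfish_amount,
                            design)
    want_selfish <- stats::runif(n) < p
    for (i in seq_len(n)) {
      tries <- 0
      while (!is.na(sim$boundary[i]) &&
             (sim$boundary[i] == 1L) != want_selfish[i] && tries < 50) {
        s1 <- .ddm_sim_cpp(1L, ddm$alpha, ddm$beta, ddm$delta, ddm$tau, dt,
                           30, TRUE)
        sim$boundary[i] <- s1$boundary
        sim$rt[i] <- s1$rt
        tries <- tries + 1
      }
    }
    choice <- ifelse(is.na(sim$boundary), "skipped",
                     ifelse(want_selfish, "selfish", "generous"))
    rt <- sim$rt
  }
  rt[choice == "skipped"] <- NA_real_
  data.frame(distance = grid$distance, selfish_amount = grid$selfish_amount,
             choice = choice, rt = rt)
}

#' Simulate one participant's session
#'
#' One record per trial-grid pair, in randomized block order. Three
#' generator modes are available:
#' \describe{
#'   \item{`"ddm"`}{(default when `ddm` is supplied) choices and response
#'     times jointly from the diffusion process; the sampled boundary
#'     determines the choice (upper = selfish).}
#'   \item{`"softmax"`}{choice-only simulation: Bernoulli choices from
#'     [choice_probability()], no response times.}
#'   \item{`"hybrid"`}{choices from the softmax agent; response times from
#'     the diffusion conditioned on the matching boundary.}
#' }
#' Trials whose diffusion run exceeds the response window are skipped and
#' re-presented once at the end of their distance block; a twice-skipped
#' trial is recorded as `"skipped"` with a missing response time.
#'
#' @param agent an [agent_params()].
#' @param ddm a [ddm_params()] or `NULL` for choice-only simulation.
#' @param design a [task_design()].
#' @param seed integer seed (required).
#' @param mode generator mode, see Details.
#' @param participant_id identifier stored in the records.
#' @param sex,condition group labels stored in the records.
#' @param fast_guess_rate,skip_rate contamination rates (see
#'   [cohort_truth()]).
#' @param dt Euler step for diffusion simulation (seconds).
#' @return A data frame of trial records: `participant_id`, `sex`,
#'   `condition`, `distance`, `selfish_amount`, `choice`, `rt`.
#' @export
simulate_participant <- function(agent, ddm = NULL, design = task_design(),
                                 seed,
                                 mode = if (is.null(ddm)) "softmax"
                                        else "ddm",
                                 participant_id = "P001",
                                 sex = "female", condition = "control",
                                 fast_guess_rate = 0, skip_rate = 0,
                                 dt = 0.001) {
  stopifnot(inherits(agent, "agent_params"))
  mode <- match.arg(mode, c("softmax", "ddm", "hybrid"))
  if (mode != "softmax" && !inherits(ddm, "ddm_params"))
    stop("modes 'ddm' and 'hybrid' require ddm parameters")
  if (missing(seed) || is.null(seed))
    stop("a seed is required for stochastic simulation")
  with_preserved_seed(seed, {
    grid <- build_trial_grid(design, seed = stats::runif(1, 1, 2^30))
    rec <- .simulate_records(agent, ddm, grid, design, mode, dt)

    # response-window timeouts and injected skips -> skipped, re-presented
    # once at end of the distance block; twice-skipped trials stay skipped
    n <- nrow(rec)
    skip1 <- (!is.na(rec$rt) & rec$rt > design$response_window)
    if (skip_rate > 0)
      skip1 <- skip1 | stats::runif(n) < skip_rate
    skip1 <- skip1 | rec$choice == "skipped"
    if (any(skip1)) {
      redo <- grid[skip1, , drop = FALSE]
      rec2 <- .simulate_records(agent, ddm, redo, design, mode, dt)
      again <- (!is.na(rec2$rt) & rec2$rt > design$response_window) |
        rec2$choice == "skipped"
      if (skip_rate > 0)
        again <- again | stats::runif(nrow(rec2)) < skip_rate
      rec2$choice[again] <- "skipped"
      rec2$rt[again] <- NA_real_
      rec[skip1, c("choice", "rt")] <- rec2[, c("choice", "rt")]
      # move re-presented trials to the end of their distance block
      ord <- order(match(rec$distance, unique(rec$distance)), skip1)
      rec <- rec[ord, , drop = FALSE]
    }

    # fast-guess contamination on scored trials
    scored <- rec$choice != "skipped"
    if (fast_guess_rate > 0 && any(scored)) {
      fg <- scored & stats::runif(n) < fast_guess_rate
      nfg <- sum(fg)
      if (nfg > 0) {
        rec$choice[fg] <- ifelse(stats::runif(nfg) < 0.5, "selfish",
                                 "generous")
        rec$rt[fg] <- stats::runif(nfg, 0.05, design$rt_floor)
      }
    }
    rec$rt[!is.na(rec$rt)] <- round(rec$rt[!is.na(rec$rt)], 3)
    data.frame(participant_id = participant_id, sex = sex,
               condition = condition, rec, row.names = NULL)
  })
}

# draw one participant's parameters around the cell means; dispersion acts
# on the modelling scale of each parameter
.draw_participant_params <- function(cell, disp) {
  ag <- cell$agent; dd <- cell$ddm
  rl <- function(m, s) if (s > 0) stats::rlnorm(1, log(m), s) else m
  agent <- agent_params(
    k = rl(max(ag$k, 1e-8), disp$k),
    V = rl(max(ag$V, 1e-8), disp$V),
    sigma = rl(max(ag$sigma, 1e-8), disp$sigma))
  beta <- stats::plogis(stats::qlogis(dd$beta) +
                          stats::rnorm(1, 0, disp$beta))
  ddm <- ddm_params(
    alpha = rl(dd$alpha, disp$alpha),
    beta = min(max(beta, 1e-4), 1 - 1e-4),
    delta = dd$delta + stats::rnorm(1, 0, disp$delta),
    tau = max(0.1, rl(dd$tau, disp$tau)))
  list(agent = agent, ddm = ddm)
}

#' Simulate a full sex-by-condition cohort
#'
#' Generates `n_per_cell` participants for each of the four sex-by-condition
#' cells, each with parameters drawn around the cell means of `truth`, and
#' simulates their sessions with [simulate_participant()], including
#' fast-guess and skipped-trial contamination.
#'
#' @param truth a [cohort_truth()].
#' @param design a [task_design()].
#' @param seed integer seed; defaults to `truth$seed`.
#' @param mode generator mode passed to [simulate_participant()].
#' @return A long-format data frame of trial records (class
#'   `choice_dataset`), with the drawn per-participant true parameters in
#'   `attr(, "truth_params")`.
#' @export
simulate_cohort <- function(truth, design = task_design(),
                            seed = truth$seed, mode = "ddm") {
  stopifnot(inherits(truth, "cohort_truth"))
  if (is.null(seed))
    stop("a seed is required for stochastic simulation")
  mode <- match.arg(mode, c("softmax", "ddm", "hybrid"))
  with_preserved_seed(seed, {
    cells <- names(truth$cells)
    out <- vector("list", 4L * truth$n_per_cell)
    pars <- vector("list", 4L * truth$n_per_cell)
    idx <- 0L
    pid <- 0L
    for (cl in cells) {
      sex <- sub("_.*$", "", cl)
      condition <- sub("^[^_]*_", "", cl)
      for (i in seq_len(truth$n_per_cell)) {
        idx <- idx + 1L
        pid <- pid + 1L
        pp <- .draw_participant_params(truth$cells[[cl]], truth$dispersion)
        id <- sprintf("P%03d", pid)
        out[[idx]] <- simulate_participant(
          pp$agent, pp$ddm, design,
          seed = stats::runif(1, 1, 2^30), mode = mode,
          participant_id = id, sex = sex, condition = condition,
          fast_guess_rate = truth$fast_guess_rate,
          skip_rate = truth$skip_rate)
        pars[[idx]] <- data.frame(
          participant_id = id, sex = sex, condition = condition,
          k = pp$agent$k, V = pp$agent$V, sigma = pp$agent$sigma,
          alpha = pp$ddm$alpha, beta = pp$ddm$beta, delta = pp$ddm$delta,
          tau = pp$ddm$tau)
      }
    }
    ds <- do.call(rbind, out)
    class(ds) <- c("choice_dataset", "data.frame")
    attr(ds, "truth_params") <- do.call(rbind, pars)
    ds
  })
}
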