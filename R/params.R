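#' Softmax discounting agent parameters
#'
#' Ground-truth parameters of a choice agent that values the generous
#' option at `generous_amount + V / (1 + k * D)` and chooses by a softmax
#' over the value difference.
#'
#' @param k hyperbolic discount rate per unit social distance (>= 0).
#' @param V generosity intercept in HKD: the premium placed on sharing at
#'   zero social distance (>= 0).
#' @param sigma softmax inverse temperature per HKD (>= 0); 0 means
#'   value-blind coin-flip choices.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(k = 0.2, V = 280, sigma = 0.05) {
  stopifnot(is.finite(k), is.finite(V), is.finite(sigma),
            k >= 0, V >= 0, sigma >= 0)
  structure(list(k = k, V = V, sigma = sigma), class = "agent_params")
}

#' Drift-diffusion process parameters
#'
#' @param alpha boundary separation (evidence units, > 0).
#' @param beta starting-point bias as a fraction of `alpha`, in (0, 1);
#'   0.5 is unbiased.
#' @param delta drift rate (evidence units per second); positive drifts
#'   toward the upper (selfish) boundary.
#' @param tau non-decision time in seconds (>= 0.1, the global reaction
#'   time floor).
#' @return An object of class `ddm_params`.
#' @export
ddm_params <- function(alpha = 1.6, beta = 0.5, delta = 0.25, tau = 0.35) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(delta),
            is.finite(tau), alpha > 0, beta > 0, beta < 1, tau >= 0.1)
  structure(list(alpha = alpha, beta = beta, delta = delta, tau = tau),
            class = "ddm_params")
}

#' Ground truth for a simulated cohort
#'
#' Defines the four sex-by-condition cells of a between-subject cohort:
#' per-cell mean agent and diffusion parameters, between-participant
#' dispersions, and the contamination rates the generator injects
#' (fast guesses below the reaction-time floor, skipped trials).
#'
#' Dispersions act on the scale on which each parameter is modelled:
#' log-normal for the positive parameters (`k`, `V`, `sigma`, `alpha`,
#' `tau`), logit-normal for `beta`, normal for `delta`. Default cell means
#' are shared across cells (a null cohort, no sex or condition effects) and
#' sized to the magnitudes typical of this task: `k = 0.2`, `V = 280` HKD,
#' `sigma = 0.05` per HKD; `alpha = 1.6`, `beta = 0.5`, `delta = 0.25`,
#' `tau = 0.35` s.
#'
#' @param n_per_cell participants per sex-by-condition cell (>= 1).
#' @param cells named list with elements `female_control`,
#'   `female_androstadienone`, `male_control`, `male_androstadienone`, each
#'   a list with components `agent` ([agent_params()]) and `ddm`
#'   ([ddm_params()]). Defaults to identical cells built from `agent` and
#'   `ddm`.
#' @param agent,ddm cell means used when `cells` is `NULL`.
#' @param dispersion named list of between-participant dispersions
#'   (`k`, `V`, `sigma`, `alpha`, `tau` as log-scale sds; `beta` as a
#'   logit-scale sd; `delta` as an sd).
#' @param fast_guess_rate fraction of scored trials replaced by fast
#'   guesses (random choice, rt below the floor), in \[0, 1).
#' @param skip_rate per-presentation probability that a trial is skipped,
#'   in \[0, 1).
#' @param seed default seed used by [simulate_cohort()].
#' @return An object of class `cohort_truth`.
#' @export
cohort_truth <- function(n_per_cell = 10,
                         cells = NULL,
                         agent = agent_params(),
                         ddm = ddm_params(),
                         dispersion = list(k = 0.3, V = 0.3, sigma = 0.3,
                                           alpha = 0.3, beta = 0.3,
                                           delta = 0.3, tau = 0.2),
                         fast_guess_rate = 0.02,
                         skip_rate = 0.01,
                         seed = NULL) {
  stopifnot(n_per_cell >= 1,
            fast_guess_rate >= 0, fast_guess_rate < 1,
            skip_rate >= 0, skip_rate < 1)
  if (any(unlist(dispersion) < 0)) stop("dispersions must be >= 0")
  cell_names <- c("female_control", "female_androstadienone",
                  "male_control", "male_androstadienone")
  if (is.null(cells)) {
    cells <- stats::setNames(
      rep(list(list(agent = agent, ddm = ddm)), 4L), cell_names)
  }
  if (!setequal(names(cells), cell_names))
    stop("cells must be named: ", paste(cell_names, collapse = ", "))
  for (cl in cells) {
    stopifnot(inherits(cl$agent, "agent_params"),
              inherits(cl$ddm, "ddm_params"))
  }
  structure(
    list(n_per_cell = as.integer(n_per_cell), cells = cells[cell_names],
         dispersion = dispersion, fast_guess_rate = fast_guess_rate,
         skip_rate = skip_rate, seed = seed),
    class = "cohort_truth")
}
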