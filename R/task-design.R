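#' Social discounting task design
#'
#' Describes the trial grid and task constants of a social discounting
#' experiment: the social distances at which a partner is placed, the range
#' of selfish payoffs offered against a fixed generous payoff shared with
#' the partner, response timing, and payout rules. Defaults reproduce the
#' standard design: distances 1, 2, 3, 5, 10, 20, 50, 100; selfish amounts
#' 130 to 290 HKD in steps of 20; generous amount 130 HKD to each party;
#' a 6 s response window, 1 s inter-trial interval, a 0.3 s fast-guess
#' floor, a 105 HKD flat fee and a 5% payout of the chosen amount.
#'
#' @param distances strictly increasing integer social distances, all >= 1.
#' @param selfish_amounts strictly increasing selfish payoffs (HKD); the
#'   smallest must be at least `generous_amount`.
#' @param generous_amount fixed generous payoff (HKD) received by both the
#'   participant and the partner.
#' @param response_window maximum response time in seconds.
#' @param iti inter-trial interval in seconds.
#' @param rt_floor fast-guess threshold in seconds; responses faster than
#'   this are treated as guesses and excluded from model fits.
#' @param flat_fee show-up fee (HKD).
#' @param payout_rate fraction of the chosen amount paid out, in (0, 1).
#' @return An object of class `task_design`.
#' @examples
#' d <- task_design()
#' nrow(build_trial_grid(d))  # 72
#' @export
task_design <- function(distances = c(1, 2, 3, 5, 10, 20, 50, 100),
                        selfish_amounts = seq(130, 290, by = 20),
                        generous_amount = 130,
                        response_window = 6,
                        iti = 1,
                        rt_floor = 0.3,
                        flat_fee = 105,
                        payout_rate = 0.05) {
  if (length(distances) < 1L || length(selfish_amounts) < 1L)
    stop("distances and selfish_amounts must be non-empty")
  if (any(distances < 1) || any(diff(distances) <= 0))
    stop("distances must be strictly increasing and >= 1")
  if (any(diff(selfish_amounts) <= 0))
    stop("selfish_amounts must be strictly increasing")
  if (min(selfish_amounts) < generous_amount)
    stop("smallest selfish amount must be >= generous_amount")
  if (!(rt_floor < response_window))
    stop("rt_floor must be smaller than response_window")
  if (!(payout_rate > 0 && payout_rate < 1))
    stop("payout_rate must lie in (0, 1)")
  structure(
    list(distances = as.numeric(distances),
         selfish_amounts = as.numeric(selfish_amounts),
         generous_amount = as.numeric(generous_amount),
         response_window = as.numeric(response_window),
         iti = as.numeric(iti),
         rt_floor = as.numeric(rt_floor),
         flat_fee = as.numeric(flat_fee),
         payout_rate = as.numeric(payout_rate)),
    class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat("Social discounting task design\n")
  cat("  distances      :", paste(x$distances, collapse = ", "), "\n")
  cat("  selfish amounts:", paste(x$selfish_amounts, collapse = ", "),
      "HKD\n")
  cat("  generous amount:", x$generous_amount, "HKD (to each party)\n")
  cat(sprintf("  response window: %g s, ITI %g s, fast-guess floor %g s\n",
              x$response_window, x$iti, x$rt_floor))
  cat(sprintf("  payout: %g HKD flat + %g%% of the chosen amount\n",
              x$flat_fee, 100 * x$payout_rate))
  invisible(x)
}

#' Build the full factorial trial grid
#'
#' Every combination of social distance and selfish amount appears exactly
#' once. Without a seed, trials are returned ordered by distance block and
#' amount; with a seed, the block order and the trial order within each
#' distance block are randomized (the design's randomization scheme).
#'
#' @param design a [task_design()].
#' @param seed optional integer seed controlling randomization.
#' @return A data frame with columns `distance` and `selfish_amount`, one
#'   row per unique trial.
#' @export
build_trial_grid <- function(design, seed = NULL) {
  stopifnot(inherits(design, "task_design"))
  grid <- expand.grid(selfish_amount = design$selfish_amounts,
                      distance = design$distances,
                      KEEP.OUT.ATTRS = FALSE)[, c("distance",
                                                  "selfish_amount")]
  if (!is.null(seed)) {
    grid <- with_preserved_seed(seed, {
      blocks <- split(grid, grid$distance)
      blocks <- blocks[sample(length(blocks))]
      blocks <- lapply(blocks, function(b) b[sample(nrow(b)), , drop = FALSE])
      do.call(rbind, blocks)
    })
  }
  rownames(grid) <- NULL
  grid
}

#' Payout for a chosen amount
#'
#' Total compensation: the flat fee plus the payout fraction of the amount
#' chosen on the randomly selected trial. The minimum possible payout is
#' attained when the generous option was chosen on the selected trial.
#'
#' @param design a [task_design()].
#' @param chosen_amount the participant's payoff on the selected trial (HKD).
#' @return Payout in HKD.
#' @examples
#' payout(task_design(), 130)  # 111.5
#' @export
payout <- function(design, chosen_amount) {
  stopifnot(inherits(design, "task_design"), chosen_amount >= 0)
  design$flat_fee + design$payout_rate * chosen_amount
}

#' @rdname payout
#' @export
min_payout <- function(design) {
  payout(design, design$generous_amount)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user state.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required for stochastic simulation")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
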