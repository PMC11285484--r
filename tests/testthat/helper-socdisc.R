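# shared fixtures, built in code

default_design <- task_design()

# a small null cohort used by several suites
small_cohort <- function(n_per_cell = 3, seed = 101, mode = "hybrid",
                         ...) {
  simulate_cohort(cohort_truth(n_per_cell = n_per_cell, ...),
                  design = default_design, seed = seed, mode = mode)
}

# one participant's choices generated from the softmax agent (no rt)
softmax_trials <- function(agent, seed, design = default_design) {
  simulate_participant(agent, ddm = NULL, design = design, seed = seed)
}

# profile data frame from a forgone-by-distance vector
profile_from_forgone <- function(forgone,
                                 distances = default_design$distances,
                                 id = "P001") {
  data.frame(participant_id = id, distance = distances,
             indifference_point = forgone + 130,
             amount_forgone = forgone, method = "logistic")
}

# balanced two-way ANOVA decomposition from cell-mean closed forms
balanced_anova_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- table(a, b)[1, 1]          # equal cell size assumed
  gm <- mean(y)
  am <- tapply(y, a, mean); bm <- tapply(y, b, mean)
  cm <- tapply(y, list(a, b), mean)
  ss_a <- n * nlevels(b) * sum((am - gm)^2)
  ss_b <- n * nlevels(a) * sum((bm - gm)^2)
  ss_ab <- n * sum((cm - outer(am - gm, bm - gm, "+") - gm)^2)
  ss_err <- sum((y - cm[cbind(a, b)])^2)
  list(ss = c(ss_a, ss_b, ss_ab, ss_err),
       df = c(nlevels(a) - 1, nlevels(b) - 1,
              (nlevels(a) - 1) * (nlevels(b) - 1),
              length(y) - nlevels(a) * nlevels(b)))
}
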