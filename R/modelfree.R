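#' Indifference point at one social distance
#'
#' Estimates the selfish amount at which the participant is equally likely
#' to choose either option, from that participant's scored choices at one
#' social distance. Exclusive choosers are imputed half an increment
#' outside the offered range (120 and 300 HKD under the default design):
#' all-selfish responders get the low imputation (they would need even less
#' to defect), all-generous responders the high one. Perfectly separated
#' mixed responses (every generous choice below every selfish choice) take
#' the midpoint of the separating gap, since the logistic likelihood
#' diverges there. Otherwise a logistic regression of choice on amount is
#' fitted and the indifference point is `-intercept/slope`, clipped to the
#' imputation range.
#'
#' @param choices character vector of `"selfish"`/`"generous"` (skipped
#'   trials must be removed upstream).
#' @param amounts selfish amounts (HKD) offered on those trials.
#' @param design a [task_design()]; supplies the imputation bounds.
#' @return A list with `indifference_point` (HKD) and `method`, one of
#'   `"logistic"`, `"imputed_low"`, `"imputed_high"`,
#'   `"separation_midpoint"`.
#' @export
fit_indifference_point <- function(choices, amounts,
                                   design = task_design()) {
  if (length(choices) == 0L)
    return(list(indifference_point = NA_real_, method = "no_data"))
  stopifnot(length(choices) == length(amounts),
            all(choices %in% c("selfish", "generous")))
  step <- if (length(design$selfish_amounts) > 1)
    min(diff(design$selfish_amounts)) else 20
  lo <- min(design$selfish_amounts) - step / 2
  hi <- max(design$selfish_amounts) + step / 2
  sel <- choices == "selfish"
  if (all(sel))
    return(list(indifference_point = lo, method = "imputed_low"))
  if (!any(sel))
    return(list(indifference_point = hi, method = "imputed_high"))
  max_gen <- max(amounts[!sel])
  min_sel <- min(amounts[sel])
  if (max_gen < min_sel)
    return(list(indifference_point = (max_gen + min_sel) / 2,
                method = "separation_midpoint"))
  fit <- suppressWarnings(
    stats::glm(sel ~ amounts, family = stats::binomial()))
  co <- stats::coef(fit)
  ip <- -co[[1]] / co[[2]]
  if (!is.finite(ip) || co[[2]] <= 0) {
    # degenerate or reversed response curve: fall back on the majority
    ip <- if (mean(sel) > 0.5) lo else hi
  }
  list(indifference_point = min(max(ip, lo), hi), method = "logistic")
}

#' Amount forgone from an indifference point
#'
#' The cost the participant accepts to be generous: the indifference point
#' minus the generous amount (130 HKD by default). An all-selfish
#' (low-imputed) participant has a forgone amount of -10 HKD, retained as
#' is; clipping to zero happens only inside the AUC normalization.
#'
#' @param indifference_point indifference point(s) in HKD; must lie in the
#'   imputation range of the design.
#' @param design a [task_design()].
#' @return Amount forgone in HKD.
#' @export
amount_forgone <- function(indifference_point, design = task_design()) {
  step <- if (length(design$selfish_amounts) > 1)
    min(diff(design$selfish_amounts)) else 20
  lo <- min(design$selfish_amounts) - step / 2
  hi <- max(design$selfish_amounts) + step / 2
  ok <- is.na(indifference_point) |
    (indifference_point >= lo & indifference_point <= hi)
  if (!all(ok))
    stop("indifference point outside [", lo, ", ", hi, "]")
  indifference_point - design$generous_amount
}

#' Per-participant discounting profiles
#'
#' Applies [fit_indifference_point()] at every social distance for every
#' participant of a long-format trial table. Skipped trials are excluded.
#'
#' @param trials a trial data frame (see [read_trials()] for the schema).
#' @param design a [task_design()].
#' @return A data frame with columns `participant_id`, `distance`,
#'   `indifference_point`, `amount_forgone`, `method`.
#' @export
discount_profile <- function(trials, design = task_design()) {
  scored <- trials[trials$choice != "skipped", , drop = FALSE]
  parts <- split(scored, scored$participant_id)
  out <- lapply(names(parts), function(id) {
    byd <- split(parts[[id]], parts[[id]]$distance)
    rows <- lapply(byd, function(tr) {
      f <- fit_indifference_point(tr$choice, tr$selfish_amount, design)
      data.frame(participant_id = id, distance = tr$distance[1],
                 indifference_point = f$indifference_point,
                 amount_forgone = amount_forgone(f$indifference_point,
                                                 design),
                 method = f$method)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$participant_id, res$distance), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Normalized area under the discounting curve
#'
#' Model-free prosociality index. Amounts forgone are clipped below at
#' zero and normalized by the theoretical maximum forgone (the high
#' imputation minus the generous amount, 170 HKD by default); distances
#' are normalized by the largest distance. An anchor at distance 0
#' carrying the smallest-distance value is prepended so a flat
#' no-discounting profile attains exactly 1, and the trapezoids between
#' successive normalized points are summed. The result lies in \[0, 1\]:
#' 0 is complete discounting, 1 no discounting.
#'
#' @param profile a profile data frame from [discount_profile()] (one or
#'   many participants).
#' @param design a [task_design()].
#' @return A data frame with `participant_id`, `auc`, `n_distances_used`.
#' @export
compute_auc <- function(profile, design = task_design()) {
  step <- if (length(design$selfish_amounts) > 1)
    min(diff(design$selfish_amounts)) else 20
  y_max <- max(design$selfish_amounts) + step / 2 - design$generous_amount
  x_max <- max(design$distances)
  parts <- split(profile, profile$participant_id)
  rows <- lapply(names(parts), function(id) {
    pr <- parts[[id]]
    pr <- pr[is.finite(pr$amount_forgone), , drop = FALSE]
    pr <- pr[order(pr$distance), , drop = FALSE]
    if (nrow(pr) < 2)
      stop("compute_auc needs at least 2 distances (participant ", id, ")")
    y <- pmax(pr$amount_forgone, 0) / y_max
    x <- pr$distance / x_max
    x <- c(0, x)
    y <- c(y[1], y)
    auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    data.frame(participant_id = id, auc = auc, n_distances_used = nrow(pr))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
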