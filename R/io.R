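.trial_columns <- c("participant_id", "sex", "condition", "distance",
                    "selfish_amount", "choice", "rt")

#' Read a long-format trial table
#'
#' Reads and validates a trials CSV (one row per trial, header
#' `participant_id,sex,condition,distance,selfish_amount,choice,rt`;
#' missing response times encoded as empty fields). Category vocabularies
#' are checked and malformed rows are rejected with their line numbers.
#' A response time must be present exactly when the trial was not
#' skipped (files with no response times at all — choice-only
#' simulations — are accepted).
#'
#' @param path CSV file path.
#' @return A validated trial data frame (class `choice_dataset`).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(participant_id = "character",
                                      sex = "character",
                                      condition = "character",
                                      distance = "numeric",
                                      selfish_amount = "numeric",
                                      choice = "character",
                                      rt = "numeric"))
  if (!identical(names(d), .trial_columns))
    stop("header must be: ", paste(.trial_columns, collapse = ","))
  line <- seq_len(nrow(d)) + 1L  # header is line 1
  bad <- function(mask, what) {
    if (any(mask))
      stop(what, " at line ", paste(line[mask][1:min(5, sum(mask))],
                                    collapse = ", "),
           if (sum(mask) > 5) " (and more)" else "")
  }
  bad(!d$sex %in% c("female", "male"), "unknown sex label")
  bad(!d$condition %in% c("control", "androstadienone"),
      "unknown condition label")
  bad(!d$choice %in% c("selfish", "generous", "skipped"),
      "unknown choice label")
  bad(is.na(d$distance) | d$distance < 1, "invalid distance")
  bad(is.na(d$selfish_amount), "invalid selfish amount")
  bad(d$choice == "skipped" & !is.na(d$rt),
      "response time recorded on a skipped trial")
  bad(d$choice != "skipped" & !is.na(d$rt) & d$rt <= 0,
      "non-positive response time")
  # scored trials carry a response time, except in a uniformly
  # choice-only file (softmax-mode simulation)
  scored <- d$choice != "skipped"
  if (any(!is.na(d$rt[scored])))
    bad(scored & is.na(d$rt), "missing response time on a scored trial")
  class(d) <- c("choice_dataset", "data.frame")
  d
}

#' Write a long-format trial table
#'
#' @param trials a trial data frame.
#' @param path output CSV path. Response times are written with 3
#'   decimals, missing ones as empty fields.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(.trial_columns %in% names(trials)))
  d <- as.data.frame(trials)[, .trial_columns]
  d$rt <- ifelse(is.na(d$rt), "", sprintf("%.3f", d$rt))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the simulation ground truth sidecar
#'
#' Serializes a [cohort_truth()] (and the per-participant drawn
#' parameters, if supplied) as YAML so that recovery analyses can be run
#' against the generating values.
#'
#' @param truth a [cohort_truth()].
#' @param path YAML file path.
#' @param truth_params optional per-participant parameter data frame
#'   (the `truth_params` attribute of [simulate_cohort()] output).
#' @return `path` invisibly (write); a list (read).
#' @export
write_truth <- function(truth, path, truth_params = NULL) {
  stopifnot(inherits(truth, "cohort_truth"))
  obj <- list(
    n_per_cell = truth$n_per_cell,
    cells = lapply(truth$cells, function(cl)
      list(agent = unclass(cl$agent), ddm = unclass(cl$ddm))),
    dispersion = truth$dispersion,
    fast_guess_rate = truth$fast_guess_rate,
    skip_rate = truth$skip_rate,
    seed = truth$seed)
  if (!is.null(truth_params))
    obj$participants <- lapply(split(truth_params,
                                     truth_params$participant_id),
                               function(r) as.list(r[1, ]))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  yaml::read_yaml(path)
}
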