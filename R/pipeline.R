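#' Pipeline configuration
#'
#' Bundles everything a full reproducible run needs: the task design, the
#' simulation ground truth (or a CSV of real trials to ingest), the
#' fast-guess floor, MCMC settings for the optional hierarchical
#' drift-diffusion stage, and the mandatory seed.
#'
#' @param seed integer seed; required before any stochastic stage runs.
#' @param design a [task_design()].
#' @param truth a [cohort_truth()] for simulation, or `NULL` when
#'   `trials_path` is given.
#' @param trials_path optional CSV of observed trials (skips simulation).
#' @param mode generator mode for the simulate stage.
#' @param rt_floor fast-guess threshold (seconds).
#' @param ddm logical; run the hierarchical drift-diffusion stage.
#' @param mcmc list of MCMC settings (`chains`, `iter`, `warmup`).
#' @param out_dir optional directory to write stage artifacts into.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            design = task_design(),
                            truth = cohort_truth(),
                            trials_path = NULL,
                            mode = "hybrid",
                            rt_floor = design$rt_floor,
                            ddm = FALSE,
                            mcmc = list(chains = 4, iter = 1000,
                                        warmup = 500),
                            out_dir = NULL) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required before any stochastic stage runs")
  stopifnot(inherits(design, "task_design"), rt_floor >= 0)
  structure(list(seed = as.integer(seed), design = design, truth = truth,
                 trials_path = trials_path, mode = mode,
                 rt_floor = rt_floor, ddm = ddm, mcmc = mcmc,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a cohort, estimates the model-free profiles and
#' AUC, fits the hyperbolic function and the trial-level MLE per
#' participant, runs the sex-by-condition ANOVAs on AUC, log k and V, and
#' optionally fits the hierarchical drift-diffusion model. Returns a run
#' report with a cell-wise summary (mean and sd of AUC, k, V and their
#' MLE counterparts by sex and condition) and per-stage records. Two runs
#' with the same configuration and seed produce identical reports.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  stages <- list()
  warn <- character()

  # --- stage: simulate or ingest -------------------------------------
  if (!is.null(config$trials_path)) {
    trials <- read_trials(config$trials_path)
    stages$ingest <- list(input = config$trials_path,
                          n_trials = nrow(trials))
  } else {
    if (is.null(config$truth)) stop("stage simulate: no truth supplied")
    trials <- simulate_cohort(config$truth, design, seed = config$seed,
                              mode = config$mode)
    stages$simulate <- list(
      n_participants = length(unique(trials$participant_id)),
      n_trials = nrow(trials), mode = config$mode, seed = config$seed)
  }
  n_fast <- sum(!is.na(trials$rt) & trials$rt < config$rt_floor)
  n_skip <- sum(trials$choice == "skipped")
  stages$filter <- list(rt_floor = config$rt_floor,
                        n_fast_guess = n_fast, n_skipped = n_skip)

  # --- stage: model-free ---------------------------------------------
  profiles <- discount_profile(trials, design)
  auc <- compute_auc(profiles, design)
  stages$modelfree <- list(n_profiles = nrow(profiles),
                           n_auc = nrow(auc))

  # --- stage: model-based fits ---------------------------------------
  hyp <- fit_hyperbolic_cohort(profiles)
  mle <- fit_mle_cohort(trials, design, rt_floor = config$rt_floor)
  if (any(!mle$converged, na.rm = TRUE))
    warn <- c(warn, sprintf("%d MLE fits did not converge",
                            sum(!mle$converged, na.rm = TRUE)))
  stages$fits <- list(n_hyperbolic = nrow(hyp), n_mle = nrow(mle),
                      mle_trials_filtered = n_fast)

  # --- stage: design statistics --------------------------------------
  meta <- unique(trials[, c("participant_id", "sex", "condition")])
  tab <- merge(merge(auc, meta, by = "participant_id"),
               stats::setNames(mle[, c("participant_id", "k", "log_k",
                                       "V")],
                               c("participant_id", "k_mle", "log_k_mle",
                                 "V_mle")),
               by = "participant_id", all.x = TRUE)
  tab <- merge(tab, hyp[, c("participant_id", "k", "V")],
               by = "participant_id", all.x = TRUE)
  anovas <- list(
    auc = two_way_anova(tab$auc, tab$sex, tab$condition),
    log_k_mle = two_way_anova(tab$log_k_mle, tab$sex, tab$condition),
    V_mle = two_way_anova(tab$V_mle, tab$sex, tab$condition))
  stages$anova <- list(responses = names(anovas))

  # --- stage: hierarchical DDM (optional) ----------------------------
  ddm_fit <- NULL
  if (isTRUE(config$ddm)) {
    ddm_fit <- fit_hierarchical_ddm(
      trials, chains = config$mcmc$chains, iter = config$mcmc$iter,
      warmup = config$mcmc$warmup, seed = config$seed,
      rt_floor = config$rt_floor)
    if (!ddm_fit$converged)
      warn <- c(warn, sprintf("DDM max R-hat %.3f >= 1.01",
                              max(ddm_fit$rhat)))
    stages$ddm <- list(chains = config$mcmc$chains,
                       iter = config$mcmc$iter,
                       max_rhat = max(ddm_fit$rhat),
                       converged = ddm_fit$converged)
  }

  # --- cell-wise summary table ---------------------------------------
  cell <- interaction(tab$sex, tab$condition, sep = "_")
  msd <- function(v) vapply(split(v, cell), function(x)
    c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE)),
    numeric(2))
  summary_tab <- list(AUC = msd(tab$auc), k = msd(tab$k),
                      V = msd(tab$V), k_mle = msd(tab$k_mle),
                      V_mle = msd(tab$V_mle))

  report <- structure(
    list(seed = config$seed, stages = stages, warnings = warn,
         summary = summary_tab, anova = anovas,
         auc = auc, profiles = profiles, hyperbolic = hyp, mle = mle,
         ddm = ddm_fit, participants = meta),
    class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(config$out_dir, "trials.csv"))
    utils::write.csv(profiles, file.path(config$out_dir, "profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(auc, file.path(config$out_dir, "auc.csv"),
                     row.names = FALSE)
    utils::write.csv(mle, file.path(config$out_dir, "mle.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Serializable view of a run report
#'
#' Stable summary of a [run_pipeline()] report (no timestamps), used for
#' the JSON artifact; two runs with the same seed serialize identically.
#'
#' @param report a `run_report`.
#' @return A plain list.
#' @export
report_to_list <- function(report) {
  list(seed = report$seed, stages = report$stages,
       warnings = report$warnings,
       summary = lapply(report$summary, function(m)
         as.data.frame(t(m))),
       anova = lapply(report$anova, as.data.frame))
}

#' @export
print.run_report <- function(x, ...) {
  cat("Social discounting pipeline run (seed", x$seed, ")\n")
  cat("  stages:", paste(names(x$stages), collapse = " -> "), "\n")
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  cat("\nCell summary (mean (sd)):\n")
  cells <- colnames(x$summary$AUC)
  tab <- sapply(names(x$summary), function(nm) {
    m <- x$summary[[nm]]
    sprintf("%.2f (%.2f)", m["mean", ], m["sd", ])
  })
  rownames(tab) <- cells
  print(t(tab), quote = FALSE)
  cat("\nANOVA p-values (sex, condition, interaction):\n")
  for (nm in names(x$anova)) {
    p <- x$anova[[nm]]$p[1:3]
    cat(sprintf("  %-10s %.3f  %.3f  %.3f\n", nm, p[1], p[2], p[3]))
  }
  invisible(x)
}
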