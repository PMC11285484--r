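#' Two-way between-subject ANOVA with generalized eta squared
#'
#' Type II sums of squares (safe for the unbalanced cells of a
#' between-subject cohort), with generalized eta squared computed as
#' `SS_effect / (SS_effect + SS_error)`; for a purely between-subject
#' design this coincides with partial eta squared.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b factor (or coercible) group labels.
#' @return A data frame (class `anova_table`) with one row per effect
#'   (`factor_a`, `factor_b`, interaction, residuals) and columns `ss`,
#'   `df`, `f`, `p`, `ges`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  ok <- is.finite(values) & !is.na(factor_a) & !is.na(factor_b)
  d <- data.frame(y = values[ok], a = factor(factor_a[ok]),
                  b = factor(factor_b[ok]))
  if (nlevels(d$a) < 2 || nlevels(d$b) < 2)
    stop("each factor needs at least 2 levels")
  if (any(table(d$a, d$b) < 2))
    stop("each cell needs at least 2 observations")
  if (stats::var(d$y) == 0)
    stop("constant response: F is undefined")
  mod <- stats::lm(y ~ a * b, data = d,
                   contrasts = list(a = "contr.sum", b = "contr.sum"))
  a2 <- car::Anova(mod, type = 2)
  ss_err <- a2["Residuals", "Sum Sq"]
  eff <- c("a", "b", "a:b")
  out <- data.frame(
    effect = c("factor_a", "factor_b", "interaction", "residuals"),
    ss = c(a2[eff, "Sum Sq"], ss_err),
    df = c(a2[eff, "Df"], a2["Residuals", "Df"]),
    f = c(a2[eff, "F value"], NA),
    p = c(a2[eff, "Pr(>F)"], NA),
    ges = c(a2[eff, "Sum Sq"] / (a2[eff, "Sum Sq"] + ss_err), NA))
  class(out) <- c("anova_table", "data.frame")
  out
}

#' One-sample t test with Cohen's d
#'
#' @param values numeric sample (n >= 2, nonzero variance).
#' @param mu0 null value.
#' @return A list with `t`, `df`, `p` (two-sided), `cohen_d`, `mean`, `n`.
#'   The identity `d * sqrt(n) = t` holds.
#' @export
one_sample_t <- function(values, mu0) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 observations")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance")
  t <- (mean(values) - mu0) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       cohen_d = t / sqrt(n), mean = mean(values), n = n)
}

#' A-priori power specification for a between-subject ANOVA effect
#'
#' @param effect_size_f Cohen's f (> 0).
#' @param alpha significance level, in (0, 1).
#' @param target_power desired power, in (0, 1).
#' @param numerator_df numerator degrees of freedom of the tested effect.
#' @param n_groups number of cells in the design (>= 2).
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(effect_size_f = 0.241, alpha = 0.05,
                       target_power = 0.80, numerator_df = 1,
                       n_groups = 4) {
  stopifnot(effect_size_f > 0, alpha > 0, alpha < 1,
            target_power > 0, target_power < 1,
            numerator_df >= 1, n_groups >= 2)
  structure(list(effect_size_f = effect_size_f, alpha = alpha,
                 target_power = target_power,
                 numerator_df = as.integer(numerator_df),
                 n_groups = as.integer(n_groups)),
            class = "power_spec")
}

#' Power of a between-subject ANOVA effect at a given total N
#'
#' `P(F' > F_crit)` where `F'` is noncentral F with
#' `(numerator_df, N - n_groups)` degrees of freedom and noncentrality
#' `lambda = f^2 * N`, and `F_crit` is the central-F critical value at
#' `alpha`.
#'
#' @param spec a [power_spec()].
#' @param total_n total sample size (> n_groups + numerator_df).
#' @return Power, in (0, 1).
#' @export
anova_power <- function(spec, total_n) {
  stopifnot(inherits(spec, "power_spec"))
  df2 <- total_n - spec$n_groups
  if (df2 < 1) stop("total_n leaves no residual degrees of freedom")
  crit <- stats::qf(1 - spec$alpha, spec$numerator_df, df2)
  1 - stats::pf(crit, spec$numerator_df, df2,
                ncp = spec$effect_size_f^2 * total_n)
}

#' Smallest total N reaching the target power
#'
#' Linear search upward from the smallest admissible N.
#'
#' @param spec a [power_spec()].
#' @param n_max search ceiling.
#' @return Integer total sample size.
#' @export
required_n <- function(spec, n_max = 1e6) {
  stopifnot(inherits(spec, "power_spec"))
  n <- spec$n_groups + spec$numerator_df + 1L
  while (n <= n_max) {
    if (anova_power(spec, n) >= spec$target_power) return(as.integer(n))
    n <- n + 1L
  }
  stop("target power unreachable with N <= ", n_max)
}

#' Exclusion by perfect odour discrimination
#'
#' Participants who identify the odd stimulus on every trial of the
#' triangle discrimination task are excluded, since perfect
#' discrimination defeats the blinding of the olfactory manipulation.
#'
#' @param n_correct integer vector of correct identifications per
#'   participant.
#' @param n_trials number of discrimination trials (default 6).
#' @return Logical vector: `TRUE` for participants to keep.
#' @export
discrimination_keep <- function(n_correct, n_trials = 6) {
  stopifnot(all(n_correct >= 0), all(n_correct <= n_trials))
  n_correct < n_trials
}
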