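#' Wiener first-passage log-density
#'
#' Log density of the first passage time at the named boundary for a
#' diffusion with boundary separation `alpha`, relative start `beta`
#' (fraction of `alpha` above the lower boundary), drift `delta`, unit
#' diffusion coefficient and non-decision shift `tau`. Computed by the
#' small-time / large-time series expansions with an automatic switch to
#' whichever needs fewer terms at truncation tolerance `eps`. Response
#' times at or below `tau` have zero density (`-Inf`).
#'
#' @param rt response time(s) in seconds.
#' @param boundary `"upper"` or `"lower"` (recycled); the upper boundary
#'   is the selfish choice throughout the package.
#' @param params a [ddm_params()].
#' @param eps series truncation tolerance.
#' @return Vector of log-densities.
#' @export
wiener_log_density <- function(rt, boundary, params, eps = 1e-7) {
  stopifnot(inherits(params, "ddm_params"),
            all(boundary %in% c("upper", "lower")))
  n <- max(length(rt), length(boundary))
  rt <- rep_len(rt, n)
  up <- as.integer(rep_len(boundary, n) == "upper")
  .wiener_lpdf_cpp(rt, up, params$alpha, params$beta, params$delta,
                   params$tau, eps)
}

#' Highest density interval of a sample
#'
#' Narrowest contiguous interval containing the stated probability mass of
#' the draws (exhaustive scan over the sorted sample).
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @param mass probability mass, default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100) stop("hdi needs at least 100 draws")
  stopifnot(mass > 0, mass < 1)
  x <- sort(draws)
  n <- length(x)
  nk <- max(2L, ceiling(mass * n))
  lo <- x[seq_len(n - nk + 1L)]
  hi <- x[seq.int(nk, n)]
  i <- which.min(hi - lo)
  c(lo[i], hi[i])
}

#' Rank-normalized split R-hat
#'
#' Convergence diagnostic: each chain is split in half, all draws are
#' jointly rank-normalized (normal scores), and the classic
#' between/within-chain variance ratio is computed on the transformed
#' split chains. Values below 1.01 indicate good mixing.
#'
#' @param chains a matrix (iterations x chains) or list of equal-length
#'   numeric vectors; at least 2 chains of at least 4 draws.
#' @return Scalar R-hat.
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2) stop("rhat needs at least 2 chains")
  if (nrow(chains) < 4) stop("rhat needs at least 4 draws per chain")
  # split each chain in half
  half <- floor(nrow(chains) / 2)
  sc <- cbind(chains[seq_len(half), , drop = FALSE],
              chains[seq.int(half + 1, 2 * half), , drop = FALSE])
  if (stats::var(as.vector(sc)) == 0) return(1)
  z <- stats::qnorm((rank(sc) - 3 / 8) / (length(sc) + 1 / 4))
  dim(z) <- dim(sc)
  n <- nrow(z); m <- ncol(z)
  w <- mean(apply(z, 2, stats::var))
  b <- n * stats::var(colMeans(z))
  sqrt(((n - 1) / n * w + b / n) / w)
}

# coefficient layout of the group-level draws
.group_par_names <- function() {
  fam <- c("alpha", "beta", "delta", "tau")
  as.vector(vapply(fam, function(f)
    paste0(f, c("_mu", "_sex", "_condition", "_interaction",
                "_subject_sd")), character(5)))
}

#' Hierarchical Bayesian drift-diffusion fit
#'
#' Fits the four diffusion parameters per participant under a group-level
#' linear model on transformed scales: for each parameter family,
#' participant values are normal around
#' `mu + b_sex * sex + b_condition * condition + b_interaction * sex *
#' condition` (dummy coding female = 0 / male = 1, control = 0 /
#' androstadienone = 1). Transforms: `alpha = exp(.)`,
#' `beta = plogis(.)`, `delta` identity,
#' `tau = 0.1 + plogis(.) * (0.95 * min observed rt - 0.1)` per
#' participant (a 0.1 s global reaction-time floor). Priors are standard
#' normal on the grand means and the 12 effect coefficients and
#' half-normal(1) on the subject-level dispersions.
#'
#' Sampling is adaptive Metropolis-within-Gibbs: random-walk updates for
#' the participant parameters and dispersions (proposal scales tuned
#' during warmup) and exact Gibbs draws for the regression coefficients.
#' Skipped trials and trials faster than `rt_floor` are excluded before
#' fitting. Convergence is assessed by rank-normalized split R-hat on
#' every stored parameter; any R-hat of 1.01 or more flags the result.
#'
#' @param trials long-format trial data frame with `participant_id`,
#'   `sex`, `condition`, `choice`, `rt` columns; at least 2 participants
#'   per sex-by-condition cell.
#' @param chains number of MCMC chains (>= 2).
#' @param iter iterations per chain (first `warmup` discarded).
#' @param warmup warm-up iterations; default half of `iter`.
#' @param seed integer seed (required).
#' @param rt_floor fast-guess exclusion threshold in seconds.
#' @param rt_lb global lower bound for reaction times (seconds).
#' @param eps Wiener density truncation tolerance.
#' @param sweeps subject-level Metropolis sweeps per iteration; more
#'   sweeps lower the autocorrelation of the random walk at linear cost.
#' @return An object of class `ddm_posterior`: group-level draws,
#'   per-parameter R-hat, 95% HDIs, per-participant posterior summaries
#'   on the natural scale, and a `converged` flag.
#' @export
fit_hierarchical_ddm <- function(trials, chains = 4, iter = 1000,
                                 warmup = floor(iter / 2), seed,
                                 rt_floor = 0.3, rt_lb = 0.1,
                                 eps = 1e-7, sweeps = 3) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for MCMC")
  stopifnot(chains >= 2, iter > warmup, warmup >= 1)
  tr <- trials[trials$choice != "skipped" & !is.na(trials$rt) &
                 trials$rt >= rt_floor, , drop = FALSE]
  if (!all(tr$sex %in% c("female", "male")))
    stop("unknown sex labels")
  if (!all(tr$condition %in% c("control", "androstadienone")))
    stop("unknown condition labels")
  tr <- tr[order(tr$participant_id), , drop = FALSE]
  ids <- unique(tr$participant_id)
  nsub <- length(ids)
  sub <- match(tr$participant_id, ids)
  first <- match(ids, tr$participant_id)
  sex <- as.numeric(tr$sex[first] == "male")
  cond <- as.numeric(tr$condition[first] == "androstadienone")
  cell_n <- table(sex, cond)
  if (length(cell_n) < 4 || any(cell_n < 2))
    stop("need at least 2 participants in each sex-by-condition cell")
  X <- cbind(sex = sex, condition = cond, interaction = sex * cond)
  up <- as.integer(tr$choice == .upper_boundary_choice)
  minrt <- tapply(tr$rt, sub, min)
  tau_ub <- 0.95 * as.numeric(minrt)
  if (any(tau_ub <= rt_lb))
    stop("a participant's fastest response leaves no room above the ",
         "reaction-time floor")
  lo <- match(seq_len(nsub), sub) - 1L
  hi <- c(lo[-1] - 1L, nrow(tr) - 1L)

  pnames <- .group_par_names()
  keep <- iter - warmup
  group <- array(NA_real_, c(keep, chains, 20),
                 dimnames = list(NULL, NULL, pnames))
  subj <- array(NA_real_, c(keep, chains, nsub * 4))

  with_preserved_seed(seed, {
    for (ch in seq_len(chains)) {
      # crude, chain-jittered initial values
      p_up <- tapply(up, sub, mean)
      th0 <- matrix(0, nsub, 4)
      th0[, 1] <- log(1.5) + stats::rnorm(nsub, 0, 0.2)
      th0[, 2] <- stats::rnorm(nsub, 0, 0.2)
      th0[, 3] <- 2 * (as.numeric(p_up) - 0.5) + stats::rnorm(nsub, 0, 0.2)
      th0[, 4] <- stats::rnorm(nsub, -1, 0.2)
      mu0 <- colMeans(th0) + stats::rnorm(4, 0, 0.1)
      b0 <- matrix(stats::rnorm(12, 0, 0.1), 4, 3)
      sd0 <- exp(stats::rnorm(4, log(0.4), 0.2))
      res <- .ddm_mcmc_chain(tr$rt, up, lo, hi, X, tau_ub,
                             as.integer(iter), as.integer(warmup),
                             th0, mu0, b0, sd0, rt_lb, eps,
                             as.integer(sweeps))
      group[, ch, ] <- res$group
      subj[, ch, ] <- res$subject
    }
  })

  rhats <- c(
    stats::setNames(vapply(seq_len(20), function(j) rhat(group[, , j]),
                           numeric(1)), pnames),
    stats::setNames(
      vapply(seq_len(nsub * 4), function(j) rhat(subj[, , j]), numeric(1)),
      paste0(rep(ids, each = 4), "_",
             rep(c("alpha", "beta", "delta", "tau"), nsub))))
  hdis <- t(vapply(seq_len(20),
                   function(j) hdi(as.vector(group[, , j])), numeric(2)))
  dimnames(hdis) <- list(pnames, c("low", "high"))

  # per-participant posterior summaries on the natural scale
  subj_sum <- do.call(rbind, lapply(seq_len(nsub), function(i) {
    d <- subj[, , (i - 1) * 4 + 1:4, drop = FALSE]
    a <- exp(d[, , 1]); b <- stats::plogis(d[, , 2]); v <- d[, , 3]
    tau <- rt_lb + stats::plogis(d[, , 4]) * (tau_ub[i] - rt_lb)
    data.frame(participant_id = ids[i],
               alpha = mean(a), beta = mean(b), delta = mean(v),
               tau = mean(tau))
  }))

  gm <- apply(group, 3, mean)
  structure(
    list(group_draws = group, group_mean = stats::setNames(gm, pnames),
         hdi_95 = hdis, rhat = rhats, participant_summary = subj_sum,
         chains = chains, iter = iter, warmup = warmup,
         n_participants = nsub, n_trials = nrow(tr),
         converged = all(rhats < 1.01)),
    class = "ddm_posterior")
}

#' @export
print.ddm_posterior <- function(x, ...) {
  cat(sprintf(
    "Hierarchical DDM posterior: %d participants, %d trials, %d chains x %d iterations (%d warm-up)\n",
    x$n_participants, x$n_trials, x$chains, x$iter, x$warmup))
  cat(sprintf("  max R-hat: %.4f (%s)\n", max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(mean = round(x$group_mean, 3),
                    hdi_low = round(x$hdi_95[, "low"], 3),
                    hdi_high = round(x$hdi_95[, "high"], 3))
  print(tab)
  invisible(x)
}

#' Credible group difference by the HDI rule
#'
#' A group-level coefficient is a credible difference if its 95% highest
#' density interval excludes zero.
#'
#' @param posterior a [fit_hierarchical_ddm()] result.
#' @param coefficient coefficient name, e.g. `"delta_condition"`; see
#'   `rownames(posterior$hdi_95)`.
#' @return `"credible"` or `"not_credible"`.
#' @export
credible_group_difference <- function(posterior, coefficient) {
  stopifnot(inherits(posterior, "ddm_posterior"))
  if (!coefficient %in% rownames(posterior$hdi_95))
    stop("unknown coefficient: ", coefficient)
  h <- posterior$hdi_95[coefficient, ]
  if (h["low"] > 0 || h["high"] < 0) "credible" else "not_credible"
}

#' Names of the 12 sex/condition effect coefficients
#' @return Character vector of coefficient names.
#' @export
ddm_effect_coefficients <- function() {
  fam <- c("alpha", "beta", "delta", "tau")
  as.vector(vapply(fam, function(f)
    paste0(f, c("_sex", "_condition", "_interaction")), character(3)))
}
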