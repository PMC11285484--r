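---
title: "Models and methods for social discounting analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for social discounting analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The task and its data

A social discounting task measures how generosity declines with social
distance. On each trial the participant chooses between a *selfish*
option (receiving an amount `A` alone) and a *generous* option (the
participant and a partner at social distance `D` each receive a fixed
130 HKD). The default design crosses eight distances (1, 2, 3, 5, 10,
20, 50, 100 — ordinal positions in the participant's social network)
with nine selfish amounts (130–290 HKD in 20 HKD steps), 72 unique
trials, 6 s response window, 1 s inter-trial interval. Skipped trials
are re-presented once at the end of their distance block. Compensation
is a 105 HKD flat fee plus 5% of the amount chosen on one randomly
selected trial, so the worst case (generous choice selected) pays
105 + 0.05 × 130 = 111.5 HKD.

`socdisc` analyses such data along three routes with increasing model
commitment, plus a joint choice/response-time model:

1. **Model-free AUC** — logistic indifference points per distance,
   normalized trapezoidal area under the forgone-amount curve.
2. **Hyperbolic discounting fit** — least squares on amounts forgone.
3. **Softmax maximum likelihood** — trial-level fit of the same
   hyperbolic value function through a logistic choice rule.
4. **Hierarchical Bayesian drift-diffusion model (DDM)** — choices and
   response times jointly, with sex × condition group regressors.

A synthetic-data generator with known ground truth backs every stage
with a recovery test.

# The synthetic-data generator

`simulate_cohort()` builds a 2 (sex) × 2 (condition:
androstadienone vs control) between-subject cohort. Participant-level
parameters are drawn around cell means: log-normally for positive
parameters (`k`, `V`, `sigma`, `alpha`, `tau`), logit-normally for the
start bias `beta`, normally for the drift `delta`. The default cell
means are chosen to be realistic for this task family and are shared
across cells — a *null* cohort, since group effects are what the
analysis has to rule in or out: discount rate `k = 0.2`, generosity
intercept `V = 280` HKD, inverse temperature `sigma = 0.05` per HKD
(matching the magnitudes a typical cohort shows on this task), boundary
separation `alpha = 1.6`, bias `beta = 0.5`, drift `delta = 0.25` per
second, non-decision time `tau = 0.35` s (typical two-alternative
choice values, mean RT just over a second inside the 6 s window).
Dispersion defaults are 0.3 on the modelling scale (0.2 for `tau`).
Contamination defaults: 2% fast guesses (uniform RT below the 0.3 s
floor, random choice) and 1% skip probability per presentation; a trial
that times out (diffusion exceeding the response window) is also
skipped and re-presented once.

Three modes decouple the two generative models. `"ddm"` draws choices
*and* RTs from the diffusion (the upper boundary is the selfish choice
— a documented package-wide convention, configurable nowhere else);
drift is constant per participant, matching the fitted model, so
choices carry no amount structure. `"softmax"` draws choices from the
discounting agent and no RTs. `"hybrid"` draws choices from the agent
and RTs from the diffusion conditioned (by rejection) on the matching
boundary — used for end-to-end runs where choices must carry
discounting structure and records still need RTs. What the generator
does *not* emulate: drifts that scale with the value difference (the
fitted DDM is constant-drift, so the generator defaults to the same
assumption), sequential effects, fatigue, or block-order effects.
Recovery tests passing on these data therefore show correctness of the
estimators under the model's own assumptions, not robustness to every
misspecification a real cohort can produce.

The diffusion simulator is an Euler–Maruyama walk (default step 1 ms,
bias far below the RT resolution) with a Brownian-bridge crossing
check inside each step, which removes most of the residual
discretization bias in hitting times; its hitting probabilities are
tested against the closed form for drifted Brownian motion.

# Model-free estimation

Per participant and distance, the indifference point is the amount at
which the selfish choice probability crosses 0.5, from a logistic
regression of choice on amount. Degenerate response patterns are
resolved deterministically: all-selfish → 120 HKD, all-generous → 300
HKD (half an increment outside the offered range), perfectly separated
mixed responses → the midpoint of the separating gap (the logistic MLE
diverges under separation; the midpoint is the deterministic analogue
of the imputation rule). Amounts forgone are indifference − 130, so the
low imputation yields −10 HKD; this raw value is retained in the
profile and clipped to 0 only inside the AUC normalization, preserving
the index's [0, 1] range.

The AUC normalizes forgone amounts by the *theoretical* maximum (170
HKD), not the per-participant observed maximum, keeping the index
comparable across participants; distances are normalized by the largest
distance; an anchor at distance 0 carries the smallest-distance value so
a flat no-discounting profile integrates to exactly 1. These three
conventions are genuine choices — the trapezoid construction is
otherwise ambiguous — and are asserted by tests (monotonicity,
collinearity invariance, exact extremes).

# Model-based estimation

The hyperbolic discount function values the premium of sharing at
distance `D` as `v = V / (1 + kD)`. `fit_hyperbolic()` fits it to the
amounts forgone by ordinary least squares (standard for discounting
curves): a 60-point log-spaced grid over `k` with the conditionally
optimal `V` in closed form, then L-BFGS-B refinement on `(log k, V)`.
Bounds: `k` in [1e-6, 10], `V` in [0, 1000]. A zero-curvature profile
pins `k` at its lower bound and raises a flag. `k` is log-transformed
for all group-level analysis.

`fit_mle()` fits `(log k, V, log sigma)` by maximizing the softmax
likelihood over scored trials, after excluding skipped trials and
responses faster than 0.3 s (fast guesses). The log parameterization
enforces positivity and conditions the optimization; a deterministic
3 × 3 × 3 multistart grid (`k` ∈ {0.02, 0.2, 1}, `V` ∈ {50, 170, 400},
`sigma` ∈ {0.01, 0.05, 0.2}) makes fits reproducible without a seed.
When the fitted `sigma` spreads less than one logit across the amount
range the likelihood is essentially flat in `(k, V)` and the fit is
flagged weakly identified rather than silently returned.

# The hierarchical drift-diffusion model

The Wiener first-passage density is computed by the small-time and
large-time series expansions with an automatic switch to whichever
needs fewer terms at truncation tolerance 1e-7; unit tests verify
reflection symmetry to machine precision, unit mass by quadrature, and
agreement with a large Euler-simulation oracle.

Each participant has four parameters on transformed scales —
`log alpha`, `logit beta`, `delta` (identity), and a scaled-logit
non-decision time `tau = 0.1 + plogis(·) · (0.95 · min observed RT −
0.1)`, realizing a 0.1 s global reaction-time floor and a
participant-specific upper constraint. For each transformed parameter
the participants' values are normal around
`mu + b_sex·sex + b_cond·condition + b_int·sex·condition` (dummy coding
female = 0 / male = 1, control = 0 / androstadienone = 1; reference
levels are a convention, the HDI rule is invariant to it), giving 12
effect coefficients. Priors are standard normal on the grand means and
effect coefficients and half-normal(1) on the subject dispersions.

Sampling is adaptive Metropolis-within-Gibbs: random-walk updates for
participant parameters (several sweeps per iteration, proposal scales
tuned to 44% acceptance during warmup), exact Gibbs draws for the
regression coefficients, and log-scale random-walk updates for the
dispersions. Each participant parameter additionally receives an
independence proposal from its conditional prior per iteration: where
the likelihood plateaus the conditional posterior reduces to the prior,
so these moves cross the plateau in one step. Two interweaved
non-centered moves — a joint shift of a
group coefficient with its subjects' parameters, and a joint rescale of
a dispersion with its residuals — traverse the prior-dominated
directions that single-site updates cross slowly; without them the
scaled-logit `tau` transform (which saturates whenever the fastest
response sits near the true non-decision time) mixes badly. Convergence
is assessed with rank-normalized split R-hat on every stored parameter;
any value at or above 1.01 flags the whole fit. A group difference is
*credible* when the coefficient's 95% highest density interval
(narrowest interval of that mass, by exhaustive scan) excludes zero.

Default test-scale configuration is 4 chains × 1000 iterations (half
warm-up); full-scale analysis uses 4 × 4000. On an 80-participant null
cohort the sampler reaches all R-hat < 1.01 at 4 × 2000–3000 within a
few minutes on one core; the package's own acceptance checks run at
that scale, and the 50-replicate coverage study uses 12-participant
cohorts with a reduced grid and 2 × 300 iterations. The model omits
across-trial variability parameters (sv, sz, st) by design.

# Design statistics

`two_way_anova()` uses Type II sums of squares, safe for unbalanced
cells (real cohorts are unbalanced; the design type is a choice, since
balanced data make the types coincide), with generalized eta squared
`SS_effect / (SS_effect + SS_error)` — for purely between-subject
designs this coincides with partial eta squared. `one_sample_t()`
returns Cohen's `d = t/√n`. `anova_power()` evaluates
`P(F' > F_crit)` with `F'` noncentral F, `lambda = f² N`, and
`required_n()` searches the smallest N meeting the target power. For
the canonical four-group, numerator-df-1 specification at
`f = 0.241`, `alpha = 0.05`, power 0.80 the exact rule returns 138
(power at 137 is 0.79967, marginally under target; an unrounded effect
size just above 0.241 yields 137 — the same rule reproduces the
textbook `f = 0.25 → N = 128` case exactly).

# Numerical conventions and limitations

Money is stored as decimal HKD (payout arithmetic such as 111.5 stays
exact in binary floating point at one decimal), RTs in seconds rounded
to 3 decimals on write. Categories serialize as lowercase strings;
dummy coding happens only inside fitting code. Every stochastic entry
point demands a seed and restores the caller's RNG state. Known
limitations: the MLE route needs informative choice variation (flagged
otherwise, common at small `sigma`); AUC depends on the stated anchor
and normalization conventions; the DDM sampler is a random-walk scheme
— adequate at cohort scale here, but slower-mixing than gradient-based
samplers at much larger scale; and the generator's constant-drift
assumption means `"ddm"`-mode choices are exchangeable across amounts,
so discounting estimators should be exercised on `"softmax"` or
`"hybrid"` data.
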