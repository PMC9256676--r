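---
title: "Starting-time drift diffusion models for lottery choice: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Starting-time drift diffusion models for lottery choice: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`stddm` analyzes accept/reject decisions and response times from a mixed
lottery task in which each trial offers `magnitude` points with probability
`win_prob` and `-magnitude` points otherwise, so the expected value is
`EV = magnitude * (2 * win_prob - 1)`. Decisions are modeled as a Wiener
diffusion: evidence `E(t)` starts at `E0 = (2 * bias - 1) * B`, accumulates as

    dE(t) = mu(t) dt + dW(t),

with the diffusion coefficient fixed at 1, and the first crossing of the
absorbing boundaries at `+B` (accept) or `-B` (reject) at time `tau`
determines the choice; the observed RT adds a non-decision time, `rt = tau +
ndt`. What makes this a *starting-time* DDM (stDDM) is that the drift `mu(t)`
is piecewise constant within a trial: different choice attributes begin to
contribute at different latencies, controlled by a signed relative starting
time `s` (seconds). The attributes are the standardized win-minus-loss
probability difference (`v_p`), the standardized reward magnitude (`v_m`),
and the standardized natural log of the previously accumulated reward
(`v_a`), weighted by `w_p`, `w_m`, `w_a` (drift per standardized unit).

Five variants are implemented:

* **M0** — standard DDM, constant drift `w_p v_p + w_m v_m`; equals M1 with
  `s = 0`.
* **M1** — probability and magnitude enter at different times; with `s > 0`
  probability leads by `s` seconds, with `s < 0` magnitude leads by `|s|`.
* **M2** — drift as M1; the accumulated reward instead shifts the *starting
  point* by `w_a v_a` evidence units (clipped just inside the boundaries).
* **M3** — the accumulated-reward term `w_a v_a` is present in the drift
  from accumulation onset; probability and magnitude switch on at 0 and `|s|`.
* **M4** — probability and magnitude enter together; the accumulated-reward
  drift term leads or lags them by `|s|`.

All schedules have at most one change point, at `|s|`; an `|s|` longer than
the decision time simply means the later attribute never contributes to that
trial. The starting-time clock runs during accumulation only (after `ndt`),
consistent with treating attribute onsets as accumulation phenomena.

# Likelihood

The likelihood of an observed (choice, rt) pair is the first-passage-time
density of the piecewise-constant-drift diffusion at `tau = rt - ndt`.

* **Constant drift** (`constant_drift_density()`): the classic dual-series
  Wiener first-passage density, using the method-of-images series for small
  `tau / a^2` and the spectral series for large, with terms truncated
  adaptively once they fall below 1e-9 of working magnitude (`a = 2B` is the
  boundary separation).
* **Two segments** (`piecewise_density()`): for `tau` beyond the change
  point, the surviving probability mass at the change point is propagated
  with the absorbing-boundary transition kernel (images/spectral, same
  switching rule) and the second segment's first-passage density is
  integrated over entry states. The default spatial rule is a 200-point
  trapezoid grid; the fitting path uses 48-node Gauss-Legendre quadrature on
  the same integrand, which reaches the same accuracy (they agree to ~1e-6
  relative in the tests) at a quarter of the cost because the integrand is
  smooth and vanishes at the boundaries.
* Just past the change point (within 1 ms) the drift switch is negligible
  and the spatial quadrature cannot resolve the entry-state boundary layer,
  so the first-segment density is used; this preserves continuity of the
  density across the change point to O(1 ms x drift change).
* Symmetrically, a very short first segment concentrates the entry-state
  mass in a spike narrower than the spatial quadrature can resolve (the
  failure mode is severe: nodes either miss the spike or land on it). Below
  a quadrature-dependent threshold (20 ms for the 48-node rule, grid-spacing
  based for the trapezoid), the first segment is therefore folded into a
  drift shift of the starting point, which is exact in the `t1 -> 0` limit
  and keeps the likelihood continuous in `s` near zero. The residual error
  peaks at a few percent just below the threshold, and is largest for
  starting points very close to a boundary combined with a near-zero `|s|`
  (an M2 corner case).
* A `simulated_kde` backend (Euler paths + kernel density) provides an
  independent Monte-Carlo check of the analytic density and is used as an
  oracle in the test suite, never as the fitting likelihood.

The Euler-Maruyama simulator (`simulate_trial()`, step 1 ms by default)
applies a Brownian-bridge correction for within-step boundary crossings,
which removes the leading-order discretization bias; without it, simulated
absorption probabilities at a 0.5 ms step are visibly biased relative to the
closed form. Trials without a response by the 4 s task deadline are recorded
as `none`. By default the likelihood is *not* renormalized by the
probability of responding before the deadline, because non-responses are
excluded from the analyses rather than modeled; `normalize_deadline = TRUE`
enables the renormalization.

# The synthetic task generator

The generator emulates the stimulus statistics of the lottery task: win
probabilities on [0.04, 0.95] with mean 50% and SD 32%, magnitudes on
[2, 110] points with mean 56 and SD 40, and EVs within [-94, 97] with mean 0
and SD about 44. A uniform draw on those ranges cannot reach SDs of 0.32 and
40 (uniform SDs would be 0.26 and 31), so the marginals are U-shaped
symmetric Beta distributions whose shapes (0.413 for probability, 0.353 for
magnitude) were calibrated once so that the *post-rejection* SDs land on the
targets; pairs whose EV (or whose reflected partners' EV, see below) would
leave the admissible range are rejected. Trials are generated as
reflection-balanced quadruples `(p, m), (1-p, m), (p, 112-m), (1-p, 112-m)`,
as in a counterbalanced factorial task design, which makes the sample means
of win probability (0.5), magnitude (56) and EV (0) exact by construction;
the EV SD then emerges at about 43.5. Probabilities are drawn on
[0.05, 0.95] so every reflected member stays in range.

`simulate_experiment()` wires the generator to the trial simulator: each
synthetic participant completes one session of interleaved decision-aid and
control trials with a shared running points total; accepting a gamble pays
`+magnitude` with probability `win_prob` and `-magnitude` otherwise, while
rejected and missed gambles leave the total unchanged. The accumulated total
before each trial feeds the next decision through `v_a` using a *fixed*
generative `attribute_scaling()` (defaults: log-accumulated mean 4.5, SD
2.6, calibrated from long pilot simulations of the default cohort), so the
generative process is fully specified before any data exist. Non-positive
totals are floored at 1 point before the log (so the first trial maps to
`log(1) = 0`); this rule is monotone, defined everywhere, and identity-safe
at one point. For fitting, attributes are re-standardized empirically by
pooling all retained participants and trials; z-scoring treats the pooled
trials as the population of interest (population SD). A scale-only variant
(`center = FALSE`) divides by SDs without centering.

The default synthetic cohort is 20 participants per age group and 120 trials
per condition, with individual parameters drawn around four (age x
condition) group-mean cells whose pattern encodes the age and decision-aid
effects of interest: a higher probability weight in younger adults
and under the decision-aid, an earlier probability starting time (larger
`s`) plus longer non-decision times and higher boundaries in older adults, a
uniformly negative accumulated-reward weight, and neutral bias. What the
generator does *not* emulate: sequential dependencies beyond the running
total (fatigue, learning), within-session parameter drift, contaminant
responses (fast guesses), and any perceptual detail of the color-coded
decision aid (the aid enters only as a condition label with its own
parameter set). Passing tests therefore show that the estimation machinery
is correct and well calibrated for data of this structure, not that the
model family is adequate for any particular empirical dataset.

# Hierarchical estimation

`fit_stddm()` estimates individual participant-condition parameters drawn
from four group-level Normal distributions (2 age groups x 2 conditions),
with group-mean priors `N(0, 1)` for `w_p`, `w_m`, `w_a`, `s`; uniform
(0.0001, 5) and (0, 10) for the boundary and non-decision-time means;
Beta(2, 2) for the bias mean; and Gamma(shape 1, scale 0.1) priors on the
group-level spreads. The gamma prior is interpreted on the SD of the
individual distribution — the standard hierarchical reading — with a
`spread_on = "precision"` alternative. Individual bounded parameters
(`ndt`, `B`, `bias`) are truncated normals on their supports.

The sampler is adaptive Metropolis-within-Gibbs: each participant-condition
block is updated by a joint random-walk proposal (reflected at parameter
bounds) against the trial-level likelihood; Normal-prior group means are
conjugate Gibbs draws; bounded, Beta and Gamma hyperparameters use
random-walk Metropolis (log-scale for spreads). Proposal scales adapt toward
30% acceptance during burn-in and are frozen afterwards. The per-draw
deviance is the running `-2 x` sum of block log-likelihoods tracked by the
sampler, recorded both overall and per group cell, which makes DIC free of
extra likelihood passes; the identity is verified exactly in the tests.
Split-R-hat and effective sample size are computed for every group-level
hyperparameter; R-hat above 1.1 triggers a warning naming the parameters.

Presets: `desk` (default; 3 chains x 1,000 kept after 2,000 burn-in) is the
scale used throughout the package's own validation, including the parameter
recovery check (20 participants/group x 120 trials/condition, truth-estimate
correlation of group-level `w_p`, `w_m`, `s` across the four cells);
`full` (3 x 10,000 kept after 50,000 burn-in) is the high-effort
setting for final inference. Initial values are moment-guided
(non-decision time at half the block's fastest RT, drift weights from a
logistic-choice approximation) and jittered across
chains; chains are seeded `seed`, `seed + 1`, ... for exact reproducibility.

# Model comparison and behavioral analyses

`compute_dic()` reports `DIC = D-bar + pD` with `pD = D-bar - D(theta-bar)`,
overall and per group cell; the per-cell criterion restricts the deviance to
the cell's trials while using the joint fit's parameters — the only
consistent reading of a per-cell table from a joint hierarchical fit.
Negative `pD` is reported with a warning rather than treated as an error.
`split_half_rmse()` fits one half of each participant-condition's trials
(odd or even indices; both splits are computed and averaged by default,
as neither half is privileged), simulates each held-out trial 100 times at
the per-participant posterior-mean parameters, and scores the RMSE between
held-out binary choices and simulated choice probabilities per participant,
summarized as mean and SD per group cell.

EV sensitivity is the slope of a per-participant logistic regression of
acceptance on the raw-points EV (`ev_slopes()`); complete separation is
capped at |slope| = 10 and flagged. The 2 x 2 factorial test on the slopes
is an aligned-rank-transform ANOVA (`aligned_rank_anova()`): for each
effect, responses are aligned by removing the estimated contributions of all
other effects (cell-mean alignment), ranked with average ties, and a
factorial ANOVA with subject as a random blocking factor is run on the
ranks, reading off only the aligned-for effect; completely tied ranks give
p = 1 by convention. The participant-level slope is the analysis unit. Its
type-I error and power properties are verified by simulation in the test
suite. Posterior comparisons (`posterior_contrasts()`) are computed per draw
on the four group-cell posteriors — age main effect (younger minus older,
averaged over conditions), condition main effect (aid minus control), and
their interaction — plus the derived probability-minus-magnitude weight
difference, summarized by the posterior mean, the 95% highest-density
interval (shortest sorted-sample window, `hdi()`), and the posterior
probability that the difference exceeds zero.

# Numerical choices and limitations

* Series truncation: adaptive, threshold 1e-9; small/large-time switch at
  `t / a^2 = 0.35` (first passage) and 0.15 (transition kernel).
* Quadrature: trapezoid 200 points (reference), Gauss-Legendre 48 nodes
  (fitting); both exposed via `piecewise_density()`.
* Simulator: 1 ms Euler step (0.5 ms in oracle checks), Brownian-bridge
  crossing correction, 10 s accumulation cap; simulated RTs beyond the 4 s
  deadline become `none`, mirroring the task.
* M2's shifted start is clipped to within `1e-6 x B` of the boundaries
  rather than allowing instant absorption; clipping keeps the likelihood
  finite and the shifted start well defined for any weight value.
* Degenerate inputs fail loudly: zero-variance attributes, infeasible
  stimulus-moment targets, unfiltered trials in `fit_stddm()`.
* The deadline-censoring correction is off by default (exclusion, not
  modeling, of non-responses); enabling it renormalizes per-trial densities.
* The sampler is random-walk based; at desk scale the group-level means of
  interest mix well, but spread hyperparameters can show higher
  autocorrelation. The full-scale preset exists for final inference.
* Split-half RMSE at small per-half trial counts is a noisy criterion;
  fewer than 20 trials per half triggers a warning.
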