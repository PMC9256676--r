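#' Expected value of a symmetric mixed gamble
#'
#' The lottery offers `magnitude` points with probability `win_prob` and
#' `-magnitude` points otherwise, so the expected value is
#' `win_prob * magnitude + (1 - win_prob) * (-magnitude)`, i.e.
#' `magnitude * (2 * win_prob - 1)`.
#'
#' @param win_prob Win probability as a fraction in `[0, 1]`.
#' @param magnitude Reward magnitude in points (non-negative).
#' @return Expected value in points, vectorized over the inputs.
#' @examples
#' expected_value(0.5, 80)   # 0
#' expected_value(0.95, 110) # 99
#' @export
expected_value <- function(win_prob, magnitude) {
  if (any(win_prob < 0 | win_prob > 1, na.rm = TRUE)) {
    abort("`win_prob` must lie in [0, 1].")
  }
  if (any(magnitude < 0, na.rm = TRUE)) {
    abort("`magnitude` must be non-negative.")
  }
  magnitude * (2 * win_prob - 1)
}

# Beta shapes calibrated once so that, after the EV-range rejection rule, the
# marginal SDs match the task's printed stimulus statistics (win probability
# 50% +/- 32%, magnitude 56 +/- 40 points).
.calib_shape_p <- 0.413
.calib_shape_m <- 0.353

#' Specify a lottery stimulus design
#'
#' Describes the target stimulus statistics of the mixed lottery task: win
#' probabilities spanning 4--95% with mean 50% and SD 32%, reward magnitudes
#' spanning 2--110 points with mean 56 and SD 40, and expected values in
#' [-94, 97] with mean 0 and SD about 44 points.
#'
#' @param n_trials Number of lottery trials per condition (>= 20).
#' @param win_prob_mean,win_prob_sd Target mean/SD of the win probability
#'   (fractions).
#' @param magnitude_mean,magnitude_sd Target mean/SD of the reward magnitude
#'   (points).
#' @param ev_mean,ev_sd Target mean/SD of the trial expected value (points);
#'   these emerge from the marginals and are used for validation.
#' @param win_prob_range,magnitude_range,ev_range Admissible ranges.
#' @return A `stimulus_design` list.
#' @export
stimulus_design <- function(n_trials = 120,
                            win_prob_mean = 0.50, win_prob_sd = 0.32,
                            magnitude_mean = 56, magnitude_sd = 40,
                            ev_mean = 0, ev_sd = 44,
                            win_prob_range = c(0.05, 0.95),
                            magnitude_range = c(2, 110),
                            ev_range = c(-94, 97)) {
  if (n_trials < 20) abort("`n_trials` must be at least 20.")
  d <- list(
    n_trials = as.integer(n_trials),
    win_prob_mean = win_prob_mean, win_prob_sd = win_prob_sd,
    magnitude_mean = magnitude_mean, magnitude_sd = magnitude_sd,
    ev_mean = ev_mean, ev_sd = ev_sd,
    win_prob_range = win_prob_range, magnitude_range = magnitude_range,
    ev_range = ev_range
  )
  # feasibility of a Beta marginal on each range
  for (nm in c("win_prob", "magnitude")) {
    rng <- d[[paste0(nm, "_range")]]
    mu  <- (d[[paste0(nm, "_mean")]] - rng[1]) / diff(rng)
    v   <- (d[[paste0(nm, "_sd")]] / diff(rng))^2
    if (mu <= 0 || mu >= 1 || v >= mu * (1 - mu)) {
      abort(sprintf(
        "Infeasible %s targets: mean %.3g, SD %.3g on range [%.3g, %.3g].",
        nm, d[[paste0(nm, "_mean")]], d[[paste0(nm, "_sd")]], rng[1], rng[2]))
    }
  }
  structure(d, class = "stimulus_design")
}

# beta shapes matching mean/var on a range; symmetric designs use the
# rejection-calibrated shapes so post-rejection SDs land on target
.beta_shapes <- function(mean, sd, range, calibrated_shape = NULL) {
  mu <- (mean - range[1]) / diff(range)
  if (!is.null(calibrated_shape) && abs(mu - 0.5) < 1e-9) {
    return(c(calibrated_shape, calibrated_shape))
  }
  v <- (sd / diff(range))^2
  nu <- mu * (1 - mu) / v - 1
  c(mu * nu, (1 - mu) * nu)
}

#' Generate a lottery stimulus set
#'
#' Draws `n_trials` (win probability, magnitude) pairs whose sample moments
#' match the design targets. Marginals are U-shaped Beta distributions on the
#' design ranges (calibrated so the printed task SDs are reproduced), and
#' pairs whose expected value would fall outside the admissible EV range are
#' rejected before use. When the targets are symmetric (the default), trials
#' are generated as reflection-balanced quadruples
#' `(p, m), (1-p, m), (p, 112-m), (1-p, 112-m)`, so the sample means of win
#' probability, magnitude and EV equal their targets exactly, as in a
#' counterbalanced task design.
#'
#' @param design A [stimulus_design()].
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `win_prob`, `magnitude`, `ev`.
#' @examples
#' stim <- design_stimuli(stimulus_design(n_trials = 120), seed = 1)
#' mean(stim$win_prob)  # exactly 0.5
#' @export
design_stimuli <- function(design = stimulus_design(), seed = NULL) {
  stopifnot(inherits(design, "stimulus_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_trials
  pr <- design$win_prob_range; mr <- design$magnitude_range
  sp <- .beta_shapes(design$win_prob_mean, design$win_prob_sd, pr,
                     .calib_shape_p)
  sm <- .beta_shapes(design$magnitude_mean, design$magnitude_sd, mr,
                     .calib_shape_m)
  balanced <- abs(design$win_prob_mean - mean(pr)) < 1e-9 &&
    abs(design$magnitude_mean - mean(mr)) < 1e-9 &&
    n %% 4L == 0L
  msum <- sum(mr)  # magnitude reflection pivot (2 + 110 = 112)

  draw_pairs <- function(k) {
    # rejection sampling of admissible (p, m) pairs
    p <- numeric(0); m <- numeric(0)
    tries <- 0L
    while (length(p) < k) {
      nb <- max(64L, 2L * (k - length(p)))
      pp <- pr[1] + diff(pr) * rbeta(nb, sp[1], sp[2])
      mm <- mr[1] + diff(mr) * rbeta(nb, sm[1], sm[2])
      if (balanced) {
        # every reflected member must respect the EV range
        keep <- abs(2 * pp - 1) * pmax(mm, msum - mm) <= min(-design$ev_range[1],
                                                             design$ev_range[2])
      } else {
        ev <- mm * (2 * pp - 1)
        keep <- ev >= design$ev_range[1] & ev <= design$ev_range[2]
      }
      p <- c(p, pp[keep]); m <- c(m, mm[keep])
      tries <- tries + 1L
      if (tries > 1000L) {
        abort("Stimulus rejection rule accepted too few pairs; targets appear infeasible with the EV range.")
      }
    }
    list(p = p[seq_len(k)], m = m[seq_len(k)])
  }

  if (balanced) {
    base <- draw_pairs(n %/% 4L)
    p <- c(base$p, 1 - base$p, base$p, 1 - base$p)
    m <- c(base$m, base$m, msum - base$m, msum - base$m)
  } else {
    pairs <- draw_pairs(n)
    p <- pairs$p; m <- pairs$m
  }
  ord <- sample.int(n)
  tibble::tibble(
    win_prob = p[ord],
    magnitude = m[ord],
    ev = expected_value(p[ord], m[ord])
  )
}
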