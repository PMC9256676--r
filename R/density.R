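#' First-passage-time density for constant drift
#'
#' Density of the decision time at one boundary of a Wiener diffusion with
#' constant drift `v`, boundary separation `a`, relative start `w` (fraction
#' of `a` from the lower boundary) and diffusion coefficient 1. Evaluated by
#' the classic dual series (method-of-images for small `t/a^2`, spectral for
#' large), truncated adaptively.
#'
#' @param v Drift rate (evidence/s).
#' @param a Boundary separation (> 0); with symmetric boundaries `(-B, B)`,
#'   `a = 2 * B`.
#' @param w Start fraction in (0, 1); `w = 0.5` is midway.
#' @param t Decision time(s) in seconds (> 0 for positive density).
#' @param boundary `"upper"` (accept) or `"lower"` (reject).
#' @return Density value(s) in 1/s.
#' @examples
#' constant_drift_density(v = 0, a = 2, w = 0.5, t = 0.5, boundary = "upper")
#' @export
constant_drift_density <- function(v, a, w, t, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  if (a <= 0) abort("`a` must be positive.")
  if (w <= 0 || w >= 1) abort("`w` must lie strictly in (0, 1).")
  .wfpt_density_cpp(t, v, a, w, boundary == "upper")
}

#' Absorption probability at the upper boundary
#'
#' Closed-form probability that a constant-drift diffusion reaches the upper
#' boundary before the lower one:
#' `(1 - exp(-2 v a w)) / (1 - exp(-2 v a))` (and `w` when `v = 0`).
#'
#' @inheritParams constant_drift_density
#' @return Probability in (0, 1).
#' @export
prob_upper <- function(v, a, w) {
  if (a <= 0) abort("`a` must be positive.")
  if (w <= 0 || w >= 1) abort("`w` must lie strictly in (0, 1).")
  .wfpt_prob_upper_cpp(v, a, w)
}

#' First-passage-time density for a two-segment drift schedule
#'
#' Density of the decision time for a Wiener diffusion whose drift is `v1` on
#' `(0, t_change)` and `v2` afterwards. For `t <= t_change` this is the
#' constant-drift density with `v1`; beyond the change point, the surviving
#' probability mass at `t_change` is propagated with the absorbing-boundary
#' transition kernel and the second-segment first-passage density is
#' integrated over entry states (spatial quadrature).
#'
#' @inheritParams constant_drift_density
#' @param v1,v2 Drift before and after the change point (evidence/s).
#' @param t_change Change-point time in seconds (>= 0).
#' @param method `"analytic_piecewise"` (default) or `"simulated_kde"`, a
#'   Monte-Carlo kernel-density validation backend.
#' @param quadrature `"trapezoid"` (spatial grid, default 200 points) or
#'   `"gauss"` (Gauss-Legendre, default 48 nodes).
#' @param n_nodes Number of spatial grid points / quadrature nodes.
#' @param n_sims Number of simulated paths for `simulated_kde` (>= 1e4).
#' @param dt Simulation step for `simulated_kde`.
#' @return Density value(s) in 1/s.
#' @export
piecewise_density <- function(v1, v2, t_change, a, w, t,
                              boundary = c("upper", "lower"),
                              method = c("analytic_piecewise", "simulated_kde"),
                              quadrature = c("trapezoid", "gauss"),
                              n_nodes = NULL, n_sims = 2e4, dt = 5e-4) {
  boundary <- match.arg(boundary)
  method <- match.arg(method)
  quadrature <- match.arg(quadrature)
  if (a <= 0) abort("`a` must be positive.")
  if (w <= 0 || w >= 1) abort("`w` must lie strictly in (0, 1).")
  if (t_change < 0) abort("`t_change` must be non-negative.")
  if (method == "simulated_kde") {
    if (n_sims < 1e4) abort("`n_sims` must be at least 1e4 for the KDE backend.")
    sim <- .sim_fpt_cpp(as.integer(n_sims), v1, v2, t_change, a, w, dt,
                        max(max(t) * 2, 10))
    want <- if (boundary == "upper") 1L else 0L
    taus <- sim$tau[!is.na(sim$hit) & sim$hit == want]
    mass <- length(taus) / n_sims
    if (length(taus) < 50) return(rep(0, length(t)))
    bw <- 0.9 * min(sd(taus), IQR(taus) / 1.34) * length(taus)^(-1/5)
    d <- stats::density(taus, bw = bw, from = 0, to = max(t) * 1.05, n = 2048)
    return(mass * stats::approx(d$x, d$y, xout = t, rule = 2)$y)
  }
  if (is.null(n_nodes)) n_nodes <- if (quadrature == "trapezoid") 200L else 48L
  .piecewise_fpt_cpp(t, v1, v2, t_change, a, w, boundary == "upper",
                     if (quadrature == "trapezoid") 0L else 1L,
                     as.integer(n_nodes))
}

#' @importFrom stats IQR
NULL

#' Choice/RT density and log-likelihood for one stDDM trial
#'
#' Maps an [stddm_params()] set and trial attributes to the first-passage
#' density of the observed (choice, RT) pair; the model variant determines the
#' drift segments and (for M2) the shifted starting point. `trial_loglik`
#' returns the log density, `-Inf` where the density is zero (e.g.
#' `rt <= ndt`). Optionally the density is renormalized by the probability of
#' responding before the task deadline; by default it is not, because trials
#' without a response are excluded rather than modeled.
#'
#' @inheritParams drift_rate
#' @param choice `"accept"` or `"reject"` (vectorized with `rt`).
#' @param rt Response time(s) in seconds (includes non-decision time).
#' @param deadline Response deadline in seconds.
#' @param normalize_deadline If `TRUE`, divide by the probability of a
#'   response before `deadline`.
#' @param quadrature,n_nodes Passed to the piecewise density evaluation.
#' @return `trial_density`: density values; `trial_loglik`: sum of log
#'   densities over the supplied trials.
#' @export
trial_density <- function(params, attrs, choice, rt,
                          quadrature = c("trapezoid", "gauss"),
                          n_nodes = NULL) {
  stopifnot(inherits(params, "stddm_params"))
  quadrature <- match.arg(quadrature)
  if (is.null(n_nodes)) n_nodes <- if (quadrature == "trapezoid") 200L else 48L
  n <- length(rt)
  va <- .attr_cols(attrs, n)
  acc <- as.integer(choice == "accept")
  .stddm_trial_density_cpp(rt, acc, va$v_p, va$v_m, va$v_a,
                           params$w_p, params$w_m, params$w_a, params$s,
                           params$ndt, params$B, params$bias,
                           .model_code(params$model_id),
                           if (quadrature == "trapezoid") 0L else 1L,
                           as.integer(n_nodes))
}

#' @rdname trial_density
#' @export
trial_loglik <- function(params, attrs, choice, rt, deadline = 4,
                         normalize_deadline = FALSE,
                         quadrature = c("gauss", "trapezoid"),
                         n_nodes = NULL) {
  quadrature <- match.arg(quadrature)
  d <- trial_density(params, attrs, choice, rt, quadrature = quadrature,
                     n_nodes = n_nodes)
  ll <- ifelse(d > 0, log(d), -Inf)
  if (normalize_deadline) {
    n <- length(rt)
    va <- .attr_cols(attrs, n)
    for (i in seq_len(n)) {
      p_resp <- .prob_response_by(params, list(v_p = va$v_p[i], v_m = va$v_m[i],
                                               v_a = va$v_a[i]), deadline)
      ll[i] <- ll[i] - log(p_resp)
    }
  }
  sum(ll)
}

# probability of a boundary crossing before the deadline, by time quadrature
.prob_response_by <- function(params, attrs, deadline) {
  tau_max <- deadline - params$ndt
  if (tau_max <= 0) return(1e-12)
  tt <- seq(1e-4, tau_max, length.out = 201)
  a <- attribute_vector(attrs$v_p, attrs$v_m, attrs$v_a)
  du <- trial_density(params, a, rep("accept", length(tt)), tt + params$ndt,
                      quadrature = "gauss")
  dl <- trial_density(params, a, rep("reject", length(tt)), tt + params$ndt,
                      quadrature = "gauss")
  h <- tt[2] - tt[1]
  min(1, sum((du + dl)) * h)
}

# accept attribute input as attribute_vector, list, or data frame with
# v_p/v_m/v_a columns; recycle scalars across n trials
.attr_cols <- function(attrs, n) {
  if (is.data.frame(attrs)) {
    out <- list(v_p = attrs$v_p, v_m = attrs$v_m, v_a = attrs$v_a)
  } else {
    out <- list(v_p = attrs[["v_p"]], v_m = attrs[["v_m"]], v_a = attrs[["v_a"]])
  }
  lapply(out, function(x) {
    if (is.null(x)) x <- 0
    rep_len(as.numeric(x), n)
  })
}
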